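# Packaged survey aggregates (2016 NHNS-J) and published reference values.

#' 2016 NHNS-J group aggregates
#'
#' Participant characteristics of the 2016 National Health and Nutrition
#' Survey, Japan, stratified by sex and age bracket (15-19, 20-29, ..., 60-69,
#' >= 70 years; 10,546 men and 12,355 women in total), as published in the
#' survey's aggregated reports: group size, mean (SD) height, body weight,
#' BMI, food and beverage weight, fluid intake from beverages, energy intake,
#' and protein/fat/carbohydrate intakes, plus the published derived columns
#' (calibrated energy intake, food quotient, predicted BMR, calibrated
#' EI/pBMR). The open bracket (>= 70) has `age_upper = NA`. Beverage fluid and
#' the derived columns are published without SDs.
#'
#' @param file Path to a CSV in the same schema; defaults to the packaged
#'   transcription.
#' @return Data.frame with one row per sex and age bracket.
#' @examples
#' head(nhns_groups())
#' @export
nhns_groups <- function(file = system.file("extdata", "nhns2016_groups.csv",
                                           package = "wtbudget")) {
  if (!nzchar(file) || !file.exists(file)) {
    stop_domain("group-summary file not found: '%s'", file)
  }
  read.csv(file, stringsAsFactors = FALSE)
}

#' Published water-budget distribution for the 2016 NHNS-J groups
#'
#' The published group-level water-consumption distribution estimated with
#' the DLW-database prediction equation on the 2016 NHNS-J aggregates: water
#' turnover and its metabolic, respiratory, transcutaneous and pre-formed
#' components (ml/day, rounded to integers) per sex and age bracket. Used as
#' reference values in regression tests; everything in it is recomputed by
#' [estimate_group_budgets()].
#'
#' @param file Path to a CSV in the same schema; defaults to the packaged
#'   transcription.
#' @return Data.frame with columns `sex`, `age_lower`, `age_upper`, `n`,
#'   `wt`, `w_met`, `w_res`, `w_trans`, `w_pre`.
#' @export
nhns_published_budget <- function(file = system.file(
                                    "extdata", "nhns2016_published_budget.csv",
                                    package = "wtbudget")) {
  if (!nzchar(file) || !file.exists(file)) {
    stop_domain("published-budget file not found: '%s'", file)
  }
  out <- read.csv(file, stringsAsFactors = FALSE)
  out$age_label <- age_label(out$age_lower, out$age_upper)
  out
}
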