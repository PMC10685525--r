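# Dietary-record-based vs equation-based pre-formed water.

#' Pre-formed water from a dietary record
#'
#' Dietary records report the weight of food consumed and the fluid drunk;
#' the water content of food averages 69\% of food weight in comparable
#' record studies. Pre-formed water is the sum of the two:
#' `beverage_fluid_ml + food_water_fraction * food_weight_g` (the food weight
#' here excludes beverages).
#'
#' @param food_weight_g Food weight (excluding beverages), g/day (>= 0).
#' @param beverage_fluid_ml Fluid from beverages, ml/day (>= 0).
#' @param food_water_fraction Water fraction of food in \[0, 1\],
#'   default 0.69.
#' @return Pre-formed water, ml/day. Vectorised.
#' @examples
#' dr_preformed_water(1000, 500) # 1190
#' @export
dr_preformed_water <- function(food_weight_g, beverage_fluid_ml,
                               food_water_fraction = 0.69) {
  check_numeric(food_weight_g, "food_weight_g", min = 0)
  check_numeric(beverage_fluid_ml, "beverage_fluid_ml", min = 0)
  check_numeric(food_water_fraction, "food_water_fraction", min = 0, max = 1)
  beverage_fluid_ml + food_water_fraction * food_weight_g
}

#' Compare equation-based and dietary-record pre-formed water per group
#'
#' Joins the two per-group estimates on their group keys and computes
#' absolute and relative differences,
#' `diff_abs = dr - equation` and `diff_rel = 100 * diff_abs / equation`
#' (the equation-based value is the denominator, so a record that captures
#' only 60\% of the equation's pre-formed water shows as -40\%).
#'
#' @param equation Data.frame with key columns (`sex`, `age_label` by
#'   default) and a `preformed` column of equation-based values, ml/day.
#' @param dr Data.frame with the same keys and a `preformed` column of
#'   dietary-record values, ml/day.
#' @param keys Character vector of join keys.
#' @return Data.frame with the keys, `preformed_equation`, `preformed_dr`,
#'   `diff_abs` (ml/day) and `diff_rel` (\%).
#' @examples
#' eq <- data.frame(sex = "male", age_label = "15-19", preformed = 2735)
#' dr <- data.frame(sex = "male", age_label = "15-19", preformed = 1648)
#' compare_preformed(eq, dr) # diff_abs -1087, diff_rel -39.7
#' @export
compare_preformed <- function(equation, dr, keys = c("sex", "age_label")) {
  for (nm in c("equation", "dr")) {
    d <- get(nm)
    miss <- setdiff(c(keys, "preformed"), names(d))
    if (length(miss)) {
      stop_domain("'%s' is missing column(s): %s", nm,
                  paste(miss, collapse = ", "))
    }
  }
  key_id <- function(d) do.call(paste, c(d[keys], sep = "\r"))
  only_eq <- setdiff(key_id(equation), key_id(dr))
  only_dr <- setdiff(key_id(dr), key_id(equation))
  if (length(only_eq) || length(only_dr)) {
    stop_domain(
      "group keys do not match; missing from dr: {%s}; missing from equation: {%s}",
      paste(gsub("\r", "/", only_eq), collapse = ", "),
      paste(gsub("\r", "/", only_dr), collapse = ", ")
    )
  }
  eq <- equation[c(keys, setdiff(names(equation), c(keys, "preformed")),
                   "preformed")]
  names(eq)[names(eq) == "preformed"] <- "preformed_equation"
  drv <- dr[c(keys, "preformed")]
  names(drv)[names(drv) == "preformed"] <- "preformed_dr"
  out <- merge(eq, drv, by = keys, sort = FALSE)
  out$diff_abs <- out$preformed_dr - out$preformed_equation
  out$diff_rel <- 100 * out$diff_abs / out$preformed_equation
  out
}

#' Age trend of the dietary-record underestimation
#'
#' Weighted linear regression of the per-group difference (relative and
#' absolute) on age: does the underestimation of pre-formed water by dietary
#' records shrink or grow with age?
#'
#' @param comparisons Data.frame from [compare_preformed()] with `diff_rel`
#'   and `diff_abs` columns.
#' @param ages Group midpoint ages, years (>= 3 groups).
#' @param weights Optional group sizes.
#' @return Data.frame with one row per measure (`diff_rel`, `diff_abs`):
#'   `slope` (per year), `se`, `p`.
#' @export
underestimation_trend <- function(comparisons, ages, weights = NULL) {
  miss <- setdiff(c("diff_rel", "diff_abs"), names(comparisons))
  if (length(miss)) {
    stop_domain("'comparisons' is missing column(s): %s",
                paste(miss, collapse = ", "))
  }
  if (nrow(comparisons) < 3) stop_domain("need >= 3 groups for a trend")
  rows <- lapply(c("diff_rel", "diff_abs"), function(m) {
    tr <- test_linear_trend(comparisons[[m]], ages, weights)
    data.frame(measure = m, slope = tr$slope, se = tr$se, p = tr$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
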