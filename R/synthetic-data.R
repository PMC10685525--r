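# Synthetic individual-level survey records whose group aggregates match
# configurable targets (stand-in for survey microdata, which is not public).

#' Specification of one synthetic survey group
#'
#' Distributional targets for one sex-by-age-bracket group: group size, mean
#' and SD of height, weight, energy intake, macronutrient intakes and food/
#' beverage weight, the alcohol energy share, and the height-weight
#' correlation. Intakes are modelled as truncated normals (truncation at 0
#' and at mean +/- 4 SD), the minimal assumption available when only means
#' and SDs are published.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_lower,age_upper Bracket bounds in years; `age_upper = NA`
#'   denotes the open bracket (ages drawn up to 80, the survey's upper age).
#' @param n Group size (>= 1).
#' @param height_mean,height_sd Height, cm.
#' @param weight_mean,weight_sd Body weight, kg.
#' @param ei_kj_mean,ei_kj_sd Reported energy intake, kJ/day (the mean is a
#'   consistency target: generated intake is rebuilt from macronutrients).
#' @param protein_g_mean,protein_g_sd,fat_g_mean,fat_g_sd,carbohydrate_g_mean,carbohydrate_g_sd
#'   Macronutrient intakes, g/day.
#' @param food_beverage_weight_mean,food_beverage_weight_sd Food and beverage
#'   weight, g/day.
#' @param beverage_fluid_ml Mean fluid intake from beverages, ml/day
#'   (published without SD; generated as a constant).
#' @param alcohol_share Alcohol share of energy, percent, or `NULL` to use
#'   the residual convention: the share by which the target energy intake
#'   exceeds the macronutrient energy at the target means, floored at 0.
#' @param hw_correlation Height-weight correlation in (-1, 1), default 0.4.
#' @param kcal_per_kj kcal per kJ used in the energy bookkeeping.
#' @return Object of class `wt_group_spec`.
#' @export
group_spec <- function(sex, age_lower, age_upper, n,
                       height_mean, height_sd, weight_mean, weight_sd,
                       ei_kj_mean, ei_kj_sd,
                       protein_g_mean, protein_g_sd,
                       fat_g_mean, fat_g_sd,
                       carbohydrate_g_mean, carbohydrate_g_sd,
                       food_beverage_weight_mean, food_beverage_weight_sd,
                       beverage_fluid_ml = NA_real_,
                       alcohol_share = NULL,
                       hw_correlation = 0.4,
                       kcal_per_kj = 0.239) {
  if (!sex %in% c("male", "female")) {
    stop_domain("'sex' must be 'male' or 'female'")
  }
  check_numeric(age_lower, "age_lower", min = 0)
  if (!is.na(age_upper)) {
    check_numeric(age_upper, "age_upper")
    if (age_upper <= age_lower) stop_domain("age bracket must have lower < upper")
  }
  check_numeric(n, "n", min = 1)
  for (nm in c("height_sd", "weight_sd", "ei_kj_sd", "protein_g_sd",
               "fat_g_sd", "carbohydrate_g_sd", "food_beverage_weight_sd")) {
    check_numeric(get(nm), nm, min = 0)
  }
  for (nm in c("height_mean", "weight_mean", "ei_kj_mean", "protein_g_mean",
               "fat_g_mean", "carbohydrate_g_mean",
               "food_beverage_weight_mean")) {
    check_numeric(get(nm), nm, min = 0)
  }
  check_numeric(hw_correlation, "hw_correlation", min = -1, max = 1,
                strict_min = TRUE)
  if (hw_correlation >= 1) stop_domain("'hw_correlation' must be < 1")
  macro_kcal <- 4 * protein_g_mean + 9 * fat_g_mean + 4 * carbohydrate_g_mean
  if (is.null(alcohol_share)) {
    ei_kcal <- ei_kj_mean * kcal_per_kj
    alcohol_share <- if (ei_kcal > 0) {
      max(0, 100 * (1 - macro_kcal / ei_kcal))
    } else 0
  }
  check_numeric(alcohol_share, "alcohol_share", min = 0, max = 50)
  structure(
    list(sex = sex, age_lower = age_lower, age_upper = age_upper, n = n,
         height_mean = height_mean, height_sd = height_sd,
         weight_mean = weight_mean, weight_sd = weight_sd,
         ei_kj_mean = ei_kj_mean, ei_kj_sd = ei_kj_sd,
         protein_g_mean = protein_g_mean, protein_g_sd = protein_g_sd,
         fat_g_mean = fat_g_mean, fat_g_sd = fat_g_sd,
         carbohydrate_g_mean = carbohydrate_g_mean,
         carbohydrate_g_sd = carbohydrate_g_sd,
         food_beverage_weight_mean = food_beverage_weight_mean,
         food_beverage_weight_sd = food_beverage_weight_sd,
         beverage_fluid_ml = beverage_fluid_ml,
         alcohol_share = alcohol_share,
         hw_correlation = hw_correlation,
         kcal_per_kj = kcal_per_kj),
    class = "wt_group_spec"
  )
}

#' Group specs for all 2016 NHNS-J groups
#'
#' Builds the 14 default [group_spec()]s from the packaged survey aggregates
#' (alcohol shares via the residual convention).
#'
#' @param groups Group-summary data.frame, default [nhns_groups()].
#' @param hw_correlation Height-weight correlation applied to every group.
#' @return Named list of `wt_group_spec` objects.
#' @export
nhns_group_specs <- function(groups = nhns_groups(), hw_correlation = 0.4) {
  specs <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    group_spec(
      sex = g$sex, age_lower = g$age_lower, age_upper = g$age_upper, n = g$n,
      height_mean = g$height_mean, height_sd = g$height_sd,
      weight_mean = g$weight_mean, weight_sd = g$weight_sd,
      ei_kj_mean = g$ei_kj_mean, ei_kj_sd = g$ei_kj_sd,
      protein_g_mean = g$protein_g_mean, protein_g_sd = g$protein_g_sd,
      fat_g_mean = g$fat_g_mean, fat_g_sd = g$fat_g_sd,
      carbohydrate_g_mean = g$carbohydrate_g_mean,
      carbohydrate_g_sd = g$carbohydrate_g_sd,
      food_beverage_weight_mean = g$food_beverage_weight_mean,
      food_beverage_weight_sd = g$food_beverage_weight_sd,
      beverage_fluid_ml = g$beverage_fluid_ml,
      hw_correlation = hw_correlation
    )
  })
  names(specs) <- paste(groups$sex,
                        age_label(groups$age_lower, groups$age_upper),
                        sep = ".")
  specs
}

# Truncated-normal sampling by inverse CDF (deterministic given the RNG
# stream; degenerate SD returns the mean).
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) {
    stop_domain("infeasible truncation: mean %s lies far outside [%s, %s]",
                format(mean), format(lower), format(upper))
  }
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate synthetic individual records for one group
#'
#' Draws `spec$n` individual records: age uniform within the bracket, height
#' and weight from a truncated bivariate normal with the spec's means, SDs
#' and correlation, macronutrients and food/beverage weight from independent
#' truncated normals (at 0 and mean +/- 4 SD), alcohol from the group's
#' alcohol energy share, and reported energy intake rebuilt as
#' 4P + 9F + 4C + 7A kcal with a multiplicative noise term (CV 3\%) so that
#' energy accounting stays internally consistent. Deterministic for a fixed
#' seed (Mersenne-Twister, inversion sampling).
#'
#' @param spec A [group_spec()].
#' @param seed Integer seed.
#' @return Data.frame of individual records in the subject-profile schema
#'   (`sex`, `age_label`, `age`, `height_cm`, `weight_kg`, `ei_kj`,
#'   `protein_g`, `fat_g`, `carbohydrate_g`, `alcohol_g`,
#'   `food_beverage_weight_g`, `beverage_fluid_ml`, `athlete`).
#' @examples
#' spec <- nhns_group_specs()[["male.15-19"]]
#' ind <- generate_individuals(spec, seed = 1)
#' colMeans(ind[c("height_cm", "weight_kg")])
#' @export
generate_individuals <- function(spec, seed) {
  if (!inherits(spec, "wt_group_spec")) {
    stop_domain("'spec' must be a wt_group_spec")
  }
  check_numeric(seed, "seed")
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  n <- spec$n
  upper_draw <- if (is.na(spec$age_upper)) 80 else spec$age_upper + 1
  age <- runif(n, spec$age_lower, upper_draw)

  height <- rtrunc_norm(n, spec$height_mean, spec$height_sd,
                        max(0, spec$height_mean - 4 * spec$height_sd),
                        spec$height_mean + 4 * spec$height_sd)
  rho <- spec$hw_correlation
  w_mu <- if (spec$height_sd == 0) {
    rep(spec$weight_mean, n)
  } else {
    spec$weight_mean +
      rho * spec$weight_sd / spec$height_sd * (height - spec$height_mean)
  }
  w_sd <- spec$weight_sd * sqrt(1 - rho^2)
  weight <- if (w_sd == 0) {
    w_mu
  } else {
    # conditional draw, truncated on the marginal's support
    lo <- max(0, spec$weight_mean - 4 * spec$weight_sd)
    hi <- spec$weight_mean + 4 * spec$weight_sd
    plo <- pnorm(lo, w_mu, w_sd)
    phi <- pnorm(hi, w_mu, w_sd)
    qnorm(runif(n, plo, phi), w_mu, w_sd)
  }

  draw_intake <- function(mean, sd) {
    rtrunc_norm(n, mean, sd, max(0, mean - 4 * sd), mean + 4 * sd)
  }
  protein <- draw_intake(spec$protein_g_mean, spec$protein_g_sd)
  fat <- draw_intake(spec$fat_g_mean, spec$fat_g_sd)
  carb <- draw_intake(spec$carbohydrate_g_mean, spec$carbohydrate_g_sd)
  food_wt <- draw_intake(spec$food_beverage_weight_mean,
                         spec$food_beverage_weight_sd)

  macro_kcal <- 4 * protein + 9 * fat + 4 * carb
  s <- spec$alcohol_share
  alc_kcal <- if (s > 0) macro_kcal * s / (100 - s) else rep(0, n)
  alcohol <- alc_kcal / 7
  noise <- 1 + rnorm(n, 0, 0.03)
  ei_kcal <- (macro_kcal + alc_kcal) * noise
  ei_kj <- ei_kcal / spec$kcal_per_kj

  data.frame(
    sex = spec$sex,
    age_label = age_label(spec$age_lower, spec$age_upper),
    age = age,
    height_cm = height,
    weight_kg = weight,
    ei_kj = ei_kj,
    protein_g = protein,
    fat_g = fat,
    carbohydrate_g = carb,
    alcohol_g = alcohol,
    food_beverage_weight_g = food_wt,
    beverage_fluid_ml = spec$beverage_fluid_ml,
    athlete = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Aggregate individual records to a group-summary table
#'
#' Per-group means and SDs of the sampled fields, the round-trip companion of
#' [generate_individuals()] (aggregating generated records recovers the spec
#' within sampling error).
#'
#' @param records Data.frame of individual records (non-empty).
#' @param by Grouping columns, default `c("sex", "age_label")`.
#' @return Data.frame with one row per group: `n`, and mean/SD columns for
#'   height, weight, energy intake, macronutrients and food/beverage weight.
#' @export
aggregate_individuals <- function(records, by = c("sex", "age_label")) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_domain("'records' must be a non-empty data.frame")
  }
  miss <- setdiff(by, names(records))
  if (length(miss)) {
    stop_domain("'records' is missing grouping column(s): %s",
                paste(miss, collapse = ", "))
  }
  fields <- c(height = "height_cm", weight = "weight_kg", ei_kj = "ei_kj",
              protein_g = "protein_g", fat_g = "fat_g",
              carbohydrate_g = "carbohydrate_g",
              food_beverage_weight = "food_beverage_weight_g")
  fields <- fields[fields %in% names(records)]
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- records[key == k, , drop = FALSE]
    out <- sub[1, by, drop = FALSE]
    out$n <- nrow(sub)
    for (i in seq_along(fields)) {
      x <- sub[[fields[i]]]
      out[[paste0(names(fields)[i], "_mean")]] <- mean(x)
      out[[paste0(names(fields)[i], "_sd")]] <-
        if (length(x) > 1) stats::sd(x) else 0
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the full default synthetic survey
#'
#' Emits individual records for all 14 sex-by-age-bracket groups using the
#' packaged survey targets. The default targets encode the survey's
#' reverse-U body-weight and energy-intake profiles over age in women, so the
#' downstream pipeline yields a female WT-age spline with significant
#' non-linearity and a male decline after about age 50.
#'
#' @param seed Integer seed; each group uses `seed + group index`.
#' @param specs List of [group_spec()]s, default [nhns_group_specs()].
#' @return Data.frame of individual records for every group.
#' @examples
#' \donttest{
#' survey <- scenario_reverse_u(seed = 1)
#' nrow(survey) # 22,901 records
#' }
#' @export
scenario_reverse_u <- function(seed = 1, specs = nhns_group_specs()) {
  check_numeric(seed, "seed")
  out <- lapply(seq_along(specs), function(i) {
    generate_individuals(specs[[i]], seed = as.integer(seed) + i)
  })
  do.call(rbind, out)
}
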