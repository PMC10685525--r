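# The WT prediction equation and the partition of water turnover into
# metabolic, respiratory, transcutaneous and pre-formed water.

#' Coefficients of the water-turnover prediction equation
#'
#' The default values are the published coefficients of the prediction
#' equation developed from the international DLW database (R2 = 0.471):
#' intercept -713.1 ml; PAL 1076 ml; body weight 14.34 ml/kg; sex (men = 1)
#' 374.9 ml; relative humidity 5.823 ml/\%; athlete status 1070 ml; HDI class
#' 104.6 ml; altitude 0.4726 ml/m; age squared -0.3529 ml/yr2; age 24.78
#' ml/yr; temperature squared 1.865 ml/degC2; temperature -19.66 ml/degC.
#' Any coefficient can be overridden (coefficients are data, not code, so
#' sensitivity sweeps can perturb them); defaults are never silently altered.
#'
#' @param ... Named overrides, e.g. `wt_coefficients(beta1_pal = 1100)`.
#' @return Named numeric vector of class `wt_coefficients`.
#' @examples
#' wt_coefficients()
#' @export
wt_coefficients <- function(...) {
  beta <- c(beta0 = -713.1, beta1_pal = 1076, beta2_weight = 14.34,
            beta3_sex = 374.9, beta4_humidity = 5.823, beta5_athlete = 1070,
            beta6_hdi = 104.6, beta7_altitude = 0.4726, beta8_age2 = -0.3529,
            beta9_age = 24.78, beta10_temp2 = 1.865, beta11_temp = -19.66)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(beta))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop_domain("unknown coefficient name(s): %s",
                  paste(bad, collapse = ", "))
    }
    for (nm in names(dots)) {
      check_numeric(dots[[nm]], nm)
      beta[nm] <- dots[[nm]]
    }
  }
  structure(beta, class = "wt_coefficients")
}

#' Predict water turnover
#'
#' Evaluates the DLW-database prediction equation
#' \deqn{WT = \beta_0 + \beta_1 PAL + \beta_2 W + \beta_3 sex + \beta_4 RH +
#'   \beta_5 athlete + \beta_6 HDI + \beta_7 alt + \beta_8 age^2 +
#'   \beta_9 age + \beta_{10} T^2 + \beta_{11} T}
#' with sex coded 1 (men) / 0 (women), athlete 1/0, and HDI 0/1/2 for
#' high/middle/low development. The equation was calibrated on adults aged 18
#' and over; ages below 18 are accepted with a warning (the survey's youngest
#' bracket starts at 15). Negative results are returned, flagged by a warning,
#' rather than clamped, so sensitivity sweeps stay faithful.
#'
#' @param pal Physical activity level (> 0).
#' @param weight Body weight, kg (> 0).
#' @param sex `"male"`/`"female"` (or 1/0).
#' @param humidity Relative humidity, percent.
#' @param athlete Logical (or 1/0), default `FALSE`.
#' @param hdi `"high"`, `"middle"`, `"low"` (or 0/1/2).
#' @param altitude Altitude, m.
#' @param age Age, years.
#' @param temperature Air temperature, degC.
#' @param coeffs Coefficient set, see [wt_coefficients()].
#' @return Predicted water turnover, ml/day. Vectorised.
#' @examples
#' predict_wt(pal = 9676 / 6380, weight = 70.9, sex = "male",
#'            humidity = 74.7, athlete = FALSE, hdi = "high",
#'            altitude = 189.2, age = 45, temperature = 10.9) # ~3243
#' @export
predict_wt <- function(pal, weight, sex, humidity, athlete = FALSE,
                       hdi = "high", altitude = 0, age, temperature,
                       coeffs = wt_coefficients()) {
  check_numeric(pal, "pal", min = 0)  # 0 is the degenerate zero-intake limit
  check_numeric(weight, "weight", min = 0, strict_min = TRUE)
  check_numeric(humidity, "humidity", min = 0, max = 100)
  check_numeric(altitude, "altitude", min = -500, max = 9000)
  check_numeric(age, "age", min = 0, max = 120)
  check_numeric(temperature, "temperature", min = -40, max = 60)
  if (!inherits(coeffs, "wt_coefficients")) {
    coeffs <- do.call(wt_coefficients, as.list(coeffs))
  }
  if (any(age < 18)) {
    warning("ages below 18 are outside the equation's calibration range",
            call. = FALSE)
  }
  male <- as.numeric(sex_is_male(sex))
  ath <- as.numeric(as.logical(athlete))
  hdi <- hdi_code(hdi)
  wt <- coeffs[["beta0"]] +
    coeffs[["beta1_pal"]] * pal +
    coeffs[["beta2_weight"]] * weight +
    coeffs[["beta3_sex"]] * male +
    coeffs[["beta4_humidity"]] * humidity +
    coeffs[["beta5_athlete"]] * ath +
    coeffs[["beta6_hdi"]] * hdi +
    coeffs[["beta7_altitude"]] * altitude +
    coeffs[["beta8_age2"]] * age^2 +
    coeffs[["beta9_age"]] * age +
    coeffs[["beta10_temp2"]] * temperature^2 +
    coeffs[["beta11_temp"]] * temperature
  if (any(wt < 0)) {
    warning("nonphysiological result: predicted water turnover is negative",
            call. = FALSE)
  }
  wt
}

#' Age at which the equation's age contribution peaks
#'
#' The age terms \eqn{\beta_8 age^2 + \beta_9 age} are extremal at
#' \eqn{-\beta_9 / (2\beta_8)}; with the default coefficients this is about
#' 35.1 years (a maximum, since \eqn{\beta_8 < 0}).
#'
#' @param coeffs Coefficient set, see [wt_coefficients()].
#' @return Age in years.
#' @export
wt_age_optimum <- function(coeffs = wt_coefficients()) {
  if (coeffs[["beta8_age2"]] == 0) {
    stop_domain("age optimum undefined: quadratic age coefficient is zero")
  }
  -coeffs[["beta9_age"]] / (2 * coeffs[["beta8_age2"]])
}

#' Metabolic water production
#'
#' Water produced by macronutrient oxidation:
#' \deqn{W_{met} = EI_{cal} \times \frac{1}{100000}
#'   \left[0.119\,\%fat + 0.103\,\%pro + 0.150\,\%carb + 0.168\,\%alc\right]}
#' with calibrated energy intake in kcal/day and percentages on the 0-100
#' scale. The bracketed product is in L/day and is returned in ml/day.
#' Percentage sums above 100 are tolerated up to 120: reported intake and
#' macronutrient energy never balance exactly in dietary records, so sums a
#' few points above 100 are routine in individual records. Sums beyond 120
#' indicate a unit or scale mistake and are a domain error.
#'
#' @param ei_calibrated_kcal Calibrated energy intake, kcal/day (>= 0).
#' @param pct_fat,pct_protein,pct_carb,pct_alcohol Energy percentages (>= 0).
#' @return Metabolic water, ml/day. Vectorised.
#' @examples
#' metabolic_water(1812.4, 26.1, 15.4, 57.3, 1.2) # ~244
#' @export
metabolic_water <- function(ei_calibrated_kcal, pct_fat, pct_protein,
                            pct_carb, pct_alcohol) {
  check_numeric(ei_calibrated_kcal, "ei_calibrated_kcal", min = 0)
  check_numeric(pct_fat, "pct_fat", min = 0)
  check_numeric(pct_protein, "pct_protein", min = 0)
  check_numeric(pct_carb, "pct_carb", min = 0)
  check_numeric(pct_alcohol, "pct_alcohol", min = 0)
  total <- pct_fat + pct_protein + pct_carb + pct_alcohol
  if (any(total > 120)) {
    stop_domain("energy percentages sum to %.1f > 120", max(total))
  }
  l_day <- ei_calibrated_kcal / 100000 *
    (0.119 * pct_fat + 0.103 * pct_protein +
       0.150 * pct_carb + 0.168 * pct_alcohol)
  l_day * 1000
}

#' Respiratory water uptake
#'
#' Atmospheric water entering through ventilation:
#' \deqn{W_{res} = [AH/1000] \times 0.035 \, rCO_2} with absolute humidity in
#' g/m3 and CO2 production in L/day (3.5\% of inhaled air is assumed to be
#' CO2). The product is in L/day and is returned in ml/day.
#'
#' @param absolute_humidity Absolute humidity, g/m3 (>= 0).
#' @param rco2 CO2 production rate, L/day (>= 0).
#' @return Respiratory water, ml/day. Vectorised.
#' @examples
#' respiratory_water(7.45, 412.6) # ~108
#' @export
respiratory_water <- function(absolute_humidity, rco2) {
  check_numeric(absolute_humidity, "absolute_humidity", min = 0)
  check_numeric(rco2, "rco2", min = 0)
  (absolute_humidity / 1000) * 0.035 * rco2 * 1000
}

#' Transcutaneous water uptake
#'
#' Atmospheric water absorbed through the skin:
#' \deqn{W_{trans} = [0.18 \, AH / 21.7] \times c \times BSA \times 1.44}
#' where 0.18 g/m2 is the transdermal absorption rate per m2 of body surface
#' in saturated air (21.7 mg/L), c is the clothing coefficient (clothing
#' halves evaporation; default 0.5), and 1.44 converts to a daily total. The
#' product is in L/day and is returned in ml/day.
#'
#' @param absolute_humidity Absolute humidity, g/m3 (>= 0).
#' @param bsa Body surface area, m2 (> 0).
#' @param clothing_factor Clothing coefficient in (0, 1\], default 0.5.
#' @return Transcutaneous water, ml/day. Vectorised.
#' @examples
#' transcutaneous_water(7.45, 1.702) # ~76
#' @export
transcutaneous_water <- function(absolute_humidity, bsa,
                                 clothing_factor = 0.5) {
  check_numeric(absolute_humidity, "absolute_humidity", min = 0)
  check_numeric(bsa, "bsa", min = 0, strict_min = TRUE)
  check_numeric(clothing_factor, "clothing_factor", min = 0, max = 1,
                strict_min = TRUE)
  (0.18 * absolute_humidity / 21.7) * clothing_factor * bsa * 1.44 * 1000
}

#' Pre-formed water by difference
#'
#' Water ingested via food and beverages, obtained by subtracting metabolic,
#' respiratory and transcutaneous water from total water turnover:
#' \deqn{W_{pre} = WT - [W_{met} + W_{res} + W_{trans}].} The difference is
#' exact (conservation); negative results are flagged by a warning, not
#' clamped.
#'
#' @param wt Water turnover, ml/day.
#' @param w_met,w_res,w_trans Component waters, ml/day.
#' @return Pre-formed water, ml/day. Vectorised.
#' @examples
#' preformed_water(3243, 311, 109, 81) # 2742
#' @export
preformed_water <- function(wt, w_met, w_res, w_trans) {
  check_numeric(wt, "wt")
  check_numeric(w_met, "w_met")
  check_numeric(w_res, "w_res")
  check_numeric(w_trans, "w_trans")
  w_pre <- wt - (w_met + w_res + w_trans)
  if (any(w_pre < 0)) {
    warning("nonphysiological result: pre-formed water is negative",
            call. = FALSE)
  }
  w_pre
}

#' Compute full water budgets for subject records
#'
#' Orchestrates the energy derivations and the water equations in order:
#' energy profile (calibrated EI, pBMR, PAL, FQ, rCO2, BSA, energy
#' percentages), then water turnover, metabolic, respiratory, transcutaneous
#' and pre-formed water. The returned budgets satisfy the conservation
#' identity \eqn{WT = W_{met} + W_{res} + W_{trans} + W_{pre}} to machine
#' precision. Warnings raised by any stage are collected into a `flags`
#' column instead of surfacing repeatedly.
#'
#' @param profile Data.frame of subject records (individuals or group-mean
#'   rows) with columns `sex`, `age`, `height_cm`, `weight_kg`, `ei_kj`,
#'   `protein_g`, `fat_g`, `carbohydrate_g`, and optionally `alcohol_g`,
#'   `athlete` and `pal` (an externally supplied PAL, used when
#'   `config$pal_source == "external_pal_table"`).
#' @param env Environment, see [survey_environment()].
#' @param config Run configuration, see [default_run_config()].
#' @return `profile` augmented with the energy columns and `wt`, `w_met`,
#'   `w_res`, `w_trans`, `w_pre` (ml/day) plus a `flags` character column.
#' @examples
#' groups <- nhns_groups()
#' prof <- group_profile(groups[groups$sex == "male" &
#'                              groups$age_lower == 40, ])
#' compute_budget(prof)[, c("wt", "w_met", "w_res", "w_trans", "w_pre")]
#' @export
compute_budget <- function(profile, env = survey_environment(),
                           config = default_run_config()) {
  if (!inherits(env, "wt_environment")) {
    stop_domain("'env' must be built with survey_environment()")
  }
  out <- withCallingHandlers(
    {
      out <- energy_profile(profile, config)
      if (identical(config$pal_source, "external_pal_table")) {
        if (!"pal" %in% names(profile)) {
          stop_domain(paste("pal_source = 'external_pal_table' requires a",
                            "'pal' column in the profile"))
        }
        out$pal <- profile$pal
      }
      athlete <- if ("athlete" %in% names(out)) out$athlete else FALSE
      out$wt <- predict_wt(
        pal = out$pal, weight = out$weight_kg, sex = out$sex,
        humidity = env$relative_humidity_pct, athlete = athlete,
        hdi = env$hdi_class, altitude = env$altitude_m, age = out$age,
        temperature = env$temperature_c, coeffs = config$coefficients
      )
      out$w_met <- metabolic_water(out$ei_calibrated_kcal, out$pct_fat,
                                   out$pct_protein, out$pct_carb,
                                   out$pct_alcohol)
      out$w_res <- respiratory_water(env$absolute_humidity_gm3, out$rco2_l)
      out$w_trans <- transcutaneous_water(env$absolute_humidity_gm3,
                                          out$bsa_m2, config$clothing_factor)
      out$w_pre <- preformed_water(out$wt, out$w_met, out$w_res, out$w_trans)
      out
    },
    # stage warnings are re-expressed as per-row flags below
    warning = function(w) invokeRestart("muffleWarning")
  )
  flag <- function(cond, label) ifelse(cond, label, NA_character_)
  flag_mat <- cbind(
    flag(out$age < 18, "age_below_calibration_range"),
    flag(out$wt < 0, "negative_wt"),
    flag(out$w_pre < 0, "negative_w_pre")
  )
  out$flags <- apply(flag_mat, 1, function(r) {
    paste(r[!is.na(r)], collapse = "; ")
  })
  out
}

#' Build a subject profile from group-aggregate rows
#'
#' Turns rows of a group-summary table (the shape of [nhns_groups()]) into a
#' group-mean subject profile usable by [compute_budget()]: each row gets the
#' bracket midpoint age (`(lower + upper + 1)/2`, e.g. 17.5 for 15-19; the
#' open bracket gets `config$open_bracket_age`, default 75), the mean
#' anthropometrics and intakes, and the group size `n`.
#'
#' @param groups Data.frame in the group-summary schema (see [nhns_groups()]).
#' @param config Run configuration (supplies the open-bracket age).
#' @return Data.frame with one row per group in the subject-profile schema,
#'   plus `age_label` and `n`.
#' @export
group_profile <- function(groups, config = default_run_config()) {
  need <- c("sex", "age_lower", "age_upper", "n", "height_mean",
            "weight_mean", "ei_kj_mean", "protein_g_mean", "fat_g_mean",
            "carbohydrate_g_mean")
  miss <- setdiff(need, names(groups))
  if (length(miss)) {
    stop_domain("group table is missing column(s): %s",
                paste(miss, collapse = ", "))
  }
  data.frame(
    sex = groups$sex,
    age_label = age_label(groups$age_lower, groups$age_upper),
    age = age_midpoint(groups$age_lower, groups$age_upper,
                       config$open_bracket_age),
    n = groups$n,
    height_cm = groups$height_mean,
    weight_kg = groups$weight_mean,
    ei_kj = groups$ei_kj_mean,
    protein_g = groups$protein_g_mean,
    fat_g = groups$fat_g_mean,
    carbohydrate_g = groups$carbohydrate_g_mean,
    athlete = FALSE,
    stringsAsFactors = FALSE
  )
}

age_midpoint <- function(lower, upper, open_bracket_age = 75) {
  ifelse(is.na(upper), open_bracket_age, (lower + upper + 1) / 2)
}

age_label <- function(lower, upper) {
  ifelse(is.na(upper), paste0(">=", lower), paste0(lower, "-", upper))
}

#' Water budgets for every group of a survey summary table
#'
#' Runs [compute_budget()] on the group means of a survey summary table and
#' returns a tidy per-group budget table (the layout of the published
#' water-consumption distribution: sex, age bracket, n, WT and its four
#' components).
#'
#' @param groups Group-summary data.frame, default the packaged 2016 NHNS-J
#'   aggregates ([nhns_groups()]).
#' @param env Environment, see [survey_environment()].
#' @param config Run configuration, see [default_run_config()].
#' @return Data.frame with columns `sex`, `age_label`, `age`, `n`, `pal`,
#'   `wt`, `w_met`, `w_res`, `w_trans`, `w_pre`, `wt_per_kg`, `flags`.
#' @examples
#' budgets <- estimate_group_budgets()
#' publication_view(budgets)
#' @export
estimate_group_budgets <- function(groups = nhns_groups(),
                                   env = survey_environment(),
                                   config = default_run_config()) {
  prof <- group_profile(groups, config)
  res <- compute_budget(prof, env, config)
  data.frame(
    sex = res$sex, age_label = res$age_label, age = res$age, n = res$n,
    pal = res$pal, wt = res$wt, w_met = res$w_met, w_res = res$w_res,
    w_trans = res$w_trans, w_pre = res$w_pre,
    wt_per_kg = res$wt / res$weight_kg,
    flags = res$flags,
    stringsAsFactors = FALSE
  )
}

#' Publication-style rounding of a budget table
#'
#' Display rounding only (full precision is kept in the computed tables):
#' water volumes to integer ml/day, PAL and per-kg values to 2 decimals.
#'
#' @param budget Data.frame from [estimate_group_budgets()].
#' @return Data.frame with rounded display columns.
#' @export
publication_view <- function(budget) {
  out <- budget
  for (nm in intersect(c("wt", "w_met", "w_res", "w_trans", "w_pre"),
                       names(out))) {
    out[[nm]] <- round(out[[nm]])
  }
  for (nm in intersect(c("pal", "fq", "wt_per_kg"), names(out))) {
    out[[nm]] <- round(out[[nm]], 2)
  }
  out
}
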