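# Run configuration and the end-to-end pipeline.

#' Default run configuration
#'
#' All constants of the analysis, settable in one place (no magic numbers in
#' stage code). Defaults reproduce the primary analysis: survey environment
#' (10.9 degC, 74.7\% RH, absolute humidity 7.45 g/m3, 189.2 m, high HDI),
#' energy-intake calibration factor 1.09, kJ-to-kcal factor 0.239, food water
#' fraction 0.69, clothing coefficient 0.5, open-bracket midpoint age 75,
#' published equation coefficients, PAL from calibrated EI / predicted BMR,
#' and spline knots at ages 18/48/77.
#'
#' @param ... Named overrides of top-level fields, e.g.
#'   `default_run_config(calibration_factor = 1)`.
#' @return Object of class `wt_config` (a list).
#' @examples
#' cfg <- default_run_config()
#' cfg$calibration_factor
#' @export
default_run_config <- function(...) {
  cfg <- list(
    environment = survey_environment(),
    calibration_factor = 1.09,
    kcal_per_kj = 0.239,
    food_water_fraction = 0.69,
    clothing_factor = 0.5,
    open_bracket_age = 75,
    coefficients = wt_coefficients(),
    pal_source = "calibrated_ei_over_pbmr",
    pal_table = NULL,
    knots = c(18, 48, 77),
    seed = NULL
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop_domain("unknown config field(s): %s", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  if (!cfg$pal_source %in% c("calibrated_ei_over_pbmr",
                             "external_pal_table")) {
    stop_domain("'pal_source' must be 'calibrated_ei_over_pbmr' or 'external_pal_table'")
  }
  structure(cfg, class = "wt_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Loads a config file and applies it on top of the defaults. The
#' `environment` block accepts keys `temperature_c`, `relative_humidity_pct`,
#' `absolute_humidity_gm3`, `altitude_m`, `hdi_class`; a `coefficients` block
#' overrides individual equation coefficients. Every override is logged
#' (via `message()`) with old and new values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Object of class `wt_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: '%s'", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop_domain("unsupported config format '.%s' (use yaml or json)", ext)
  )
  cfg <- default_run_config()
  log_override <- function(field, old, new) {
    message(sprintf("config override: %s: %s -> %s", field,
                    paste(format(old), collapse = ","),
                    paste(format(new), collapse = ",")))
  }
  if (!is.null(raw$environment)) {
    env_args <- list(temperature_c = 10.9, relative_humidity_pct = 74.7,
                     absolute_humidity_gm3 = 7.45, altitude_m = 189.2,
                     hdi_class = "high")
    for (k in names(raw$environment)) {
      if (!k %in% names(env_args)) {
        stop_domain("unknown environment key '%s'", k)
      }
      log_override(paste0("environment.", k), env_args[[k]],
                   raw$environment[[k]])
      # [k] <- list(...) so an explicit YAML null survives as NULL
      env_args[k] <- list(raw$environment[[k]])
    }
    cfg$environment <- do.call(survey_environment, env_args)
    raw$environment <- NULL
  }
  if (!is.null(raw$coefficients)) {
    overrides <- raw$coefficients
    defaults <- wt_coefficients()
    for (k in names(overrides)) {
      log_override(paste0("coefficients.", k), defaults[[k]], overrides[[k]])
    }
    cfg$coefficients <- do.call(wt_coefficients, as.list(overrides))
    raw$coefficients <- NULL
  }
  if (!is.null(raw$pal_table)) {
    cfg$pal_table <- as.data.frame(raw$pal_table, stringsAsFactors = FALSE)
    log_override("pal_table", "NULL", sprintf("%d rows", nrow(cfg$pal_table)))
    raw$pal_table <- NULL
  }
  for (k in names(raw)) {
    if (!k %in% names(cfg)) stop_domain("unknown config field '%s'", k)
    log_override(k, cfg[[k]], raw[[k]])
    cfg[[k]] <- raw[[k]]
  }
  default_run_config_check(cfg)
}

default_run_config_check <- function(cfg) {
  args <- cfg[setdiff(names(cfg), c("environment", "coefficients"))]
  out <- do.call(default_run_config, args)
  out$environment <- cfg$environment
  out$coefficients <- cfg$coefficients
  out
}

# schema detection: group-aggregate vs individual-level tables
input_kind <- function(input) {
  if ("height_mean" %in% names(input)) "group"
  else if ("height_cm" %in% names(input)) "individual"
  else stop_domain(
    "unrecognised input schema: expected column 'height_mean' (group table) or 'height_cm' (individual table); found: %s",
    paste(names(input), collapse = ", "))
}

validate_input <- function(input, kind) {
  need <- if (kind == "group") {
    c("sex", "age_lower", "age_upper", "n", "height_mean", "weight_mean",
      "ei_kj_mean", "protein_g_mean", "fat_g_mean", "carbohydrate_g_mean")
  } else {
    c("sex", "age", "height_cm", "weight_kg", "ei_kj", "protein_g",
      "fat_g", "carbohydrate_g")
  }
  miss <- setdiff(need, names(input))
  if (length(miss)) {
    stop_domain("input schema violation: missing column(s) %s",
                paste(miss, collapse = ", "))
  }
  for (nm in setdiff(need, c("sex", "age_upper"))) {
    bad <- which(!is.finite(input[[nm]]))
    if (length(bad)) {
      stop_domain("input schema violation: non-finite value at row %d, column '%s'",
                  bad[1], nm)
    }
  }
  invisible(input)
}

#' Run the full analysis pipeline
#'
#' Binds the stages in order — environment, energy derivations, water-budget
#' partition, dietary-record comparison, spline dose-response — on either a
#' group-aggregate table (the published survey schema, see [nhns_groups()])
#' or an individual-level table (the subject-profile schema emitted by
#' [generate_individuals()]).
#'
#' For group input the dietary-record pre-formed water is taken from the
#' published `beverage_fluid_ml` column (which in the survey aggregates
#' already equals beverages plus 69\% of food-only weight); for individual
#' input it is rebuilt per record with [dr_preformed_water()], treating
#' beverage weight as 1 g/ml so food-only weight is the combined weight minus
#' beverage fluid.
#'
#' @param input Data.frame, or path to a CSV, in either schema.
#' @param config Run configuration, see [default_run_config()].
#' @param output_dir Optional directory; when given, the budget, comparison
#'   and spline-curve tables are written there as CSV (full precision, plus a
#'   `budget_publication.csv` display view).
#' @return List of class `wt_pipeline_result`: `budget` (per-group water
#'   budgets), `comparison` (pre-formed water comparison with `diff_abs`,
#'   `diff_rel`), `trend` (per-sex underestimation trends), `splines` (per-sex
#'   `wt_rcs` fits for WT and pre-formed water), `curves` (fitted curves on an
#'   age grid), `warnings` (collected stage flags), `config`.
#' @examples
#' res <- run_pipeline(nhns_groups())
#' publication_view(res$budget)
#' res$splines$male_wt$nonlinearity_p
#' @export
run_pipeline <- function(input, config = default_run_config(),
                         output_dir = NULL) {
  if (is.character(input)) {
    if (!file.exists(input)) stop_domain("input file not found: '%s'", input)
    input <- read.csv(input, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(input) || nrow(input) == 0) {
    stop_domain("input schema violation: empty input table")
  }
  kind <- input_kind(input)
  validate_input(input, kind)
  env <- config$environment

  if (kind == "group") {
    groups <- input
    if (identical(config$pal_source, "external_pal_table")) {
      groups <- merge_pal_table(groups, config$pal_table)
    }
    prof <- group_profile(groups, config)
    if (!is.null(groups$pal_external)) prof$pal <- groups$pal_external
    budget_full <- compute_budget(prof, env, config)
    budget <- data.frame(
      sex = budget_full$sex, age_label = budget_full$age_label,
      age = budget_full$age, n = budget_full$n, pal = budget_full$pal,
      wt = budget_full$wt, w_met = budget_full$w_met,
      w_res = budget_full$w_res, w_trans = budget_full$w_trans,
      w_pre = budget_full$w_pre,
      wt_per_kg = budget_full$wt / budget_full$weight_kg,
      flags = budget_full$flags, stringsAsFactors = FALSE)
    dr <- data.frame(sex = groups$sex,
                     age_label = age_label(groups$age_lower,
                                           groups$age_upper),
                     preformed = groups$beverage_fluid_ml,
                     stringsAsFactors = FALSE)
  } else {
    budget_full <- compute_budget(input, env, config)
    if (!"age_label" %in% names(budget_full)) {
      budget_full$age_label <- cut(budget_full$age,
                                   c(15, 20, 30, 40, 50, 60, 70, Inf),
                                   right = FALSE)
    }
    budget <- budget_group_means(budget_full)
    dr <- NULL
    if (all(c("food_beverage_weight_g", "beverage_fluid_ml") %in%
            names(budget_full))) {
      dr_vals <- dr_preformed_water(
        pmax(0, budget_full$food_beverage_weight_g -
               budget_full$beverage_fluid_ml),
        budget_full$beverage_fluid_ml, config$food_water_fraction)
      dr <- stats::aggregate(
        list(preformed = dr_vals),
        by = list(sex = budget_full$sex, age_label = budget_full$age_label),
        FUN = mean)
    }
  }

  comparison <- NULL
  trend <- NULL
  if (!is.null(dr)) {
    eq <- budget[c("sex", "age_label", "n", "w_pre")]
    names(eq)[names(eq) == "w_pre"] <- "preformed"
    comparison <- compare_preformed(eq, dr)
    comparison <- merge(comparison,
                        unique(budget[c("sex", "age_label", "age")]),
                        by = c("sex", "age_label"), sort = FALSE)
    trend <- do.call(rbind, lapply(split(comparison, comparison$sex),
      function(d) {
        tr <- underestimation_trend(d, d$age, d$n)
        tr$sex <- d$sex[1]
        tr
      }))
    rownames(trend) <- NULL
  }

  splines <- list()
  curves <- list()
  for (sx in unique(budget$sex)) {
    if (kind == "group") {
      d <- budget[budget$sex == sx, ]
      wts <- d$n
    } else {
      d <- budget_full[budget_full$sex == sx, ]
      wts <- NULL
    }
    for (oc in c("wt", "w_pre")) {
      fit <- fit_spline(d[[oc]], d$age, weights = wts, knots = config$knots)
      nm <- paste0(sx, "_", oc)
      splines[[nm]] <- fit
      curves[[nm]] <- spline_curve(fit)
    }
  }

  res <- structure(
    list(budget = budget, comparison = comparison, trend = trend,
         splines = splines, curves = curves,
         warnings = unique(budget$flags[budget$flags != ""]),
         config = config),
    class = "wt_pipeline_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(budget, file.path(output_dir, "budget.csv"),
              row.names = FALSE)
    write.csv(publication_view(budget),
              file.path(output_dir, "budget_publication.csv"),
              row.names = FALSE)
    if (!is.null(comparison)) {
      write.csv(comparison, file.path(output_dir, "comparison.csv"),
                row.names = FALSE)
      write.csv(trend, file.path(output_dir, "trend.csv"), row.names = FALSE)
    }
    for (nm in names(curves)) {
      write.csv(curves[[nm]],
                file.path(output_dir, paste0("spline_", nm, ".csv")),
                row.names = FALSE)
    }
  }
  res
}

# per-group means of individual-level budgets (for the comparison stage)
budget_group_means <- function(budget_full) {
  agg <- stats::aggregate(
    budget_full[c("wt", "w_met", "w_res", "w_trans", "w_pre", "weight_kg",
                  "age", "pal")],
    by = list(sex = budget_full$sex, age_label = budget_full$age_label),
    FUN = mean)
  cnt <- stats::aggregate(list(n = budget_full$wt),
                          by = list(sex = budget_full$sex,
                                    age_label = budget_full$age_label),
                          FUN = length)
  out <- merge(agg, cnt, by = c("sex", "age_label"), sort = FALSE)
  out$wt_per_kg <- out$wt / out$weight_kg
  out$flags <- ""
  out
}

merge_pal_table <- function(groups, pal_table) {
  if (is.null(pal_table)) {
    stop_domain("pal_source = 'external_pal_table' but config$pal_table is NULL")
  }
  need <- c("sex", "age_label", "pal")
  miss <- setdiff(need, names(pal_table))
  if (length(miss)) {
    stop_domain("pal_table is missing column(s): %s",
                paste(miss, collapse = ", "))
  }
  # rename before merging: survey tables may carry their own printed 'pal'
  pal_table <- pal_table[c("sex", "age_label", "pal")]
  names(pal_table)[3] <- "pal_external"
  groups$age_label <- age_label(groups$age_lower, groups$age_upper)
  groups$.row <- seq_len(nrow(groups))
  m <- merge(groups, pal_table, by = c("sex", "age_label"), all.x = TRUE,
             sort = FALSE)
  m <- m[order(m$.row), ]
  m$.row <- NULL
  if (any(is.na(m$pal_external))) {
    stop_domain("pal_table has no PAL for group(s): %s",
                paste(m$age_label[is.na(m$pal_external)], collapse = ", "))
  }
  m
}

#' @export
print.wt_pipeline_result <- function(x, ...) {
  cat("Water-budget pipeline result\n")
  cat(sprintf("  %d groups, %d spline fits\n", nrow(x$budget),
              length(x$splines)))
  print(publication_view(x$budget))
  invisible(x)
}
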