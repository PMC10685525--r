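specs <- nhns_group_specs()

test_that("degenerate zero-SD specs emit records equal to the group means", {
  spec <- group_spec(
    sex = "female", age_lower = 30, age_upper = 39, n = 6,
    height_mean = 158, height_sd = 0, weight_mean = 54, weight_sd = 0,
    ei_kj_mean = 7100, ei_kj_sd = 0, protein_g_mean = 62, protein_g_sd = 0,
    fat_g_mean = 56, fat_g_sd = 0, carbohydrate_g_mean = 225,
    carbohydrate_g_sd = 0, food_beverage_weight_mean = 1786,
    food_beverage_weight_sd = 0, beverage_fluid_ml = 1443)
  ind <- generate_individuals(spec, seed = 3)
  expect_equal(nrow(ind), 6)
  for (col in c("height_cm", "weight_kg", "protein_g", "fat_g",
                "carbohydrate_g", "food_beverage_weight_g")) {
    expect_equal(length(unique(ind[[col]])), 1)
  }
  expect_equal(ind$height_cm[1], 158)
  expect_equal(ind$weight_kg[1], 54)
  expect_true(all(ind$age >= 30 & ind$age < 40))
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_individuals(specs[["male.20-29"]], seed = 17)
  b <- generate_individuals(specs[["male.20-29"]], seed = 17)
  expect_identical(a, b)
  c <- generate_individuals(specs[["male.20-29"]], seed = 18)
  expect_false(identical(a, c))
  s1 <- scenario_reverse_u(seed = 5)
  s2 <- scenario_reverse_u(seed = 5)
  expect_identical(s1, s2)
})

test_that("generated records satisfy the subject-profile invariants", {
  for (nm in c("male.15-19", "female.>=70", "female.40-49")) {
    sp <- specs[[nm]]
    ind <- generate_individuals(sp, seed = 9)
    expect_true(all(ind$height_cm > 0))
    expect_true(all(ind$weight_kg > 0))
    expect_true(all(ind$ei_kj > 0))
    expect_true(all(ind$protein_g >= 0))
    expect_true(all(ind$fat_g >= 0))
    expect_true(all(ind$carbohydrate_g >= 0))
    expect_true(all(ind$alcohol_g >= 0))
    # energy accounting: reported energy stays within the noise band of the
    # macronutrient + alcohol energy (multiplicative CV 3%, 4 sigma guard)
    macro_kcal <- 4 * ind$protein_g + 9 * ind$fat_g +
      4 * ind$carbohydrate_g + 7 * ind$alcohol_g
    expect_true(all(abs(ind$ei_kj * 0.239 / macro_kcal - 1) < 0.15))
  }
})

test_that("aggregation inverts generation within sampling error", {
  spec <- specs[["male.15-19"]] # n = 559
  ind <- generate_individuals(spec, seed = 1)
  agg <- aggregate_individuals(ind)
  expect_equal(agg$n, spec$n)
  targets <- c(height = spec$height_mean, weight = spec$weight_mean,
               ei_kj = spec$ei_kj_mean, protein_g = spec$protein_g_mean,
               fat_g = spec$fat_g_mean,
               carbohydrate_g = spec$carbohydrate_g_mean,
               food_beverage_weight = spec$food_beverage_weight_mean)
  for (nm in names(targets)) {
    got <- agg[[paste0(nm, "_mean")]]
    se <- agg[[paste0(nm, "_sd")]] / sqrt(agg$n)
    expect_lt(abs(got - targets[[nm]]), 3 * se)
  }
})

test_that("aggregation handles single records and pooling identities", {
  one <- generate_individuals(specs[["female.30-39"]], seed = 2)[1, ]
  agg1 <- aggregate_individuals(one)
  expect_equal(agg1$n, 1)
  expect_equal(agg1$height_mean, one$height_cm)
  expect_equal(agg1$height_sd, 0)
  # pooling two equal-n sets: pooled mean is the average of the two means
  a <- generate_individuals(specs[["female.30-39"]], seed = 4)[1:50, ]
  b <- generate_individuals(specs[["female.30-39"]], seed = 5)[1:50, ]
  pooled <- aggregate_individuals(rbind(a, b))
  expect_equal(pooled$weight_mean,
               (mean(a$weight_kg) + mean(b$weight_kg)) / 2, tolerance = 1e-12)
  expect_error(aggregate_individuals(one[0, ]), "non-empty")
})

test_that("individual-level budgets aggregate to the group-mean budgets", {
  # near-linearity of the equations: per-group means of individual budgets
  # agree with the budget of the group means within 2%
  survey <- scenario_reverse_u(seed = 2)
  ind_budget <- suppressWarnings(compute_budget(survey))
  by_group <- aggregate(
    ind_budget[c("wt", "w_met", "w_res", "w_trans", "w_pre")],
    by = list(sex = ind_budget$sex, age_label = ind_budget$age_label),
    FUN = mean)
  gb <- suppressWarnings(estimate_group_budgets())
  m <- match(paste(by_group$sex, by_group$age_label),
             paste(gb$sex, gb$age_label))
  expect_false(anyNA(m))
  for (cc in c("wt", "w_met", "w_res", "w_trans")) {
    expect_true(all(abs(by_group[[cc]] - gb[[cc]][m]) / gb[[cc]][m] < 0.02))
  }
  # pre-formed water is a difference of close quantities, so the same
  # absolute gap is mechanically larger in relative terms
  expect_true(all(abs(by_group$w_pre - gb$w_pre[m]) / gb$w_pre[m] < 0.03))
})

test_that("an age-flat population with no equation curvature shows no non-linearity", {
  # negative control: constant anthropometrics and intakes across brackets,
  # and the quadratic age coefficient disabled so the generating truth is
  # genuinely linear in age (the default equation is itself quadratic in
  # age, so flat covariates alone cannot remove curvature)
  flat_spec <- function(lo, hi) {
    group_spec(sex = "female", age_lower = lo, age_upper = hi, n = 120,
               height_mean = 158, height_sd = 5, weight_mean = 54,
               weight_sd = 8, ei_kj_mean = 7100, ei_kj_sd = 1800,
               protein_g_mean = 62, protein_g_sd = 18, fat_g_mean = 56,
               fat_g_sd = 21, carbohydrate_g_mean = 225,
               carbohydrate_g_sd = 64, food_beverage_weight_mean = 1786,
               food_beverage_weight_sd = 569, beverage_fluid_ml = 1443)
  }
  los <- c(15, 20, 30, 40, 50, 60, 70)
  his <- c(19, 29, 39, 49, 59, 69, NA)
  fspecs <- Map(flat_spec, los, his)
  cfg <- default_run_config(coefficients = wt_coefficients(beta8_age2 = 0))
  p_vals <- vapply(1:10, function(s) {
    recs <- do.call(rbind, lapply(seq_along(fspecs), function(i) {
      generate_individuals(fspecs[[i]], seed = 1000 * s + i)
    }))
    bud <- suppressWarnings(compute_budget(recs, config = cfg))
    fit_spline(bud$wt, bud$age)$nonlinearity_p
  }, numeric(1))
  expect_lte(sum(p_vals < 0.05), 3)
})
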