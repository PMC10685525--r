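# Restricted cubic spline dose-response of water consumption against age.

#' Restricted cubic spline basis (3 knots)
#'
#' Builds the restricted (natural) cubic spline design for a three-knot
#' configuration: a linear column and one non-linear column, so the fitted
#' curve is cubic between the boundary knots and linear beyond them. The
#' non-linear column uses the standard truncated-power construction
#' normalised by the knot range,
#' \deqn{z(x) = \frac{(x-t_1)_+^3 - (x-t_2)_+^3 (t_3-t_1)/(t_3-t_2) +
#'   (x-t_3)_+^3 (t_2-t_1)/(t_3-t_2)}{(t_3-t_1)^2}.}
#' Default knots are at ages 18, 48 and 77 years (the 5th, 50th and 95th
#' percentiles of the survey age distribution).
#'
#' @param ages Numeric vector of ages, years.
#' @param knots Three strictly increasing knots.
#' @return Matrix with columns `age` and `age_rcs` (the non-linear term).
#' @examples
#' rcs_basis(c(18, 30, 50, 80))
#' @export
rcs_basis <- function(ages, knots = c(18, 48, 77)) {
  check_numeric(ages, "ages")
  check_numeric(knots, "knots")
  if (length(knots) != 3 || any(diff(knots) <= 0)) {
    stop_domain("'knots' must be 3 strictly increasing values")
  }
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  cube <- function(u) pmax(u, 0)^3
  z <- (cube(ages - t1) -
          cube(ages - t2) * (t3 - t1) / (t3 - t2) +
          cube(ages - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  cbind(age = ages, age_rcs = z)
}

#' Fit a restricted cubic spline dose-response model
#'
#' (Weighted) least-squares fit of an outcome on the three-knot restricted
#' cubic spline basis in age. With group-aggregate inputs the fit should be
#' weighted by group size (approximating the individual-level fit the
#' published analysis ran); with individual records it is unweighted.
#'
#' @param outcome Numeric outcome vector (e.g. water turnover, ml/day).
#' @param ages Ages, years (>= 4 distinct values).
#' @param weights Optional non-negative weights (group sizes).
#' @param knots Three strictly increasing knots; default `c(18, 48, 77)`.
#' @return An object of class `wt_rcs`: list with `knots`, `coefficients`,
#'   `covariance`, the underlying `lm` fit, `fitted_curve(age)` returning a
#'   data.frame of mean and pointwise 95\% confidence limits, and
#'   `nonlinearity_p` (Wald, see [test_nonlinearity()]).
#' @examples
#' b <- estimate_group_budgets()
#' men <- b[b$sex == "male", ]
#' fit <- fit_spline(men$wt, men$age, weights = men$n)
#' fit$fitted_curve(c(20, 50, 75))
#' @export
fit_spline <- function(outcome, ages, weights = NULL, knots = c(18, 48, 77)) {
  check_numeric(outcome, "outcome")
  check_numeric(ages, "ages")
  if (length(outcome) != length(ages)) {
    stop_domain("'outcome' and 'ages' differ in length")
  }
  if (length(unique(ages)) < 4) {
    stop_domain("need at least 4 distinct ages to fit the spline")
  }
  if (!is.null(weights)) check_numeric(weights, "weights", min = 0)
  basis <- rcs_basis(ages, knots)
  dat <- data.frame(y = outcome, age = basis[, "age"],
                    age_rcs = basis[, "age_rcs"])
  fit <- if (is.null(weights)) {
    lm(y ~ age + age_rcs, data = dat)
  } else {
    lm(y ~ age + age_rcs, data = dat, weights = weights)
  }
  if (any(!is.finite(coef(fit)))) {
    stop_domain("degenerate spline design (rank-deficient fit)")
  }
  V <- vcov(fit)
  cf <- coef(fit)
  fitted_curve <- function(age) {
    b <- rcs_basis(age, knots)
    X <- cbind(1, b)
    mean <- drop(X %*% cf)
    se <- sqrt(rowSums((X %*% V) * X))
    data.frame(age = age, mean = mean,
               lower95 = mean - 1.96 * se, upper95 = mean + 1.96 * se)
  }
  out <- structure(
    list(knots = knots, coefficients = cf, covariance = V, fit = fit,
         fitted_curve = fitted_curve, nonlinearity_p = NA_real_),
    class = "wt_rcs"
  )
  out$nonlinearity_p <- test_nonlinearity(out)
  out
}

#' @export
print.wt_rcs <- function(x, ...) {
  cat("Restricted cubic spline fit (3 knots at",
      paste(x$knots, collapse = ", "), "years)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("p for non-linearity (Wald): %.4g\n", x$nonlinearity_p))
  invisible(x)
}

#' Test non-linearity of the spline fit
#'
#' Tests that the non-linear spline coefficient is zero, i.e. that the
#' dose-response is a straight line. With three knots this is a 1-df test.
#' The primary method is the Wald test with the large-sample chi-square
#' reference; a likelihood-ratio variant comparing the spline model with the
#' nested linear model is provided as a cross-check (the two are
#' asymptotically equivalent).
#'
#' @param fit A `wt_rcs` object from [fit_spline()].
#' @param method `"wald"` (default) or `"lr"`.
#' @return p-value in \[0, 1\].
#' @export
test_nonlinearity <- function(fit, method = c("wald", "lr")) {
  method <- match.arg(method)
  if (!inherits(fit, "wt_rcs")) stop_domain("'fit' must be a wt_rcs object")
  if (method == "wald") {
    b <- fit$coefficients[["age_rcs"]]
    v <- fit$covariance["age_rcs", "age_rcs"]
    if (!is.finite(v) || v < 0) stop_domain("singular covariance matrix")
    if (v == 0) return(if (b == 0) 1 else 0)
    stat <- b^2 / v
    pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    full <- fit$fit
    dat <- full$model
    w <- full$weights
    reduced <- if (is.null(w)) {
      lm(y ~ age, data = dat)
    } else {
      lm(y ~ age, data = dat, weights = w)
    }
    rss1 <- sum(if (is.null(w)) residuals(full)^2 else
      w * residuals(full)^2)
    rss0 <- sum(if (is.null(w)) residuals(reduced)^2 else
      w * residuals(reduced)^2)
    n <- nrow(dat)
    if (rss1 <= 0) return(if (rss0 <= rss1 + 1e-12) 1 else 0)
    stat <- n * log(rss0 / rss1)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Linear trend test against age
#'
#' p-value of the age coefficient in a (weighted) linear regression of the
#' outcome on continuous age — the trend test reported alongside the
#' group-level comparisons.
#'
#' @param outcome Numeric outcome vector.
#' @param ages Ages, years (>= 3 points, not all equal).
#' @param weights Optional non-negative weights (group sizes).
#' @return List with `slope`, `se` and `p`.
#' @examples
#' test_linear_trend(c(10, 8, 5), c(20, 40, 60))
#' @export
test_linear_trend <- function(outcome, ages, weights = NULL) {
  check_numeric(outcome, "outcome")
  check_numeric(ages, "ages")
  if (length(outcome) != length(ages) || length(ages) < 3) {
    stop_domain("need >= 3 matching (outcome, age) points")
  }
  if (length(unique(ages)) < 2) stop_domain("ages are constant")
  if (!is.null(weights)) check_numeric(weights, "weights", min = 0)
  dat <- data.frame(y = outcome, age = ages)
  fit <- if (is.null(weights)) lm(y ~ age, data = dat) else
    lm(y ~ age, data = dat, weights = weights)
  sm <- summary(fit)$coefficients
  slope <- sm["age", "Estimate"]
  se <- sm["age", "Std. Error"]
  p <- sm["age", "Pr(>|t|)"]
  # exact-fit guard: with zero residual variance the t-statistic is 0/0 (or
  # pure floating-point noise), so decide on the slope's magnitude instead
  rss <- sum(residuals(fit)^2)
  if (!is.finite(p) || rss <= 1e-12 * max(mean(outcome^2), 1e-300)) {
    rise <- abs(slope) * diff(range(ages))
    p <- if (rise <= 1e-8 * max(1, mean(abs(outcome)))) 1 else 0
    if (p == 1) slope <- 0
  }
  list(slope = slope, se = se, p = p)
}

#' Export a fitted spline curve on an age grid
#'
#' Evaluates the fitted curve and confidence band on a regular age grid, the
#' shape used for plotting dose-response panels.
#'
#' @param fit A `wt_rcs` object.
#' @param from,to,by Age grid, years.
#' @return Data.frame with `age`, `mean`, `lower95`, `upper95`.
#' @export
spline_curve <- function(fit, from = 18, to = 77, by = 1) {
  if (!inherits(fit, "wt_rcs")) stop_domain("'fit' must be a wt_rcs object")
  fit$fitted_curve(seq(from, to, by = by))
}
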