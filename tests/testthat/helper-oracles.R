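# Independent one-line transcriptions of the published equations, kept
# deliberately separate from the package implementation so each side checks
# the other. Coefficients and constants are written out literally.

oracle_wt <- function(pal, weight, male, humidity, athlete, hdi_code,
                      altitude, age, temperature) {
  -713.1 + 1076 * pal + 14.34 * weight + 374.9 * male + 5.823 * humidity +
    1070 * athlete + 104.6 * hdi_code + 0.4726 * altitude +
    -0.3529 * age^2 + 24.78 * age + 1.865 * temperature^2 +
    -19.66 * temperature
}

oracle_wmet <- function(ei_kcal, pfat, ppro, pcarb, palc) {
  1000 * ei_kcal * (1 / 100000) *
    (0.119 * pfat + 0.103 * ppro + 0.150 * pcarb + 0.168 * palc)
}

oracle_wres <- function(ah, rco2_l) {
  1000 * (ah / 1000) * 0.035 * rco2_l
}

oracle_wtrans <- function(ah, bsa, clothing) {
  1000 * (0.18 * ah / 21.7) * clothing * bsa * 1.44
}

oracle_wpre <- function(wt, wmet, wres, wtrans) {
  wt - (wmet + wres + wtrans)
}

oracle_rco2 <- function(ei_kcal, fq) ei_kcal / (1.106 + (3.94 / fq))

oracle_bmr_kj <- function(w, h, a, s) {
  1000 * (0.1238 + 0.0481 * w + 0.0234 * h - 0.0138 * a - 0.5473 * s)
}

oracle_tetens_ah <- function(t, rh) {
  216.7 * (6.1078 * 10^(7.5 * t / (237.3 + t)) * rh / 100) / (t + 273.15)
}

# brute-force restricted cubic term: truncated cubics with the linearity
# constraints solved independently of the package's closed form
oracle_rcs_term <- function(x, k) {
  stopifnot(length(k) == 3)
  p <- function(u) ifelse(u > 0, u^3, 0)
  # coefficients of (x-k1)^3_+, (x-k2)^3_+, (x-k3)^3_+ with c1 = 1 and
  # linearity beyond k3: sum(ci) = 0 and sum(ci * ki) = 0
  c1 <- 1
  c2 <- -(k[3] - k[1]) / (k[3] - k[2])
  c3 <- (k[2] - k[1]) / (k[3] - k[2])
  (c1 * p(x - k[1]) + c2 * p(x - k[2]) + c3 * p(x - k[3])) / (k[3] - k[1])^2
}

# midpoint ages of the survey brackets, published-budget join helper
published_joined <- function() {
  groups <- nhns_groups()
  pub <- nhns_published_budget()
  merge(groups, pub, by = c("sex", "age_lower"), suffixes = c("", ".pub"))
}

random_physiological_inputs <- function(n, seed) {
  set.seed(seed)
  data.frame(
    pal = runif(n, 1.1, 2.5),
    weight = runif(n, 35, 120),
    male = sample(0:1, n, replace = TRUE),
    humidity = runif(n, 20, 100),
    athlete = sample(0:1, n, replace = TRUE),
    hdi = sample(0:2, n, replace = TRUE),
    altitude = runif(n, 0, 3000),
    age = runif(n, 18, 90),
    temperature = runif(n, -5, 35),
    ei_kcal = runif(n, 1200, 3500),
    fq = runif(n, 0.7, 1.0),
    ah = runif(n, 1, 25),
    bsa = runif(n, 1.3, 2.3),
    clothing = runif(n, 0.2, 1.0)
  )
}
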