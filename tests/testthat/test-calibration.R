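# brute-force definitional oracles for the statistics layer

ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  c(slope = slope, intercept = intercept)
}

pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

anova_oracle <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  c(ss_between = ss_b, ss_within = ss_w)
}

test_that("calibration fitting matches the normal equations", {
  expect_error(fit_calibration(1:2, c(2, 4)), "at least 3")
  expect_error(fit_calibration(rep(2, 4), 1:4), "degenerate")

  m <- fit_calibration(1:5, 2 * (1:5))
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 0, tolerance = 1e-14)
  expect_equal(m$r, 1)

  set.seed(3)
  x <- seq(1, 18, length.out = 8)
  y <- 0.069 * x - 0.005 + rnorm(8, 0, 0.002)
  m2 <- fit_calibration(x, y)
  oracle <- ols_oracle(x, y)
  expect_equal(m2$slope, oracle[["slope"]], tolerance = 1e-10)
  expect_equal(m2$intercept, oracle[["intercept"]], tolerance = 1e-10)
  expect_equal(m2$sigma_resid,
               sqrt(sum((y - oracle[["intercept"]] -
                           oracle[["slope"]] * x)^2) / 6),
               tolerance = 1e-10)
  expect_equal(predict_conc(m2, m2$intercept + m2$slope * 7), 7)
})

test_that("detection limits follow the 3.3/10 sigma-over-slope rule", {
  m <- fit_calibration(1:5, 2 * (1:5))
  m$sigma_resid <- 0.01
  m$slope <- 0.1
  expect_equal(lod_loq(m), c(lod = 0.33, loq = 1.0))

  # the LOQ/LOD ratio is 10/3.3 for every model
  set.seed(9)
  for (i in 1:5) {
    mm <- fit_calibration(1:6, 0.08 * (1:6) + rnorm(6, 0, 0.003))
    ll <- lod_loq(mm)
    expect_equal(ll[["loq"]] / ll[["lod"]], 10 / 3.3, tolerance = 1e-12)
  }
  m$slope <- 0
  expect_error(lod_loq(m), "zero slope")
})

test_that("recovery and dispersion summaries reproduce printed arithmetic", {
  expect_equal(recovery_percent(4, 4), 100)
  expect_error(recovery_percent(4, 0), "taken")

  # five published per-mixture recoveries for one method/analyte column
  ms <- mean_sd(c(99.96, 99.97, 99.58, 99.47, 98.69))
  expect_equal(round(ms[["mean"]], 2), 99.53)
  expect_equal(round(ms[["sd"]], 3), 0.522)

  expect_equal(mean_sd(rep(100, 5)), c(mean = 100, sd = 0))
  expect_error(mean_sd(numeric(0)), "empty")

  # %RSD round-trips with mean_sd
  set.seed(5)
  x <- rnorm(9, 100, 0.8)
  ms <- mean_sd(x)
  expect_equal(percent_rsd(x), 100 * ms[["sd"]] / ms[["mean"]])
})

test_that("standard addition recovers the added analyte", {
  sa <- standard_addition(4, 2, 6)
  expect_equal(sa$levels$recovery, 100)

  sa2 <- standard_addition(4, c(2, 4, 6), c(5.9, 8.1, 10.0))
  expect_equal(sa2$levels$recovery, c(95, 102.5, 100))
  expect_equal(round(sa2$mean, 2), 99.17)

  expect_error(standard_addition(4, c(0, 2), c(4, 6)), "added")
  expect_error(standard_addition(4, c(2, 4), 6), "length")
})

test_that("t/F comparison matches the definitional formulas", {
  a <- c(99.5, 100.2, 100.9)
  expect_error(two_sample_t_f(a, 100), "n >= 2")
  expect_error(two_sample_t_f(rep(1, 3), rep(1, 3)), "zero variance")

  # identical samples: t = 0, F = 1
  r0 <- two_sample_t_f(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$f, 1)
  expect_equal(r0$verdict, "no significant difference")

  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(3, 100, 1)
    y <- rnorm(3, 100.5, 1.5)
    r <- two_sample_t_f(x, y)
    expect_equal(r$t, pooled_t_oracle(x, y), tolerance = 1e-10)
    expect_equal(r$f, max(var(x), var(y)) / min(var(x), var(y)),
                 tolerance = 1e-10)
    expect_equal(r$t_df, 4)
  }
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  res <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$ss_between, 13.5)
  expect_equal(res$ss_within, 4)
  expect_equal(res$ss_total, 17.5)

  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(1:3, 5)), "n >= 2")

  # identical constant groups: F reported as undefined, with a flag
  flat <- one_way_anova(list(rep(2, 3), rep(2, 3)))
  expect_true(is.na(flat$f))
  expect_match(flat$flags, "identical")

  set.seed(21)
  for (i in 1:5) {
    groups <- lapply(1:4, function(k) rnorm(3, 100 + k / 10, 1))
    res <- one_way_anova(groups)
    oracle <- anova_oracle(groups)
    expect_equal(res$ss_between, oracle[["ss_between"]], tolerance = 1e-10)
    expect_equal(res$ss_within, oracle[["ss_within"]], tolerance = 1e-10)
    # eta-squared bounds and SS additivity
    expect_gte(res$eta_squared, 0)
    expect_lte(res$eta_squared, 1)
    expect_equal(res$ss_total, res$ss_between + res$ss_within,
                 tolerance = 1e-10)
    # the raw-data route equals the from-sums route on its own SS
    fs <- anova_from_sums(res$ss_between, res$df_between,
                          res$ss_within, res$df_within)
    expect_equal(fs$f, res$f, tolerance = 1e-12)
    expect_equal(fs$eta_squared, res$eta_squared, tolerance = 1e-12)
  }
})

test_that("from-sums ANOVA reproduces the published table rows", {
  h <- anova_from_sums(5.99, 3, 13.82, 8)
  expect_equal(round(h$f, 2), 1.16)
  expect_equal(round(h$eta_squared, 2), 0.30)

  t <- anova_from_sums(8.29, 3, 9.35, 8)
  expect_equal(round(t$f, 2), 2.36)
  expect_equal(round(t$eta_squared, 2), 0.47)

  u <- anova_from_sums(1, 1, 1, 1)
  expect_equal(u$f, 1)
  expect_equal(u$eta_squared, 0.5)

  expect_error(anova_from_sums(1, 0, 1, 1), "> 0")
})

test_that("critical values match the published 95% table entries", {
  expect_equal(round(f_critical(0.05, 3, 8), 2), 4.07)
  expect_equal(round(t_critical(0.05, 4), 2), 2.78)
  expect_error(t_critical(1.2, 4), "alpha")
  expect_error(f_critical(0.05, 0, 8), "df")

  # monotone decrease of the t critical value in df
  tc <- vapply(c(2, 4, 8, 16, 32, 120), function(df) t_critical(0.05, df),
               numeric(1))
  expect_true(all(diff(tc) < 0))
})
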