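# OLS calibration and the validation/statistics battery: recoveries,
# precision, standard addition, t/F comparison against a reference method,
# one-way ANOVA with eta-squared, and the ICH Q2(R1) LOD/LOQ convention.

#' Fit a straight-line calibration
#'
#' Ordinary least squares of signal on concentration. `r` is the Pearson
#' correlation between concentration and signal; `sigma_resid` is the
#' residual standard deviation on n - 2 degrees of freedom. LOD and LOQ
#' follow the ICH Q2(R1) convention `3.3 * sigma / |slope|` and
#' `10 * sigma / |slope|` (the published LOQ/LOD ratios of ~3.03 are
#' consistent with this choice).
#'
#' @param conc Concentrations in ug/mL (n >= 3, not all equal).
#' @param signal Measured signals (same length).
#' @param analyte,context Optional labels stored on the model.
#' @param wavelength Optional measurement wavelength (nm) stored on the model.
#' @return A `calibration_model`: slope, intercept, r, sigma_resid, n,
#'   range, lod, loq plus the labels.
#' @export
fit_calibration <- function(conc, signal, analyte = "", wavelength = NA_real_,
                            context = "") {
  if (length(conc) != length(signal))
    stop("conc and signal differ in length", call. = FALSE)
  n <- length(conc)
  if (n < 3) stop("calibration needs at least 3 points", call. = FALSE)
  if (var(conc) == 0)
    stop("degenerate design: concentrations all equal", call. = FALSE)
  fit <- lm(signal ~ conc)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  sigma_resid <- sqrt(sum(residuals(fit)^2) / (n - 2))
  r <- cor(conc, signal)
  model <- structure(
    list(slope = slope, intercept = intercept, r = r,
         sigma_resid = sigma_resid, n = n, range = range(conc),
         lod = NA_real_, loq = NA_real_,
         analyte = analyte, wavelength = wavelength, context = context),
    class = "calibration_model")
  if (slope != 0) {
    ll <- lod_loq(model)
    model$lod <- ll[["lod"]]
    model$loq <- ll[["loq"]]
  }
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s%s\n", x$analyte,
              if (nzchar(x$context)) paste0(" (", x$context, ")") else ""))
  cat(sprintf("  signal = %.6g * conc + %.6g   (n = %d, %g-%g ug/mL)\n",
              x$slope, x$intercept, x$n, x$range[1], x$range[2]))
  cat(sprintf("  r = %.4f, sigma_resid = %.3g, LOD = %.3g, LOQ = %.3g ug/mL\n",
              x$r, x$sigma_resid, x$lod, x$loq))
  invisible(x)
}

#' Detection and quantitation limits of a calibration
#'
#' `lod = 3.3 * sigma_resid / |slope|`, `loq = 10 * sigma_resid / |slope|`,
#' so `loq / lod = 10 / 3.3` identically.
#'
#' @param model A `calibration_model`.
#' @return Named numeric `c(lod = , loq = )` in ug/mL.
#' @export
lod_loq <- function(model) {
  if (model$slope == 0) stop("zero slope: LOD/LOQ undefined", call. = FALSE)
  c(lod = 3.3 * model$sigma_resid / abs(model$slope),
    loq = 10 * model$sigma_resid / abs(model$slope))
}

#' Invert a calibration: signal to concentration
#' @param model A `calibration_model`.
#' @param signal Signal value(s).
#' @return Concentration(s) in ug/mL.
#' @export
predict_conc <- function(model, signal) {
  (signal - model$intercept) / model$slope
}

#' Percentage recovery
#' @param found,taken Found and taken concentrations (ug/mL); `taken > 0`.
#' @return `100 * found / taken`.
#' @export
recovery_percent <- function(found, taken) {
  if (any(taken <= 0)) stop("taken must be > 0", call. = FALSE)
  100 * found / taken
}

#' Mean and sample standard deviation
#' @param values Non-empty numeric vector; sd uses the n - 1 denominator and
#'   is `NA` for a single value.
#' @return Named numeric `c(mean = , sd = )`.
#' @export
mean_sd <- function(values) {
  if (!length(values)) stop("empty value list", call. = FALSE)
  c(mean = mean(values),
    sd = if (length(values) >= 2) sd(values) else NA_real_)
}

#' Percentage relative standard deviation
#' @param values Numeric vector, n >= 2.
#' @return `100 * sd / mean`.
#' @export
percent_rsd <- function(values) {
  ms <- mean_sd(values)
  100 * ms[["sd"]] / ms[["mean"]]
}

#' Standard-addition recovery
#'
#' Recovery of the *added* analyte: `100 * (total_found_i - base_found) /
#' added_i` per spiking level, summarized as mean and %RSD.
#'
#' @param base_found Concentration found in the unspiked sample (ug/mL).
#' @param added Added concentrations (ug/mL, all > 0).
#' @param total_found Concentrations found after spiking (same length).
#' @return List with a per-level data frame (`added`, `total_found`,
#'   `recovery`) and `mean`, `sd`, `rsd` of the recoveries.
#' @export
standard_addition <- function(base_found, added, total_found) {
  if (length(added) != length(total_found))
    stop("added and total_found differ in length", call. = FALSE)
  if (any(added <= 0)) stop("added must be > 0", call. = FALSE)
  rec <- 100 * (total_found - base_found) / added
  ms <- mean_sd(rec)
  list(levels = data.frame(added = added, total_found = total_found,
                           recovery = rec),
       mean = ms[["mean"]], sd = ms[["sd"]],
       rsd = 100 * ms[["sd"]] / ms[["mean"]])
}

#' Two-sample t and F comparison
#'
#' Classic pooled-variance Student t (df = n_a + n_b - 2; Welch available via
#' `welch = TRUE`) plus the variance-ratio F with the larger variance in the
#' numerator, each with its two-sided (t) / upper-tail (F) critical value at
#' `alpha`. Verdict is "no significant difference" when both statistics fall
#' below their critical values.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch t-test instead of pooled variance.
#' @return List: `t`, `t_df`, `t_critical`, `f`, `f_df` (length 2),
#'   `f_critical`, `significant` (logical), `verdict`.
#' @export
two_sample_t_f <- function(a, b, alpha = 0.05, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0)
    stop("both samples have zero variance: t undefined", call. = FALSE)
  tt <- t.test(a, b, var.equal = !welch)
  t_stat <- unname(tt$statistic)
  t_df <- unname(tt$parameter)
  if (va >= vb) {
    f_stat <- if (vb > 0) va / vb else Inf
    f_df <- c(length(a) - 1L, length(b) - 1L)
  } else {
    f_stat <- vb / va
    f_df <- c(length(b) - 1L, length(a) - 1L)
  }
  t_crit <- t_critical(alpha, t_df)
  f_crit <- f_critical(alpha, f_df[1], f_df[2])
  sig <- abs(t_stat) >= t_crit || f_stat >= f_crit
  list(t = t_stat, t_df = t_df, t_critical = t_crit,
       f = f_stat, f_df = f_df, f_critical = f_crit,
       significant = sig,
       verdict = if (sig) "significant difference"
                 else "no significant difference")
}

#' One-way analysis of variance with effect size
#'
#' Between/within sums of squares, mean squares, F, p and eta-squared
#' (`SS_between / SS_total`). When every observation is identical both sums
#' of squares are zero and F is reported as `NA` with a flag rather than a
#' number.
#'
#' @param groups List (optionally named) of numeric vectors, >= 2 groups,
#'   each n >= 2.
#' @return List: `ss_between`, `df_between`, `ms_between`, `ss_within`,
#'   `df_within`, `ms_within`, `ss_total`, `f`, `p_value`, `eta_squared`,
#'   `flags`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  sm <- summary(aov(y ~ g))[[1]]
  ss_b <- sm[["Sum Sq"]][1]; df_b <- sm[["Df"]][1]
  ss_w <- sm[["Sum Sq"]][2]; df_w <- sm[["Df"]][2]
  flags <- character(0)
  if (ss_b + ss_w <= .Machine$double.eps * sum(y^2 + 1)) {
    f <- NA_real_; p <- NA_real_; eta <- NA_real_
    flags <- "all observations identical: F undefined"
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
    eta <- ss_b / (ss_b + ss_w)
  }
  list(ss_between = ss_b, df_between = df_b, ms_between = ss_b / df_b,
       ss_within = ss_w, df_within = df_w, ms_within = ss_w / df_w,
       ss_total = ss_b + ss_w, f = f, p_value = p, eta_squared = eta,
       flags = flags)
}

#' ANOVA summary quantities from printed sums of squares
#'
#' Recomputes mean squares, F, p and eta-squared from a published ANOVA
#' table's SS and df entries.
#'
#' @param ss_between,ss_within Sums of squares (>= 0).
#' @param df_between,df_within Degrees of freedom (> 0).
#' @return List: `ms_between`, `ms_within`, `f`, `p_value`, `eta_squared`.
#' @export
anova_from_sums <- function(ss_between, df_between, ss_within, df_within) {
  if (df_between <= 0 || df_within <= 0)
    stop("degrees of freedom must be > 0", call. = FALSE)
  if (ss_between < 0 || ss_within < 0)
    stop("sums of squares must be >= 0", call. = FALSE)
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  f <- ms_b / ms_w
  list(ms_between = ms_b, ms_within = ms_w, f = f,
       p_value = pf(f, df_between, df_within, lower.tail = FALSE),
       eta_squared = ss_between / (ss_between + ss_within))
}

#' Critical values of the t and F distributions
#'
#' `t_critical` is the two-sided quantile at level `alpha` (i.e.
#' `qt(1 - alpha/2, df)`); `f_critical` is the upper-tail quantile
#' `qf(1 - alpha, df1, df2)`.
#'
#' @param alpha Significance level in (0, 1).
#' @param df,df1,df2 Degrees of freedom, >= 1.
#' @return Critical value.
#' @export
t_critical <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  qt(1 - alpha / 2, df)
}

#' @rdname t_critical
#' @export
f_critical <- function(alpha, df1, df2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (df1 < 1 || df2 < 1) stop("df must be >= 1", call. = FALSE)
  qf(1 - alpha, df1, df2)
}
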