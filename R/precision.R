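## Scan-rescan precision and agreement statistics.

.check_pairs <- function(x1, x2, min_n = 2) {
  if (length(x1) != length(x2)) stop("pair vectors must have equal length", call. = FALSE)
  if (length(x1) < min_n)
    stop(sprintf("at least %d subjects are required", min_n), call. = FALSE)
  if (any(!is.finite(x1)) || any(!is.finite(x2))) stop("non-finite pair values", call. = FALSE)
  invisible(NULL)
}

## per-subject within-pair CVs of the RMS method
.pair_cv <- function(x1, x2) {
  m <- (x1 + x2) / 2
  if (any(m <= 0)) stop("pair means must be > 0 for a ratio-scale CoV", call. = FALSE)
  abs(x1 - x2) / (sqrt(2) * m)
}

#' Root-mean-square coefficient of variation with bootstrap
#'
#' Scan-rescan CoV by the RMS method: per subject,
#' `CV_i = |x1 - x2| / (sqrt(2) * pair mean)`; the reported CoV is
#' `100 * sqrt(mean(CV_i^2))`. Uncertainty by percentile bootstrap over
#' subjects.
#'
#' @param x1,x2 Paired measurements (scan 1, scan 2), natural units, > 0.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `"lv_cov"`: `cov_pct`, `ci` (low, high),
#'   `sd` (bootstrap SD), `n`, `n_boot`.
#' @export
cov_rms <- function(x1, x2, n_boot = 10000, seed = 1L, conf = 0.95) {
  .check_pairs(x1, x2, min_n = 1)
  cv <- .pair_cv(x1, x2)
  est <- 100 * sqrt(mean(cv^2))
  n <- length(cv)
  boots <- .with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    100 * sqrt(rowMeans(matrix(cv[idx]^2, nrow = n_boot)))
  })
  a <- (1 - conf) / 2
  structure(list(cov_pct = est,
                 ci = as.numeric(stats::quantile(boots, c(a, 1 - a), names = FALSE)),
                 sd = stats::sd(boots), n = n, n_boot = n_boot),
            class = "lv_cov")
}

#' @export
print.lv_cov <- function(x, ...) {
  cat(sprintf("RMS CoV %.2f%% (95%% CI %.2f-%.2f, bootstrap SD %.2f, n = %d)\n",
              x$cov_pct, x$ci[1], x$ci[2], x$sd, x$n))
  invisible(x)
}

#' Standard error of measurement and minimal detectable change
#'
#' SEM from paired differences, `sqrt(sum(d^2) / (2n))` (the within-subject
#' SD for two occasions); MDC is the 95% no-change band
#' `1.96 * SEM * sqrt(2)`.
#'
#' @param x1,x2 Paired measurements.
#' @return Named numeric vector `c(SEM =, MDC =)` in the metric's units.
#' @export
sem_mdc <- function(x1, x2) {
  .check_pairs(x1, x2)
  d <- x1 - x2
  sem <- sqrt(sum(d^2) / (2 * length(d)))
  c(SEM = sem, MDC = 1.96 * sem * sqrt(2))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Computed from the two-way ANOVA decomposition of the subjects x occasions
#' table.
#'
#' @param x1,x2 Paired measurements (n >= 3 subjects).
#' @return ICC value; attribute `degenerate` is TRUE (value NA) when the
#'   table has zero total variance.
#' @export
icc21 <- function(x1, x2) {
  .check_pairs(x1, x2)
  n <- length(x1)
  if (n < 3) stop("ICC(2,1) requires at least 3 subjects", call. = FALSE)
  k <- 2
  Y <- cbind(x1, x2)
  grand <- mean(Y)
  if (sum((Y - grand)^2) < 1e-24) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  ms_r <- k * sum((rowMeans(Y) - grand)^2) / (n - 1)          # subjects
  ms_c <- n * sum((colMeans(Y) - grand)^2) / (k - 1)          # occasions
  sse <- sum((Y - outer(rowMeans(Y), rep(1, k)) -
                outer(rep(1, n), colMeans(Y)) + grand)^2)
  ms_e <- sse / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  structure(icc, degenerate = FALSE)
}

#' Bootstrap comparison of two RMS CoVs on the same subjects
#'
#' Paired subject-level bootstrap of `delta = CoV_A - CoV_B`; the p-value is
#' the two-sided percentile probability of 0 under the bootstrap
#' distribution.
#'
#' @param a1,a2 Pairs for method A; `b1,b2` pairs for method B, same subjects
#'   in the same order.
#' @param b1,b2 See `a1`.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return List: `delta` (CoV_A - CoV_B, percentage points), `p` (two-sided),
#'   `ci` (percentile 95% CI of delta), `degenerate` (TRUE when n < 3).
#' @export
compare_cov <- function(a1, a2, b1, b2, n_boot = 10000, seed = 1L) {
  .check_pairs(a1, a2); .check_pairs(b1, b2)
  if (length(a1) != length(b1))
    stop("methods must be measured on the same subjects", call. = FALSE)
  cva <- .pair_cv(a1, a2); cvb <- .pair_cv(b1, b2)
  n <- length(cva)
  delta <- 100 * (sqrt(mean(cva^2)) - sqrt(mean(cvb^2)))
  boots <- .with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    100 * (sqrt(rowMeans(matrix(cva[idx]^2, nrow = n_boot))) -
             sqrt(rowMeans(matrix(cvb[idx]^2, nrow = n_boot))))
  })
  p <- min(1, 2 * min(mean(boots <= 0), mean(boots >= 0)))
  list(delta = delta, p = p,
       ci = as.numeric(stats::quantile(boots, c(0.025, 0.975), names = FALSE)),
       degenerate = n < 3)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`, reported at 4 decimal places.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  round(alpha / m, 4)
}

#' Paired-test sample size (normal approximation)
#'
#' Subjects needed to detect a mean paired difference `delta` given the SD of
#' paired differences, by the normal approximation
#' `n = ceil((z_{1-alpha/2} + z_{power})^2 * sd^2 / delta^2)`, floor 2.
#' `exact = TRUE` instead iterates the noncentral-t calculation
#' (`stats::power.t.test(type = "paired")`).
#'
#' @param sd_diff SD of paired differences (same units as `delta`).
#' @param delta Difference to detect (> 0).
#' @param alpha Two-sided type-I error rate.
#' @param power Target power (< 1).
#' @param exact Use the noncentral-t iteration instead.
#' @return Integer number of subjects.
#' @export
paired_sample_size <- function(sd_diff, delta, alpha = 0.05, power = 0.9,
                               exact = FALSE) {
  if (sd_diff <= 0 || alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("sd_diff must be > 0 and alpha, power in (0, 1)", call. = FALSE)
  if (delta == 0) stop("delta must be nonzero", call. = FALSE)
  if (exact) {
    n <- stats::power.t.test(delta = abs(delta), sd = sd_diff,
                             sig.level = alpha, power = power,
                             type = "paired")$n
    return(max(2L, as.integer(ceiling(n))))
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  max(2L, as.integer(ceiling(z^2 * sd_diff^2 / delta^2)))
}

#' Relative sample-size reduction from improved measurement error
#'
#' With a paired endpoint, required n scales with the squared SEM; a method
#' with smaller SEM needs `100 * (1 - (sem_new / sem_ref)^2)` percent fewer
#' subjects for the same power.
#'
#' @param sem_new,sem_ref Positive SEMs of the new and reference method.
#' @return Integer percent reduction.
#' @export
relative_sample_size <- function(sem_new, sem_ref) {
  if (sem_new <= 0 || sem_ref <= 0) stop("SEMs must be > 0", call. = FALSE)
  as.integer(round(100 * (1 - (sem_new / sem_ref)^2)))
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Observed versus chance-corrected agreement for a k x k contingency table
#' of two observers, with optional linear or quadratic disagreement
#' weighting (all weightings coincide for a binary table). The CI uses the
#' large-sample weighted-kappa standard error.
#'
#' @param tab k x k contingency table (observer 1 in rows, observer 2 in
#'   columns), counts.
#' @param weighting `"none"`, `"linear"` or `"quadratic"`.
#' @param conf Confidence level (default 0.95).
#' @return List: `kappa`, `se`, `ci`, `p_o`, `p_e`, `n`; `degenerate` TRUE
#'   (kappa NA) when chance agreement equals 1.
#' @export
cohen_kappa <- function(tab, weighting = c("none", "linear", "quadratic"),
                        conf = 0.95) {
  weighting <- match.arg(weighting)
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("table must be square", call. = FALSE)
  n <- sum(tab)
  if (n < 2) stop("at least 2 rated cases are required", call. = FALSE)
  k <- nrow(tab)
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / max(1, k - 1)
  W <- switch(weighting, none = (d == 0) * 1, linear = 1 - d, quadratic = 1 - d^2)
  P <- tab / n
  pr <- rowSums(P); pc <- colSums(P)
  p_o <- sum(W * P)
  p_e <- sum(W * outer(pr, pc))
  if (1 - p_e < 1e-12)
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                p_o = p_o, p_e = p_e, n = n, degenerate = TRUE))
  kap <- (p_o - p_e) / (1 - p_e)
  ## large-sample SE of (weighted) kappa
  wr <- as.numeric(W %*% pc)        # row-wise expected weights
  wc <- as.numeric(pr %*% W)        # column-wise expected weights
  term <- sum(P * (W - outer(wr, wc, "+") * (1 - kap))^2)
  v <- (term - (kap - p_e * (1 - kap))^2) / (n * (1 - p_e)^2)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(kappa = kap, se = se, ci = c(kap - z * se, kap + z * se),
       p_o = p_o, p_e = p_e, n = n, degenerate = FALSE)
}

#' Normal reference interval (mean +/- 2 SD)
#'
#' @param values Numeric sample (n >= 2).
#' @return Named numeric vector `mean`, `sd`, `lower`, `upper`.
#' @export
reference_interval <- function(values) {
  if (length(values) < 2) stop("at least 2 values are required", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  c(mean = m, sd = s, lower = m - 2 * s, upper = m + 2 * s)
}

#' Bland-Altman agreement analysis
#'
#' @param a,b Paired measurements of the same quantity by two methods.
#' @return List: `bias` (mean of a - b), `loa` (bias -/+ 1.96 SD of
#'   differences), `mean` and `diff` series for plotting.
#' @export
bland_altman <- function(a, b) {
  .check_pairs(a, b)
  d <- a - b
  s <- stats::sd(d)
  list(bias = mean(d), loa = mean(d) + c(-1.96, 1.96) * s,
       mean = (a + b) / 2, diff = d)
}

#' Scan-rescan precision report for one metric
#'
#' Bundles [cov_rms()], [sem_mdc()] and [icc21()] into one row mirroring a
#' test-retest precision table.
#'
#' @param x1,x2 Paired measurements.
#' @param n_boot,seed Bootstrap controls for the CoV.
#' @return One-row data frame: `CoV_pct`, `CoV_lo`, `CoV_hi`, `CoV_sd`,
#'   `SEM`, `MDC`, `ICC`.
#' @export
precision_report <- function(x1, x2, n_boot = 10000, seed = 1L) {
  cv <- cov_rms(x1, x2, n_boot = n_boot, seed = seed)
  sm <- sem_mdc(x1, x2)
  ic <- icc21(x1, x2)
  data.frame(CoV_pct = cv$cov_pct, CoV_lo = cv$ci[1], CoV_hi = cv$ci[2],
             CoV_sd = cv$sd, SEM = sm[["SEM"]], MDC = sm[["MDC"]],
             ICC = as.numeric(ic))
}
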