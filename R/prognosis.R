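## Univariable Cox proportional-hazards comparison of competing LV metrics.

#' Univariable Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ covariate` with Breslow tie handling and
#' collects the model-comparison statistics: likelihood-ratio chi-square
#' against the null, AIC, and Harrell's C-index of the linear predictor.
#'
#' @param records Data frame with columns `time` (> 0), `event` (0/1) and
#'   the covariate.
#' @param covariate Name of the covariate column.
#' @return An object of class `"lv_coxfit"`: `beta`, `se`, `hr`, `hr_ci`,
#'   `p` (Wald), `loglik`, `chisq` (LR vs null), `chisq_p`, `aic`, `c_index`,
#'   `n`, `n_events`, `covariate`, `flagged` (monotone-likelihood /
#'   non-convergence), plus the underlying `fit` and `records`.
#' @export
fit_cox <- function(records, covariate) {
  stopifnot(is.data.frame(records), covariate %in% names(records),
            all(c("time", "event") %in% names(records)))
  x <- records[[covariate]]
  if (sum(records$event) < 1) stop("no events in the records", call. = FALSE)
  if (stats::sd(x) == 0) stop("covariate is constant", call. = FALSE)
  flagged <- FALSE
  fml <- stats::as.formula(paste0("survival::Surv(time, event) ~ ", covariate))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "breslow"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  if (!is.finite(beta) || abs(beta) > 15) flagged <- TRUE
  chisq <- unname(2 * (fit$loglik[2] - fit$loglik[1]))
  ll <- fit$loglik[2]
  structure(list(beta = beta, se = se,
                 hr = exp(beta), hr_ci = exp(beta + c(-1.96, 1.96) * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = ll, chisq = chisq,
                 chisq_p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 aic = -2 * ll + 2 * 1,
                 c_index = c_index(records$time, records$event, beta * x),
                 n = nrow(records), n_events = sum(records$event),
                 covariate = covariate, flagged = flagged,
                 fit = fit, records = records),
            class = "lv_coxfit")
}

#' @export
print.lv_coxfit <- function(x, ...) {
  cat(sprintf("Cox PH fit: ~ %s  (n = %d, events = %d)%s\n",
              x$covariate, x$n, x$n_events,
              if (x$flagged) "  [flagged: convergence]" else ""))
  cat(sprintf("  beta %.4f  HR %.3f (95%% CI %.3f-%.3f)  p = %.3g\n",
              x$beta, x$hr, x$hr_ci[1], x$hr_ci[2], x$p))
  cat(sprintf("  LR chi2 %.1f  AIC %.1f  C-index %.3f\n",
              x$chisq, x$aic, x$c_index))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of comparable record pairs in which the higher risk score fails
#' earlier. A pair (i, j) is comparable when subject i has an event and
#' either `time_i < time_j`, or `time_i == time_j` with j censored. Tied
#' risk scores count 0.5.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param risk Risk scores (higher = predicted earlier failure).
#' @return C-index in [0, 1]; `NA` with attribute `degenerate = TRUE` when
#'   no comparable pairs exist.
#' @export
c_index <- function(time, event, risk) {
  stopifnot(length(time) == length(event), length(time) == length(risk))
  ev <- which(event == 1)
  conc <- 0; total <- 0
  for (i in ev) {
    comp <- time > time[i] | (time == time[i] & event == 0)
    comp[i] <- FALSE
    nc <- sum(comp)
    if (nc == 0) next
    total <- total + nc
    conc <- conc + sum(risk[i] > risk[comp]) + 0.5 * sum(risk[i] == risk[comp])
  }
  if (total == 0) return(structure(NA_real_, degenerate = TRUE))
  conc / total
}

#' Compare two univariable Cox fits of the same records
#'
#' Computes the deltas of the model-fit statistics (A minus B), applies the
#' decision rules (superior fit requires an AIC reduction greater than 4;
#' greater discrimination requires an absolute C-index difference of at
#' least 0.05), and bootstraps a two-sided p-value for the C-index
#' difference by subject resampling of the fitted linear predictors.
#'
#' @param fitA,fitB `"lv_coxfit"` objects fitted to identical records.
#' @param n_boot Bootstrap draws for the delta-C p-value (default 1000).
#' @param seed Integer seed.
#' @param aic_rule AIC reduction required to declare superior fit.
#' @param c_rule Absolute C-index difference required to declare greater
#'   discrimination.
#' @return An object of class `"lv_coxcomparison"`: `delta_chisq`,
#'   `delta_aic`, `delta_c`, `p_delta_c`, `verdict_fit`
#'   (`"A"`/`"B"`/`"none"`), `verdict_discrimination`.
#' @export
compare_models <- function(fitA, fitB, n_boot = 1000, seed = 1L,
                           aic_rule = 4, c_rule = 0.05) {
  stopifnot(inherits(fitA, "lv_coxfit"), inherits(fitB, "lv_coxfit"))
  if (fitA$n != fitB$n ||
      !isTRUE(all.equal(fitA$records$time, fitB$records$time)) ||
      !isTRUE(all.equal(fitA$records$event, fitB$records$event)))
    stop("fits must be on identical records", call. = FALSE)
  d_chi <- fitA$chisq - fitB$chisq
  d_aic <- fitA$aic - fitB$aic
  d_c <- fitA$c_index - fitB$c_index
  tm <- fitA$records$time; evt <- fitA$records$event
  ra <- fitA$beta * fitA$records[[fitA$covariate]]
  rb <- fitB$beta * fitB$records[[fitB$covariate]]
  n <- length(tm)
  boots <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    c_index(tm[idx], evt[idx], ra[idx]) - c_index(tm[idx], evt[idx], rb[idx])
  }, numeric(1)))
  boots <- boots[is.finite(boots)]
  p_c <- if (length(boots)) min(1, 2 * min(mean(boots <= 0), mean(boots >= 0))) else NA_real_
  verdict_fit <- if (d_aic < -aic_rule) "A" else if (d_aic > aic_rule) "B" else "none"
  verdict_disc <- if (is.na(d_c) || abs(d_c) < c_rule) "none" else if (d_c > 0) "A" else "B"
  structure(list(delta_chisq = d_chi, delta_aic = d_aic, delta_c = d_c,
                 p_delta_c = p_c, verdict_fit = verdict_fit,
                 verdict_discrimination = verdict_disc,
                 aic_rule = aic_rule, c_rule = c_rule),
            class = "lv_coxcomparison")
}

#' @export
print.lv_coxcomparison <- function(x, ...) {
  cat("Cox model comparison (A - B)\n")
  cat(sprintf("  delta chi2 %.2f  delta AIC %.2f  delta C %.4f (bootstrap p = %.3g)\n",
              x$delta_chisq, x$delta_aic, x$delta_c, x$p_delta_c))
  cat(sprintf("  superior fit: %s (|dAIC| > %g)  greater discrimination: %s (|dC| >= %g)\n",
              x$verdict_fit, x$aic_rule, x$verdict_discrimination, x$c_rule))
  invisible(x)
}

#' Global Schoenfeld proportional-hazards test
#'
#' Score test of zero correlation between the scaled Schoenfeld residuals
#' and Kaplan-Meier-transformed event time (the global test of
#' [survival::cox.zph()]).
#'
#' @param fit An `"lv_coxfit"`.
#' @return Global test p-value; `NA` with attribute `degenerate = TRUE` when
#'   fewer than 2 events are available.
#' @export
schoenfeld_global <- function(fit) {
  stopifnot(inherits(fit, "lv_coxfit"))
  if (fit$n_events < 2) return(structure(NA_real_, degenerate = TRUE))
  z <- survival::cox.zph(fit$fit, transform = "km", global = TRUE)
  unname(z$table["GLOBAL", "p"])
}

#' Reclassification across EF treatment thresholds
#'
#' Counts subjects classified differently by two ejection-fraction
#' measurements at each clinical threshold.
#'
#' @param efA,efB Per-subject EF (%) by the two methods, equal length.
#' @param thresholds EF cutoffs, % (defaults 35 and 50).
#' @return Data frame: `threshold`, `below_A`, `below_B`, `reclassified`.
#' @export
ef_reclassification <- function(efA, efB, thresholds = c(35, 50)) {
  if (length(efA) != length(efB))
    stop("EF vectors must have equal length", call. = FALSE)
  do.call(rbind, lapply(thresholds, function(t) {
    a <- efA < t; b <- efB < t
    data.frame(threshold = t, below_A = sum(a), below_B = sum(b),
               reclassified = sum(xor(a, b)))
  }))
}
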