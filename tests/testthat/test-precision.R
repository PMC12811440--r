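test_that("RMS CoV: degenerate and hand-computed cases", {
  z <- cov_rms(c(100, 100, 100), c(100, 100, 100), n_boot = 200, seed = 1)
  expect_equal(z$cov_pct, 0)
  expect_equal(z$ci, c(0, 0))

  # single informative pair: CV = |100 - 110| / (sqrt(2) * 105)
  s <- cov_rms(100, 110, n_boot = 100, seed = 1)
  expect_equal(s$cov_pct, 100 * 10 / (sqrt(2) * 105), tolerance = 1e-12)
  expect_equal(round(s$cov_pct, 2), 6.73)

  expect_error(cov_rms(c(1, 2), c(-3, 2), n_boot = 10), "> 0")
})

test_that("CoV is scale-invariant and order-invariant; SEM scales linearly", {
  set.seed(2)
  x1 <- rlnorm(40, log(100), 0.2); x2 <- x1 * rlnorm(40, 0, 0.05)
  a <- cov_rms(x1, x2, n_boot = 500, seed = 3)
  b <- cov_rms(7 * x1, 7 * x2, n_boot = 500, seed = 3)
  expect_equal(a$cov_pct, b$cov_pct, tolerance = 1e-12)
  expect_equal(a$ci, b$ci, tolerance = 1e-12)
  o <- sample(40)
  c_ <- cov_rms(x1[o], x2[o], n_boot = 500, seed = 3)
  expect_equal(a$cov_pct, c_$cov_pct, tolerance = 1e-12)

  sm <- sem_mdc(x1, x2); sm7 <- sem_mdc(7 * x1, 7 * x2)
  expect_equal(7 * sm[["SEM"]], sm7[["SEM"]], tolerance = 1e-12)
  expect_equal(sm[["MDC"]], 1.96 * sqrt(2) * sm[["SEM"]], tolerance = 1e-15)
})

test_that("bootstrap is reproducible bit-exactly under a fixed seed", {
  set.seed(4)
  x1 <- rlnorm(30, log(120), 0.15); x2 <- x1 * rlnorm(30, 0, 0.04)
  a <- cov_rms(x1, x2, n_boot = 1000, seed = 11)
  b <- cov_rms(x1, x2, n_boot = 1000, seed = 11)
  expect_identical(a, b)
})

test_that("SEM from paired differences: closed-form cases", {
  expect_equal(sem_mdc(c(5, 5), c(5, 5))[["MDC"]], 0)
  # pairs engineered to have SEM exactly 7.6
  s <- 7.6
  sm <- sem_mdc(c(100, 100), c(100 - 2 * s, 100))
  expect_equal(sm[["SEM"]], s, tolerance = 1e-12)
  expect_equal(round(sm[["MDC"]], 1), 21.1)
})

test_that("ICC(2,1) matches the two-way ANOVA oracle on a small fixture", {
  x1 <- c(10.1, 12.3, 9.8, 14.2, 11.0, 13.5)
  x2 <- c(10.4, 12.0, 10.1, 13.8, 11.4, 13.1)
  expect_equal(as.numeric(icc21(x1, x2)), icc21_aov(x1, x2), tolerance = 1e-10)
  # identical pairs with between-subject spread: perfect agreement
  expect_equal(as.numeric(icc21(x1, x1)), 1)
  # zero total variance flags degenerate
  z <- icc21(rep(3, 5), rep(3, 5))
  expect_true(attr(z, "degenerate"))
  expect_error(icc21(c(1, 2), c(1, 2)), "3 subjects")
})

test_that("ICC of pure noise is near zero", {
  set.seed(5)
  x1 <- rnorm(500); x2 <- rnorm(500)
  expect_lt(abs(as.numeric(icc21(x1, x2))), 0.1)
})

test_that("CoV comparison: identity gives p = 1; reordering both is invariant", {
  set.seed(6)
  x1 <- rlnorm(50, log(100), 0.2); x2 <- x1 * rlnorm(50, 0, 0.05)
  cmp <- compare_cov(x1, x2, x1, x2, n_boot = 500, seed = 7)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p, 1)
  expect_error(compare_cov(x1, x2, x1[1:10], x2[1:10]), "same subjects")
  tiny <- compare_cov(c(10, 11), c(10.5, 10.9), c(10, 11), c(10.2, 11.3),
                      n_boot = 100, seed = 1)
  expect_true(tiny$degenerate)
})

test_that("CoV comparison detects a genuine precision difference", {
  set.seed(8)
  hits <- 0
  for (r in 1:15) {
    m <- rlnorm(200, log(100), 0.2)
    a1 <- m * rlnorm(200, 0, 0.10); a2 <- m * rlnorm(200, 0, 0.10)
    b1 <- m * rlnorm(200, 0, 0.05); b2 <- m * rlnorm(200, 0, 0.05)
    cmp <- compare_cov(a1, a2, b1, b2, n_boot = 400, seed = r)
    if (cmp$p < 0.05 && cmp$delta > 0) hits <- hits + 1
  }
  expect_gte(hits, 13)
})

test_that("Bonferroni threshold and sample-size calculators", {
  expect_equal(bonferroni_threshold(0.05, 15), 0.0033)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "m")

  expect_equal(paired_sample_size(3, 1, 0.05, 0.9), 95L)
  # (1.95996 + 1.28155)^2 = 10.507 -> ceil(10.507 * 9 / 9) = 11
  expect_equal(paired_sample_size(3, 3, 0.05, 0.9), 11L)
  expect_equal(paired_sample_size(3, 1000, 0.05, 0.9), 2L)
  expect_error(paired_sample_size(3, 0), "delta")
  # exact noncentral-t iteration gives a slightly larger n
  expect_gte(paired_sample_size(3, 1, 0.05, 0.9, exact = TRUE), 95L)

  expect_equal(relative_sample_size(2.7, 3.4), 37L)
  expect_equal(relative_sample_size(2, 2), 0L)
  expect_equal(relative_sample_size(1, 2), 75L)
  expect_error(relative_sample_size(0, 1), "> 0")
})

test_that("Cohen's kappa: agreement tables and weighting", {
  tab <- matrix(c(10, 3, 2, 518), 2, 2)      # a, c, b, d (column-major)
  k <- cohen_kappa(tab)
  expect_equal(round(k$kappa, 2), 0.8)
  # binary table: all weightings coincide
  expect_equal(cohen_kappa(tab, "linear")$kappa, k$kappa, tolerance = 1e-12)
  expect_equal(cohen_kappa(tab, "quadratic")$kappa, k$kappa, tolerance = 1e-12)
  # transposing observers leaves kappa unchanged
  expect_equal(cohen_kappa(t(tab))$kappa, k$kappa, tolerance = 1e-12)
  # perfect agreement
  expect_equal(cohen_kappa(diag(c(20, 30)))$kappa, 1)
  # degenerate marginals: everyone in one cell
  z <- cohen_kappa(matrix(c(50, 0, 0, 0), 2, 2))
  expect_true(z$degenerate)
  expect_error(cohen_kappa(matrix(1, 2, 3)), "square")
})

test_that("kappa CI behaves like a large-sample interval", {
  set.seed(9)
  # simulate tables from a known-agreement process and check CI coverage
  hits <- 0
  for (r in 1:40) {
    a <- simulate_error_audit(600, 0.1, 0.8, seed = r)
    tab <- table(factor(a[, 1], 0:1), factor(a[, 2], 0:1))
    k <- cohen_kappa(tab)
    # true kappa for the miss-only observer model, computed from the
    # generative probabilities
    eps <- 0.1 # (1 - 0.8) / 2
    p11 <- 0.1 * (1 - eps)^2; p10 <- 0.1 * eps * (1 - eps)
    po <- p11 + (1 - 0.1) + 0.1 * eps^2
    pm <- p11 + p10
    pe <- pm^2 + (1 - pm)^2
    ktrue <- (po - pe) / (1 - pe)
    if (ktrue >= k$ci[1] && ktrue <= k$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 32)
})

test_that("reference intervals are mean +/- 2 SD", {
  v <- c(124 - 20.5 / sqrt(2), 124 + 20.5 / sqrt(2))
  ri <- reference_interval(v)
  expect_equal(ri[["mean"]], 124)
  expect_equal(ri[["sd"]], 20.5, tolerance = 1e-12)
  expect_equal(round(ri[["upper"]]), 165)
  ri0 <- reference_interval(c(7, 7, 7))
  expect_equal(ri0[["lower"]], ri0[["upper"]])
  set.seed(10)
  rin <- reference_interval(rnorm(1e5))
  expect_lt(abs(rin[["lower"]] + 2), 0.05)
  expect_lt(abs(rin[["upper"]] - 2), 0.05)
})

test_that("Bland-Altman bias and limits of agreement", {
  a <- c(10, 12, 14, 16)
  expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(bland_altman(a, a)$loa, c(0, 0))
  ba <- bland_altman(a + 5, a)
  expect_equal(ba$bias, 5)
  expect_equal(diff(ba$loa), 0)
  expect_equal(ba$diff, rep(5, 4))
})

test_that("bootstrap CoV covers a known within-subject CV", {
  set.seed(12)
  hits <- 0
  for (r in 1:25) {
    m <- rlnorm(200, log(100), 0.25)
    sdl <- 0.05
    x1 <- m * rlnorm(200, 0, sdl); x2 <- m * rlnorm(200, 0, sdl)
    z <- cov_rms(x1, x2, n_boot = 500, seed = r)
    true_cov <- 100 * sqrt(exp(sdl^2 * 2) - 1) / sqrt(2) # paired lognormal CV
    if (true_cov >= z$ci[1] && true_cov <= z$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 21)
})
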