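# shared fixtures and independent oracles used across test files

# default phantom at a truth resolution that keeps the suite fast; the
# oracle-convergence test itself checks 0.5 mm vs 0.25 mm
fast_spec <- function(...) phantom_spec(truth_res_mm = 0.5, ...)

# noiseless two-level disk: blood 0.9 inside r_blood, myocardium 0.3 in the
# shell to r_myo, background 0.05; optional dark papillary spot
disk_image <- function(n = 160, r_blood = 20, r_myo = 30,
                       spot_centre = NULL, spot_r = 3) {
  ctr <- (n + 1) / 2
  px <- rep(seq_len(n), times = n); py <- rep(seq_len(n), each = n)
  r <- sqrt((px - ctr)^2 + (py - ctr)^2)
  img <- matrix(0.05, n, n)
  img[r <= r_myo] <- 0.3
  img[r <= r_blood] <- 0.9
  if (!is.null(spot_centre)) {
    rs <- sqrt((px - spot_centre[1])^2 + (py - spot_centre[2])^2)
    img[rs <= spot_r] <- 0.3
  }
  img
}

disk_labels <- function(n = 160, r_blood = 20, r_myo = 30) {
  ctr <- (n + 1) / 2
  px <- rep(seq_len(n), times = n); py <- rep(seq_len(n), each = n)
  r <- sqrt((px - ctr)^2 + (py - ctr)^2)
  lab <- matrix(0L, n, n)
  lab[r <= r_myo] <- 2L
  lab[r <= r_blood] <- 1L
  lab
}

# random rigid transform (rotation + translation) for equivariance checks
random_rigid <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(A)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 50))
}
apply_rigid <- function(tf, x) {
  if (is.matrix(x)) t(tf$R %*% t(x) + tf$t) else as.numeric(tf$R %*% x + tf$t)
}
rigid_plane <- function(tf, p) {
  plane(apply_rigid(tf, p$origin),
        as.numeric(tf$R %*% p$axes[, 1]),
        as.numeric(tf$R %*% p$axes[, 2]))
}

# independent Breslow partial log-likelihood (used as a grid-search oracle
# for the Cox fit); written from the definition, no survival-package code
breslow_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
  }
  ll
}

# exhaustive Harrell concordance enumeration (pair loop, oracle form)
c_index_bruteforce <- function(time, event, risk) {
  conc <- 0; total <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- time[j] > time[i] || (time[j] == time[i] && event[j] == 0)
      if (!comparable) next
      total <- total + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / total
}

# two-way ANOVA variance-components ICC(2,1) via stats::aov (oracle route)
icc21_aov <- function(x1, x2) {
  n <- length(x1)
  d <- data.frame(y = c(x1, x2),
                  subj = factor(rep(seq_len(n), 2)),
                  occ = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subj + occ, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]; msc <- tab["occ", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}
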