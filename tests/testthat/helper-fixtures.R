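# Fixtures and independent oracles used across the suite. Everything is
# built in code at test time.

default_geometry <- function(sectors_per_slice = 12, n_slices = 3) {
  list(slice = rep(c("basal", "mid", "apical")[seq_len(n_slices)],
                   each = sectors_per_slice),
       angle = rep(seq(0, 360 - 360 / sectors_per_slice,
                       by = 360 / sectors_per_slice) +
                     180 / sectors_per_slice, n_slices))
}

# one shortening-reshortening curve sampled on the frame grid
ref_curve <- function(onset_ms = 0, n_frames = 30, dt = 17,
                      peak = -0.15) {
  crtcmr:::ecc_waveform((seq_len(n_frames) - 1) * dt, onset_ms, peak,
                        150, 200, 0.35)
}

# strain matrix with the same curve in every sector
uniform_strain <- function(onset_ms = 34, n_frames = 30, dt = 17) {
  g <- default_geometry()
  curve <- ref_curve(onset_ms, n_frames, dt)
  strain_matrix(matrix(rep(curve, each = length(g$slice)),
                       length(g$slice), n_frames),
                dt, g$slice, g$angle)
}

# strain matrix with per-sector onsets given as a vector (ms)
onset_strain <- function(onsets_ms, n_frames = 30, dt = 17) {
  g <- default_geometry()
  stopifnot(length(onsets_ms) == length(g$slice))
  M <- t(vapply(onsets_ms, ref_curve, numeric(n_frames),
                n_frames = n_frames, dt = dt))
  strain_matrix(M, dt, g$slice, g$angle)
}

random_strain <- function() {
  g <- default_geometry()
  n <- length(g$slice)
  M <- matrix(stats::runif(n * 30, -0.4, 0.2), n, 30)
  strain_matrix(M, 17, g$slice, g$angle)
}

# --- oracles -------------------------------------------------------------

# frame-wise spatial Fourier powers on the rank-1 reconstruction,
# combined by the same sqrt(sum A0 / sum(A0 + A1)) formula
cure_framewise_oracle <- function(strain) {
  sv <- svd(strain$ecc)
  M1 <- sv$d[1] * sv$u[, 1] %o% sv$v[, 1]
  a0 <- 0; a1 <- 0
  for (s in unique(strain$geometry$slice)) {
    idx <- which(strain$geometry$slice == s)
    idx <- idx[order(strain$geometry$angle_deg[idx])]
    for (t in seq_len(ncol(M1))) {
      X <- stats::fft(M1[idx, t])
      a0 <- a0 + Mod(X[1])^2
      a1 <- a1 + Mod(X[2])^2
    }
  }
  sqrt(a0 / (a0 + a1))
}

# brute-force Youden scan by direct confusion-count arithmetic
youden_bruteforce <- function(values, outcome, step) {
  cuts <- seq(step, max(values), by = step)
  best <- NULL
  for (cc in cuts) {
    tp <- sum(values >= cc & outcome == 1)
    fn <- sum(values < cc & outcome == 1)
    tn <- sum(values < cc & outcome == 0)
    fp <- sum(values >= cc & outcome == 0)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (is.null(best) || j > best$J + 1e-12) best <- list(cutoff = cc, J = j)
  }
  best
}

# Newton-Raphson maximum likelihood for logistic regression
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  X1 <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X1))
  for (i in seq_len(maxit)) {
    p <- stats::plogis(drop(X1 %*% beta))
    W <- p * (1 - p)
    step <- solve(crossprod(X1, X1 * W), crossprod(X1, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# censored Gaussian log-likelihood and an iteratively refined grid search
cg_loglik <- function(b0, b1, log_s, time, event, x) {
  mu <- b0 + b1 * x
  s <- exp(log_s)
  sum(ifelse(event == 1,
             stats::dnorm(time, mu, s, log = TRUE),
             stats::pnorm(time, mu, s, lower.tail = FALSE, log.p = TRUE)))
}

cg_gridsearch <- function(time, event, x, rounds = 6, width0 = c(6, 6, 2)) {
  ctr <- c(mean(time), 0, log(stats::sd(time)))
  w <- width0
  for (r in seq_len(rounds)) {
    g0 <- seq(ctr[1] - w[1], ctr[1] + w[1], length.out = 15)
    g1 <- seq(ctr[2] - w[2], ctr[2] + w[2], length.out = 15)
    g2 <- seq(ctr[3] - w[3], ctr[3] + w[3], length.out = 15)
    best <- -Inf
    for (a in g0) for (b in g1) for (s in g2) {
      ll <- cg_loglik(a, b, s, time, event, x)
      if (ll > best) { best <- ll; ctr <- c(a, b, s) }
    }
    w <- w / 6
  }
  list(coef = ctr[1:2], scale = exp(ctr[3]), loglik = best)
}

# Efron partial likelihood for a single covariate
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D]) -
      sum(log(sR - (seq_len(d) - 1) / d * sD))
  }
  ll
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_enum_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand product-limit estimator (reverse KM: censoring as the event)
reverse_km_oracle <- function(time, event) {
  cens <- 1 - event
  tt <- sort(unique(time[cens == 1]))
  S <- 1
  med <- NA_real_
  for (t in tt) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & cens == 1)
    S <- S * (1 - d / at_risk)
    if (is.na(med) && S <= 0.5) med <- t
  }
  med
}

# small mediation test cohort (groups 1 and 2 only)
two_arm_cohort <- function(n_per_arm, seed = NULL, ...) {
  cfg <- cohort_gen_config(n_per_group = c(n_per_arm, n_per_arm, 0L),
                           seed = seed, ...)
  coh <- generate_outcomes(generate_clinical_cohort(cfg), cfg)
  coh$exposure <- as.integer(coh$group == 2)
  coh
}
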