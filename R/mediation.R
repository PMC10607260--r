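#' Censored Gaussian regression of survival time
#'
#' Fits a parametric survival model with a Gaussian distribution on the
#' (untransformed) time scale: the latent survival time is linear in the
#' covariates with normal errors, deaths contribute density terms to the
#' likelihood and censored observations upper-tail survival terms, and
#' the scale parameter is estimated jointly. The fit is delegated to
#' [survival::survreg()] with `dist = "gaussian"` (or `"lognormal"` when
#' `log_time = TRUE`). With zero censoring the likelihood reduces to
#' ordinary least squares.
#'
#' @param time observed times (death or censoring).
#' @param event event indicator (1 = death, 0 = censored).
#' @param X covariate matrix or data.frame.
#' @param log_time model `log(time)` instead of time (off by default).
#' @return object of class `"cens_gaussian_fit"`: `coef`, `se`, `scale`,
#'   `loglik`, `converged`, `fit`.
#' @export
fit_censored_gaussian_regression <- function(time, event, X,
                                             log_time = FALSE) {
  event <- as.integer(event)
  if (!all(event %in% c(0, 1))) stop("'event' must be 0/1")
  if (any(!is.finite(time))) stop("'time' must be finite")
  if (all(event == 0))
    stop("all observations censored: scale parameter not identifiable")
  X <- as.data.frame(X)
  df <- cbind(.time = time, .event = event, X)
  dist <- if (log_time) "lognormal" else "gaussian"
  fit <- survival::survreg(survival::Surv(.time, .event) ~ ., data = df,
                           dist = dist,
                           control = survival::survreg.control(
                             maxiter = 100, rel.tolerance = 1e-10))
  conv <- is.null(fit$fail)
  if (!conv)
    warning("censored Gaussian fit did not converge: ", fit$fail)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[seq_along(cf)]
  structure(list(coef = cf, se = se, scale = fit$scale,
                 loglik = fit$loglik[2], converged = conv, fit = fit,
                 log_time = log_time),
            class = "cens_gaussian_fit")
}

#' @export
print.cens_gaussian_fit <- function(x, ...) {
  cat("Censored Gaussian survival regression",
      if (x$log_time) "(log-time scale)", "\n")
  print(data.frame(coef = x$coef, se = x$se), digits = 4)
  cat(sprintf("  scale = %.4g, loglik = %.2f\n", x$scale, x$loglik))
  invisible(x)
}

#' Average causal mediation effect (product of coefficients)
#'
#' @param a exposure-to-mediator regression coefficient.
#' @param b mediator-to-outcome regression coefficient (from the outcome
#'   model adjusted for exposure).
#' @return the product `a * b`.
#' @export
acme_point <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) stop("'a' and 'b' must be finite")
  a * b
}

#' Proportion of the total effect transmitted through the mediator
#'
#' `acme / total`. When the mediated and total effects have opposite
#' signs, or the ratio falls outside \[0, 1\], the value is reported
#' verbatim with an `"inconsistent"` attribute set to `TRUE`
#' (inconsistent mediation).
#'
#' @param acme average causal mediation effect.
#' @param total total effect of the exposure on the outcome.
#' @return numeric proportion with attribute `inconsistent`.
#' @export
proportion_mediated <- function(acme, total) {
  if (!is.finite(acme) || !is.finite(total)) stop("inputs must be finite")
  if (total == 0) stop("total effect is zero: proportion undefined")
  p <- acme / total
  attr(p, "inconsistent") <- p < 0 || p > 1
  p
}

#' Bootstrapped causal mediation of a group effect on survival time
#'
#' Implements the product-of-coefficients mediation analysis for a
#' censored survival outcome: the mediator is regressed on the binary
#' exposure by ordinary least squares (path `a`), survival time is
#' regressed on exposure and mediator by censored Gaussian regression
#' (mediator path `b` and direct effect), and the total effect is the
#' exposure coefficient of the outcome model without the mediator. The
#' ACME is `a * b`; inference is by nonparametric patient-level
#' resampling with percentile confidence intervals. Bootstrap replicates
#' in which only one exposure class is drawn are redrawn (counted; a
#' warning is raised if more than 10% of replicates needed a redraw).
#'
#' @param data data.frame containing the analysis columns.
#' @param exposure name of the binary (0/1) exposure column.
#' @param mediator name of the mediator column (e.g. creatinine, mg/dL).
#' @param time,event names of the survival time (years) and event
#'   columns.
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level for percentile intervals.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @param log_time passed to [fit_censored_gaussian_regression()].
#' @return object of class `"mediation_result"` with point estimates
#'   (`a`, `b`, `acme`, `total`, `direct`, `prop_mediated`), percentile
#'   CIs, bootstrap p-values, the bootstrap draws, and the redraw count.
#' @export
bootstrap_mediation <- function(data, exposure, mediator,
                                time = "time_years", event = "event",
                                n_boot = 1000L, conf = 0.95, seed = NULL,
                                log_time = FALSE) {
  if (n_boot < 1) stop("'n_boot' must be >= 1")
  for (col in c(exposure, mediator, time, event))
    if (!col %in% names(data)) stop("column not found: ", col)
  x <- as.numeric(data[[exposure]])
  if (!all(x %in% c(0, 1)) || length(unique(x)) < 2)
    stop("'exposure' must be binary 0/1 with both classes present")
  if (!is.null(seed)) set.seed(seed)

  fit_paths <- function(d) {
    a <- unname(stats::coef(stats::lm(d[[mediator]] ~ d[[exposure]]))[2])
    out <- fit_censored_gaussian_regression(
      d[[time]], d[[event]],
      stats::setNames(d[, c(exposure, mediator)], c("exposure", "mediator")),
      log_time = log_time)
    tot <- fit_censored_gaussian_regression(
      d[[time]], d[[event]],
      stats::setNames(d[, exposure, drop = FALSE], "exposure"),
      log_time = log_time)
    c(a = a, b = unname(out$coef["mediator"]),
      direct = unname(out$coef["exposure"]),
      total = unname(tot$coef["exposure"]))
  }

  pt <- fit_paths(data)
  n <- nrow(data)
  draws <- matrix(NA_real_, n_boot, 4,
                  dimnames = list(NULL, c("a", "b", "direct", "total")))
  redraws <- 0L
  for (r in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(x[idx])) == 2) break
      redraws <- redraws + 1L
    }
    draws[r, ] <- fit_paths(data[idx, , drop = FALSE])
  }
  if (redraws > 0.1 * n_boot)
    warning(redraws, " bootstrap redraws (> 10% of replicates); ",
            "exposure groups may be too small")

  acme_draws <- draws[, "a"] * draws[, "b"]
  alpha <- (1 - conf) / 2
  ci <- function(v) unname(stats::quantile(v, c(alpha, 1 - alpha)))
  boot_p <- function(v) {
    p <- 2 * min(mean(v <= 0), mean(v >= 0))
    max(min(p, 1), 1 / n_boot)
  }
  acme <- acme_point(pt["a"], pt["b"])
  structure(list(
    a = unname(pt["a"]), b = unname(pt["b"]),
    acme = unname(acme), direct = unname(pt["direct"]),
    total = unname(pt["total"]),
    prop_mediated = proportion_mediated(unname(acme), unname(pt["total"])),
    ci_acme = ci(acme_draws), ci_total = ci(draws[, "total"]),
    ci_direct = ci(draws[, "direct"]),
    ci_prop = ci(acme_draws / draws[, "total"]),
    p_acme = boot_p(acme_draws), p_total = boot_p(draws[, "total"]),
    se_acme = stats::sd(acme_draws), se_total = stats::sd(draws[, "total"]),
    boot = cbind(draws, acme = acme_draws),
    n_boot = as.integer(n_boot), redraws = redraws, conf = conf,
    n = n), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(v) format(v, digits = 3)
  cat("Causal mediation (product of coefficients,", x$n_boot,
      "bootstraps)\n")
  cat(sprintf("  a (exposure -> mediator)      : %s\n", fmt(x$a)))
  cat(sprintf("  b (mediator -> survival time) : %s\n", fmt(x$b)))
  cat(sprintf("  ACME = a*b : %s  [%s, %s]  p = %s\n", fmt(x$acme),
              fmt(x$ci_acme[1]), fmt(x$ci_acme[2]), fmt(x$p_acme)))
  cat(sprintf("  total effect : %s  [%s, %s]  p = %s\n", fmt(x$total),
              fmt(x$ci_total[1]), fmt(x$ci_total[2]), fmt(x$p_total)))
  cat(sprintf("  direct effect: %s\n", fmt(x$direct)))
  cat(sprintf("  proportion mediated: %s%s\n", fmt(x$prop_mediated),
              if (isTRUE(attr(x$prop_mediated, "inconsistent")))
                "  [inconsistent mediation]" else ""))
  invisible(x)
}
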