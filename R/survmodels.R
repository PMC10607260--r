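#' L1-regularized logistic regression path by coordinate descent
#'
#' Solves the penalized logistic negative log-likelihood
#' `-(1/n) loglik + lambda * sum(|beta_j|)` over a decreasing lambda grid
#' by iteratively reweighted least squares with cyclic coordinate descent
#' and warm starts. Columns of `X` are standardized internally (mean 0,
#' SD 1 with the 1/n variance convention); coefficients are reported on
#' the original scale. The intercept is never penalized. At
#' `lambda >= lambda_max = max_j |X_s' (y - ybar)| / n` all slopes are
#' exactly zero; at `lambda = 0` the solution is the unpenalized maximum
#' likelihood fit.
#'
#' @param X numeric matrix or data.frame of covariates.
#' @param y binary response (0/1).
#' @param lambda optional decreasing vector of penalty values; by default
#'   a log-spaced grid of `nlambda` values from `lambda_max` down to
#'   `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio grid controls when `lambda` is `NULL`.
#' @param tol convergence tolerance on the maximum standardized
#'   coefficient change.
#' @param maxit maximum IRLS iterations per lambda.
#' @return object of class `"l1_logit_path"`: `lambda`, `beta` (covariates
#'   x lambda, original scale), `intercept`, `active` (list of active-set
#'   names per lambda), `lambda_max`, `dropped` (constant columns).
#' @export
fit_l1_logistic_path <- function(X, y, lambda = NULL, nlambda = 50,
                                 lambda_min_ratio = 1e-3,
                                 tol = 1e-10, maxit = 500L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  n <- nrow(X)
  sds <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  p <- ncol(X)
  mus <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mus), 2, sds, "/")

  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- sort(lambda, decreasing = TRUE)
  }

  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  beta <- rep(0, p)
  b0 <- stats::qlogis(mean(y))
  B <- matrix(0, p, length(lambda), dimnames = list(colnames(X), NULL))
  B0 <- numeric(length(lambda))
  warned_sep <- FALSE

  for (k in seq_along(lambda)) {
    lam <- lambda[k]
    for (it in seq_len(maxit)) {
      eta <- drop(Xs %*% beta) + b0
      pr <- stats::plogis(eta)
      w <- pmax(pr * (1 - pr), 1e-5)
      z <- eta + (y - pr) / w
      # one full IRLS step: coordinate-descent sweeps on the quadratic
      beta_old_outer <- beta; b0_old_outer <- b0
      r <- z - eta  # residual of current fit
      repeat {
        maxdel <- 0
        for (j in seq_len(p)) {
          bj <- beta[j]
          num <- sum(w * Xs[, j] * (r + Xs[, j] * bj)) / n
          den <- sum(w * Xs[, j]^2) / n
          bj_new <- soft(num, lam) / den
          if (bj_new != bj) {
            r <- r - Xs[, j] * (bj_new - bj)
            maxdel <- max(maxdel, abs(bj_new - bj))
            beta[j] <- bj_new
          }
        }
        b0_new <- b0 + sum(w * r) / sum(w)
        if (b0_new != b0) {
          r <- r - (b0_new - b0)
          maxdel <- max(maxdel, abs(b0_new - b0))
          b0 <- b0_new
        }
        if (maxdel < tol) break
      }
      if (max(abs(beta - beta_old_outer), abs(b0 - b0_old_outer)) < tol) break
      if (it == maxit && lam == 0 && !warned_sep) {
        warned_sep <- TRUE
        warning("unpenalized fit did not converge in ", maxit,
                " iterations; possible separation")
      }
    }
    if (lam == 0 && max(abs(beta)) > 50 && !warned_sep) {
      warned_sep <- TRUE
      warning("very large coefficients at lambda = 0; possible separation")
    }
    B[, k] <- beta / sds
    B0[k] <- b0 - sum(beta * mus / sds)
  }
  active <- apply(B, 2, function(b) colnames(X)[b != 0], simplify = FALSE)
  structure(list(lambda = lambda, beta = B, intercept = B0,
                 active = active, lambda_max = lambda_max,
                 dropped = dropped, nobs = n),
            class = "l1_logit_path")
}

#' @export
print.l1_logit_path <- function(x, ...) {
  cat("L1 logistic path:", nrow(x$beta), "covariates,",
      length(x$lambda), "lambda values\n")
  cat(sprintf("  lambda_max = %.4g; active at smallest lambda: %s\n",
              x$lambda_max,
              paste(x$active[[length(x$active)]], collapse = ", ")))
  invisible(x)
}

#' Extract coefficients from an L1 path at a given penalty
#'
#' @param object an `"l1_logit_path"`.
#' @param lambda penalty value; the nearest grid point is used.
#' @param ... unused.
#' @return named vector (intercept first), original scale.
#' @export
coef.l1_logit_path <- function(object, lambda = min(object$lambda), ...) {
  k <- which.min(abs(object$lambda - lambda))
  c("(Intercept)" = object$intercept[k], object$beta[, k])
}

#' Ordinary (unpenalized) logistic regression
#'
#' Maximum-likelihood fit via [stats::glm()], with a perfect-separation
#' flag raised when fitted probabilities degenerate to 0/1.
#'
#' @param X covariate matrix or data.frame.
#' @param y binary response (0/1).
#' @return object of class `"crt_logistic"`: `intercept`, `coef`, `se`,
#'   `fit` (the glm object), `separation` flag.
#' @export
fit_logistic <- function(X, y) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  df <- cbind(.y = y, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  structure(list(intercept = unname(cf[1]), coef = cf[-1],
                 se = sqrt(diag(stats::vcov(fit)))[-1],
                 fit = fit, separation = sep),
            class = "crt_logistic")
}

#' @export
print.crt_logistic <- function(x, ...) {
  cat("Logistic model\n  intercept:", format(x$intercept, digits = 4), "\n")
  print(data.frame(coef = x$coef, se = x$se))
  if (x$separation) cat("  [flagged: possible perfect separation]\n")
  invisible(x)
}

#' @export
predict.crt_logistic <- function(object, newdata, type = "response", ...) {
  stats::predict(object$fit, newdata = as.data.frame(newdata), type = type)
}

#' Train/test split evaluation of a logistic prognostic model
#'
#' Splits the cohort into a training fraction and a held-out test set,
#' fits the logistic model on the training set, and reports test-set
#' accuracy at a probability threshold of 0.5. If a split leaves the
#' training set with only one outcome class, it is redrawn (logged).
#'
#' @param data data.frame with the outcome and covariates.
#' @param outcome name of the binary outcome column.
#' @param covariates character vector of covariate column names.
#' @param train_frac training fraction (default 0.70).
#' @param seed RNG seed for the split.
#' @param max_redraws maximum redraw attempts for degenerate splits.
#' @return list with `accuracy`, `n_train`, `n_test`, `model`, `redraws`.
#' @export
evaluate_split <- function(data, outcome, covariates, train_frac = 0.70,
                           seed = NULL, max_redraws = 25L) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  y <- as.numeric(data[[outcome]])
  redraws <- 0L
  repeat {
    idx <- sample.int(n, round(train_frac * n))
    if (length(unique(y[idx])) == 2 && length(unique(y[-idx])) >= 1) break
    redraws <- redraws + 1L
    if (redraws > max_redraws)
      stop("could not draw a training set containing both classes")
  }
  if (redraws > 0)
    message("evaluate_split: redrew the split ", redraws,
            " time(s) to obtain both classes in training")
  model <- fit_logistic(data[idx, covariates, drop = FALSE], y[idx])
  pr <- predict(model, data[-idx, covariates, drop = FALSE])
  acc <- mean((pr >= 0.5) == (y[-idx] == 1))
  list(accuracy = acc, n_train = length(idx), n_test = n - length(idx),
       model = model, redraws = redraws)
}

# exact (Clopper-Pearson) binomial CI via beta quantiles
clopper_pearson <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' ROC curve, AUC and exact binomial CIs at operating points
#'
#' The AUC uses the rank (Mann-Whitney) formulation with half credit for
#' ties, which makes it invariant under strictly monotone transforms of
#' the scores. Exact Clopper-Pearson 95% confidence intervals for
#' sensitivity and specificity are reported at three operating points:
#' the Youden-optimal threshold and the thresholds nearest sensitivity
#' 0.8 and specificity 0.8.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels binary labels (0/1); both classes must be present.
#' @param conf confidence level for the exact intervals.
#' @return object of class `"crt_roc"`: `auc`, `points` (data.frame of
#'   threshold, sensitivity, specificity over all cut positions), and
#'   `operating` (3-row data.frame with CI columns).
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present: AUC undefined")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks give the tie half-credit convention
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores))
  pts <- t(vapply(thr, function(cc) {
    pred <- scores >= cc
    c(sens = sum(pred & labels == 1) / n1,
      spec = sum(!pred & labels == 0) / n0)
  }, numeric(2)))
  points <- data.frame(threshold = thr, sensitivity = pts[, 1],
                       specificity = pts[, 2])

  pick <- c(youden = which.max(points$sensitivity + points$specificity - 1),
            sens80 = which.min(abs(points$sensitivity - 0.8)),
            spec80 = which.min(abs(points$specificity - 0.8)))
  operating <- do.call(rbind, lapply(names(pick), function(nm) {
    i <- pick[[nm]]
    kse <- round(points$sensitivity[i] * n1)
    ksp <- round(points$specificity[i] * n0)
    ci_se <- clopper_pearson(kse, n1, conf)
    ci_sp <- clopper_pearson(ksp, n0, conf)
    data.frame(point = nm, threshold = points$threshold[i],
               sensitivity = points$sensitivity[i],
               sens_lower = ci_se[1], sens_upper = ci_se[2],
               specificity = points$specificity[i],
               spec_lower = ci_sp[1], spec_upper = ci_sp[2])
  }))
  structure(list(auc = auc, points = points, operating = operating,
                 n_pos = n1, n_neg = n0, conf = conf),
            class = "crt_roc")
}

#' @export
print.crt_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  print(x$operating, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Build a nomogram from a fitted logistic model
#'
#' Converts each covariate's contribution to the linear predictor into a
#' 0-100 point scale: `points_j(x) = 100 * |beta_j| * (x - x_ref_j) /
#' max_k(|beta_k| * range_k)`, with the reference at the favorable end of
#' each covariate (the end that increases the modeled probability), so
#' the covariate with the widest linear-predictor range spans exactly
#' 0-100 and larger totals mean a less favorable prognosis. Total points
#' map back to probability through the inverse logit of the reconstructed
#' linear predictor.
#'
#' @param model a `"crt_logistic"` fit (e.g. of 4-year survival).
#' @param ranges named list of `c(min, max)` per covariate; binary
#'   covariates should use `c(0, 1)`.
#' @param grid_n rows in each continuous covariate's points table.
#' @return object of class `"nomogram_table"`: per-covariate `scales`
#'   (value -> points), `total` (total points -> probability), and the
#'   internal mapping constants.
#' @export
build_nomogram <- function(model, ranges, grid_n = 25L) {
  stopifnot(inherits(model, "crt_logistic"))
  beta <- model$coef
  covs <- names(beta)
  if (!all(covs %in% names(ranges)))
    stop("'ranges' must name every model covariate")
  span <- vapply(covs, function(j) abs(beta[j]) * diff(range(ranges[[j]])),
                 numeric(1))
  keep <- span > 0
  if (any(!keep)) {
    warning("excluding zero-range covariate(s): ",
            paste(covs[!keep], collapse = ", "))
    covs <- covs[keep]; span <- span[keep]
  }
  if (!length(covs)) stop("no covariate has a nonzero points range")
  denom <- max(span)

  # favorable reference: the end of the range with the larger contribution
  # to the linear predictor (higher modeled probability)
  ref <- vapply(covs, function(j) {
    rg <- range(ranges[[j]])
    if (beta[j] >= 0) rg[2] else rg[1]
  }, numeric(1))

  scales <- lapply(covs, function(j) {
    rg <- range(ranges[[j]])
    vals <- if (isTRUE(all.equal(rg, c(0, 1))) &&
                length(unique(ranges[[j]])) <= 2) c(0, 1)
            else seq(rg[1], rg[2], length.out = grid_n)
    data.frame(value = vals,
               points = 100 * abs(beta[j]) * abs(vals - ref[j]) / denom)
  })
  names(scales) <- covs

  lp_fav <- model$intercept + sum(beta[covs] * ref)
  max_total <- sum(vapply(scales, function(s) max(s$points), numeric(1)))
  tot <- seq(0, max_total, length.out = 101)
  total <- data.frame(total_points = tot,
                      probability = stats::plogis(lp_fav - denom / 100 * tot))
  structure(list(scales = scales, total = total, reference = ref,
                 denom = denom, lp_favorable = lp_fav, beta = beta[covs],
                 intercept = model$intercept),
            class = "nomogram_table")
}

#' @export
print.nomogram_table <- function(x, ...) {
  cat("Nomogram (0-100 points per covariate; larger total = lower probability)\n")
  for (j in names(x$scales)) {
    s <- x$scales[[j]]
    cat(sprintf("  %-14s value %g..%g -> points %.1f..%.1f\n", j,
                min(s$value), max(s$value), min(s$points), max(s$points)))
  }
  cat(sprintf("  total points 0..%.1f -> probability %.3f..%.3f\n",
              max(x$total$total_points), x$total$probability[1],
              x$total$probability[nrow(x$total)]))
  invisible(x)
}

#' Score a nomogram for new observations
#'
#' @param nomo a `"nomogram_table"`.
#' @param newdata data.frame with the nomogram covariates.
#' @return data.frame with per-covariate points, `total_points` and the
#'   `probability` read off the total-points scale.
#' @export
nomogram_predict <- function(nomo, newdata) {
  stopifnot(inherits(nomo, "nomogram_table"))
  covs <- names(nomo$scales)
  pts <- sapply(covs, function(j) {
    100 * abs(nomo$beta[j]) * abs(newdata[[j]] - nomo$reference[j]) /
      nomo$denom
  })
  pts <- matrix(pts, nrow = nrow(newdata),
                dimnames = list(NULL, covs))
  total <- rowSums(pts)
  prob <- stats::plogis(nomo$lp_favorable - nomo$denom / 100 * total)
  data.frame(pts, total_points = total, probability = prob,
             check.names = FALSE)
}

#' Cox proportional hazards fit with Efron tie handling
#'
#' Thin wrapper around [survival::coxph()] reporting hazard ratios, Wald
#' 95% confidence intervals and p-values. Constant covariates raise an
#' error; monotone-likelihood (infinite coefficient) fits are flagged.
#'
#' @param time follow-up times (>= 0).
#' @param event event indicator (1 = death).
#' @param X covariate matrix or data.frame.
#' @return object of class `"crt_cox"`: `table` (HR, CI, p per
#'   covariate), `fit`, `flagged`.
#' @export
fit_cox <- function(time, event, X) {
  if (any(time < 0)) stop("negative follow-up times")
  X <- as.data.frame(X)
  const <- vapply(X, function(v) length(unique(v)) < 2, logical(1))
  if (any(const))
    stop("covariate(s) carry no information (constant): ",
         paste(names(X)[const], collapse = ", "))
  df <- cbind(.time = time, .event = event, X)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(hr = s$conf.int[, "exp(coef)"],
                    lower = s$conf.int[, "lower .95"],
                    upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"])
  rownames(tab) <- rownames(s$conf.int)
  structure(list(table = tab, fit = fit, flagged = flagged,
                 ties = "efron"), class = "crt_cox")
}

#' @export
print.crt_cox <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties)\n")
  print(x$table, digits = 3)
  if (x$flagged) cat("  [flagged: possible monotone likelihood]\n")
  invisible(x)
}

#' Median follow-up by the reverse Kaplan-Meier estimator
#'
#' Computes the product-limit estimate treating censoring as the event
#' (and deaths as censored), whose median is the standard estimate of
#' median follow-up. Returns the quartiles as well. With no censored
#' observations the median follow-up is undefined; the maximum observed
#' time is returned with `defined = FALSE`.
#'
#' @param time follow-up times (>= 0).
#' @param event event indicator (1 = death, 0 = censored).
#' @return list with `median`, `q25`, `q75`, `defined`, `fit`.
#' @export
reverse_km_median_followup <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up times")
  event <- as.integer(event)
  if (all(event == 1)) {
    return(list(median = max(time), q25 = NA_real_, q75 = NA_real_,
                defined = FALSE, fit = NULL))
  }
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  q <- stats::quantile(fit, probs = c(0.25, 0.5, 0.75))$quantile
  list(median = unname(q[2]), q25 = unname(q[1]), q75 = unname(q[3]),
       defined = TRUE, fit = fit)
}
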