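make_logit_data <- function(n = 300, seed = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    y <- rbinom(n, 1, plogis(0.3 + X[, 1] - 0.8 * X[, 2]))
    list(X = X, y = y)
  })
}

test_that("all slopes vanish at and above lambda_max", {
  d <- make_logit_data()
  p <- fit_l1_logistic_path(d$X, d$y, lambda = c(1, 0.5))
  lmax <- p$lambda_max
  p2 <- fit_l1_logistic_path(d$X, d$y, lambda = c(lmax * 1.5, lmax))
  expect_true(all(p2$beta == 0))
  expect_equal(p2$intercept[1], qlogis(mean(d$y)), tolerance = 1e-8)
  p3 <- fit_l1_logistic_path(d$X, d$y, lambda = lmax * 0.9)
  expect_gt(sum(p3$beta != 0), 0)
})

test_that("the unpenalized limit matches a Newton-Raphson oracle", {
  d <- make_logit_data()
  p <- fit_l1_logistic_path(d$X, d$y, lambda = c(0.05, 0.01, 0))
  oracle <- newton_logistic(d$X, d$y)
  expect_lt(max(abs(coef(p, 0) - oracle)), 1e-6)
})

test_that("the path agrees with glmnet and drops constant columns", {
  skip_if_not_installed("glmnet")
  d <- make_logit_data()
  lams <- c(0.1, 0.05, 0.02)
  gn <- glmnet::glmnet(d$X, d$y, family = "binomial", lambda = lams,
                       thresh = 1e-14)
  p <- fit_l1_logistic_path(d$X, d$y, lambda = lams)
  for (i in seq_along(lams)) {
    expect_lt(max(abs(c(p$intercept[i], p$beta[, i]) -
                        as.numeric(glmnet::coef.glmnet(gn, s = lams[i])))),
              1e-6)
  }
  Xc <- cbind(d$X, const = 1)
  expect_warning(pc <- fit_l1_logistic_path(Xc, d$y, lambda = 0.1),
                 "constant column")
  expect_equal(pc$dropped, "const")
})

test_that("active-set size is non-increasing in the penalty", {
  for (s in c(3, 11, 29)) {
    d <- make_logit_data(seed = s)
    p <- fit_l1_logistic_path(d$X, d$y, nlambda = 30)
    sizes <- lengths(p$active)  # lambda is stored decreasing
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("the L1 path ranks true prognostic covariates first", {
  # known-truth single-group cohort in which BNP, creatinine, CABG and
  # the activation flag all carry survival signal while age/QRS/QLV/AF
  # are independent of outcome by construction
  cfg <- cohort_gen_config(n_per_group = c(600, 0, 0),
                           tos_lead_median = rep(40, 3),
                           survival_intercept = 5.5,
                           bnp_effect = -1.5, cabg_effect = -1.8,
                           tos_effect = 1.8, seed = 61)
  coh <- generate_outcomes(generate_clinical_cohort(cfg), cfg)
  X <- data.frame(bnp = log(coh$bnp), creatinine = coh$creatinine,
                  cabg = coh$cabg, tos_ge34 = coh$tos_ge34,
                  age = coh$age, qrs = coh$qrs_ms, qlv = coh$qlv_ms,
                  af = coh$af)
  p <- fit_l1_logistic_path(X, coh$alive_4y, nlambda = 60)
  true_set <- c("bnp", "creatinine", "cabg", "tos_ge34")
  first_full <- which(vapply(p$active, function(a)
    all(true_set %in% a), logical(1)))[1]
  expect_false(is.na(first_full))
  # no null covariate is active before the four true ones are all in
  before <- unique(unlist(p$active[seq_len(first_full)]))
  expect_true(all(before %in% true_set))
})

test_that("plain logistic regression matches closed forms", {
  # constant outcome: intercept-only at the prevalence logit
  X <- data.frame(x = rnorm(20))
  expect_error(fit_logistic(X, rep(2, 20)), "binary")
  # 2x2 single binary covariate: slope = log odds ratio of the table
  x <- rep(c(0, 1), c(40, 40))
  y <- c(rep(c(0, 1), c(30, 10)), rep(c(0, 1), c(12, 28)))
  f <- fit_logistic(data.frame(x = x), y)
  expect_equal(unname(f$coef), log((28 / 12) / (10 / 30)), tolerance = 1e-7)
  # balanced antisymmetric design: intercept 0 by symmetry
  xa <- c(-2, -1, 1, 2); ya <- c(0, 0, 1, 1)
  fa <- fit_logistic(data.frame(x = rep(xa, 10)), rep(ya, 10))
  expect_equal(fa$intercept, 0, tolerance = 1e-3)
})

test_that("split evaluation reproduces a per-seed refit oracle", {
  cfg <- cohort_gen_config(n_per_group = c(120, 120, 60), seed = 15)
  coh <- generate_outcomes(generate_clinical_cohort(cfg), cfg)
  covs <- c("creatinine", "bnp")
  for (s in c(1, 2, 3, 4, 5)) {
    r <- evaluate_split(coh, "alive_4y", covs, seed = s)
    # independent route: same RNG stream, direct glm fit and counting
    set.seed(s)
    idx <- sample.int(nrow(coh), round(0.7 * nrow(coh)))
    g <- glm(alive_4y ~ creatinine + bnp, binomial, coh[idx, ])
    pr <- predict(g, coh[-idx, ], type = "response")
    acc <- mean((pr >= 0.5) == (coh$alive_4y[-idx] == 1))
    expect_equal(r$accuracy, acc, tolerance = 1e-10)
  }
})

test_that("split evaluation handles separable and null designs", {
  withr::with_seed(8, {
    x <- rnorm(200)
    d <- data.frame(x = x, y = as.integer(x > 0))
    r <- evaluate_split(d, "y", "x", seed = 1)
    expect_equal(r$accuracy, 1.0)
    # pure-noise covariate on an unbalanced outcome: accuracy tracks the
    # majority class
    d2 <- data.frame(x = rnorm(400), y = rbinom(400, 1, 0.7))
    r2 <- evaluate_split(d2, "y", "x", seed = 2)
    expect_gt(r2$accuracy, 0.55)
  })
})

test_that("AUC follows the rank formulation and its invariances", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  withr::with_seed(5, {
    sc <- rnorm(60); lb <- rbinom(60, 1, plogis(sc))
    a <- roc_auc(sc, lb)$auc
    expect_equal(roc_auc(exp(sc), lb)$auc, a)           # monotone transform
    expect_equal(roc_auc(rank(sc), lb)$auc, a)
  })
  expect_error(roc_auc(1:5, rep(1, 5)), "undefined")
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(6, {
    sc <- rnorm(80); lb <- rbinom(80, 1, plogis(1.5 * sc))
    expect_equal(roc_auc(sc, lb)$auc,
                 as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))),
                 tolerance = 1e-10)
  })
})

test_that("operating-point CIs are exact beta-quantile bounds", {
  ci <- crtcmr:::clopper_pearson(0, 10)
  expect_equal(unname(ci["lower"]), 0)
  expect_equal(unname(ci["upper"]), qbeta(0.975, 1, 10))
  ci2 <- crtcmr:::clopper_pearson(7, 10)
  expect_equal(unname(ci2["lower"]), qbeta(0.025, 7, 4))
  expect_equal(unname(ci2["upper"]), qbeta(0.975, 8, 3))
  withr::with_seed(10, {
    sc <- rnorm(50); lb <- rbinom(50, 1, plogis(2 * sc))
    r <- roc_auc(sc, lb)
    expect_equal(nrow(r$operating), 3)
    expect_true(all(r$operating$sens_lower <= r$operating$sensitivity))
    expect_true(all(r$operating$spec_upper >= r$operating$specificity))
  })
})

test_that("nomogram points round-trip to model probabilities", {
  withr::with_seed(12, {
    d <- data.frame(bnp = rlnorm(150, log(270), 0.6),
                    creat = rlnorm(150, log(1.1), 0.3),
                    cabg = rbinom(150, 1, 0.25))
    y <- rbinom(150, 1, plogis(4 - 0.004 * d$bnp - 1.5 * d$creat - d$cabg))
    m <- fit_logistic(d, y)
    nomo <- build_nomogram(m, list(bnp = range(d$bnp),
                                   creat = range(d$creat), cabg = c(0, 1)))
    # binary covariate has exactly two point values {0, 100|b|/denom}
    expect_equal(nomo$scales$cabg$points,
                 c(0, 100 * abs(m$coef["cabg"]) / nomo$denom)[
                   order(c(0, 1) != nomo$reference["cabg"])],
                 ignore_attr = TRUE)
    # round trip: probability from total points == direct model prediction
    pred_nomo <- nomogram_predict(nomo, d)$probability
    pred_mod <- predict(m, d)
    expect_lt(max(abs(pred_nomo - pred_mod)), 1e-10)
    # reading through the printed table (rounded to the 0.5-point grid)
    # stays within the table's rounding tolerance
    tot <- round(nomogram_predict(nomo, d)$total_points * 2) / 2
    p_tab <- plogis(nomo$lp_favorable - nomo$denom / 100 * tot)
    expect_lt(max(abs(p_tab - pred_mod)), nomo$denom / 100 * 0.25 + 1e-12)
  })
})

test_that("single-covariate nomograms span 0 to 100 points", {
  withr::with_seed(13, {
    d <- data.frame(x = runif(100, 0, 10))
    y <- rbinom(100, 1, plogis(1 - 0.4 * d$x))
    m <- fit_logistic(d, y)
    nomo <- build_nomogram(m, list(x = c(0, 10)))
    expect_equal(range(nomo$scales$x$points), c(0, 100))
    # points increase linearly away from the favorable end
    expect_true(all(diff(nomo$scales$x$points) > 0) ||
                  all(diff(nomo$scales$x$points) < 0))
  })
})

test_that("Cox score test at beta = 0 equals the log-rank statistic", {
  withr::with_seed(14, {
    time <- rexp(80); event <- rbinom(80, 1, 0.8)
    x <- rbinom(80, 1, 0.5)
    f <- fit_cox(time, event, data.frame(x = x))
    sc <- summary(f$fit)$sctest["test"]
    lr <- survival::survdiff(survival::Surv(time, event) ~ x)$chisq
    expect_equal(unname(sc), unname(lr), tolerance = 1e-6)
    expect_error(fit_cox(time, event, data.frame(x = rep(1, 80))),
                 "no information|constant")
    expect_error(fit_cox(-time, event, data.frame(x = x)), "negative")
  })
})

test_that("Cox with a tie matches a grid search of the Efron likelihood", {
  time <- c(1, 1, 2, 3, 4, 5)
  event <- c(1, 1, 1, 1, 0, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  f <- fit_cox(time, event, data.frame(x = x))
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, efron_loglik, numeric(1), time = time, event = event,
               x = x)
  expect_lt(abs(log(f$table["x", "hr"]) - grid[which.max(ll)]), 1e-4)
})

test_that("Cox estimates are consistent on exponential data", {
  withr::with_seed(17, {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    t0 <- rexp(n, rate = exp(0.7 * x))
    cens <- runif(n, 0, 3)
    f <- fit_cox(pmin(t0, cens), as.integer(t0 <= cens),
                 data.frame(x = x))
    se <- sqrt(diag(f$fit$var))
    expect_lt(abs(log(f$table["x", "hr"]) - 0.7), 3 * se)
  })
})

test_that("reverse KM median follow-up matches hand computation", {
  # all censored at 4.8 years: point mass
  r <- reverse_km_median_followup(rep(4.8, 10), rep(0, 10))
  expect_equal(r$median, 4.8)
  expect_true(r$defined)
  # no censored observations: undefined, flagged
  r2 <- reverse_km_median_followup(c(1, 2, 3), c(1, 1, 1))
  expect_false(r2$defined)
  expect_equal(r2$median, 3)
  # 8-subject mixed example vs the hand product-limit oracle
  time <- c(0.5, 1.2, 2.0, 2.5, 3.1, 4.0, 4.6, 5.0)
  event <- c(1, 0, 1, 0, 0, 1, 0, 0)
  r3 <- reverse_km_median_followup(time, event)
  expect_equal(r3$median, reverse_km_oracle(time, event))
  # identity: equals ordinary KM on flipped indicators
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  expect_equal(r3$median,
               unname(quantile(fit, 0.5)$quantile))
})
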