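#' Compare a variable across CRT groups
#'
#' Continuous variables are compared with the tie-corrected
#' Kruskal-Wallis test and Dunn's rank-based z post hoc tests for the
#' pairwise contrasts (reported unadjusted by default, optionally
#' Holm-adjusted). Categorical variables use the chi-square test, or
#' Fisher's exact test when any expected cell count is below 5; the
#' group 1 vs 2 pairwise p-value applies the same rule to the two-group
#' subtable.
#'
#' @param data data.frame with the variable and a group column.
#' @param variable name of the column to compare.
#' @param group name of the grouping column (default `"group"`).
#' @param type `"auto"` (factor/character/binary -> categorical),
#'   `"continuous"` or `"categorical"`.
#' @param adjust apply a Holm adjustment to the pairwise p-values.
#' @return object of class `"group_comparison"`: `test`, `statistic`,
#'   `p_overall`, `p_pairwise` (named by contrast), `degenerate` flag.
#' @export
compare_groups <- function(data, variable, group = "group",
                           type = c("auto", "continuous", "categorical"),
                           adjust = FALSE) {
  type <- match.arg(type)
  v <- data[[variable]]
  g <- factor(data[[group]])
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups with data")
  if (type == "auto") {
    type <- if (is.factor(v) || is.character(v) ||
                length(unique(v)) <= 2) "categorical" else "continuous"
  }
  if (length(unique(v)) < 2) {
    return(structure(list(variable = variable, test = "none (constant)",
                          statistic = NA_real_, p_overall = NA_real_,
                          p_pairwise = NULL, degenerate = TRUE),
                     class = "group_comparison"))
  }
  if (type == "continuous") {
    kw <- stats::kruskal.test(v, g)
    pw <- dunn_pairwise(v, g)
    if (adjust) pw <- stats::p.adjust(pw, "holm")
    res <- list(variable = variable, test = "Kruskal-Wallis + Dunn",
                statistic = unname(kw$statistic), p_overall = kw$p.value,
                p_pairwise = pw, degenerate = FALSE)
  } else {
    tab <- table(v, g)
    use_fisher <- any(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE))$expected < 5)
    overall <- if (use_fisher) stats::fisher.test(tab, workspace = 2e6)
               else suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    pw <- NULL
    lv <- levels(g)
    if (length(lv) >= 2) {
      pw <- numeric(0)
      for (pair in utils::combn(lv, 2, simplify = FALSE)) {
        sub <- tab[, pair, drop = FALSE]
        sub <- sub[rowSums(sub) > 0, , drop = FALSE]
        p <- if (nrow(sub) < 2) NA_real_
        else if (any(suppressWarnings(
          stats::chisq.test(sub, correct = FALSE))$expected < 5))
          stats::fisher.test(sub)$p.value
        else suppressWarnings(stats::chisq.test(sub, correct = FALSE))$p.value
        pw[paste(pair, collapse = " vs ")] <- p
      }
      if (adjust) pw <- stats::p.adjust(pw, "holm")
    }
    res <- list(variable = variable,
                test = if (use_fisher) "Fisher exact" else "chi-square",
                statistic = if (use_fisher) NA_real_
                            else unname(overall$statistic),
                p_overall = overall$p.value,
                p_pairwise = pw, degenerate = FALSE)
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, p = %s\n", x$variable, x$test,
              format(x$p_overall, digits = 3)))
  if (!is.null(x$p_pairwise)) {
    for (nm in names(x$p_pairwise))
      cat(sprintf("  %s: p = %s\n", nm,
                  format(x$p_pairwise[nm], digits = 3)))
  }
  invisible(x)
}

# Dunn's post hoc z tests on the joint ranks, with tie correction
dunn_pairwise <- function(v, g) {
  r <- rank(v)
  N <- length(v)
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  out <- numeric(0)
  for (pair in utils::combn(lv, 2, simplify = FALSE)) {
    i <- g == pair[1]; j <- g == pair[2]
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / sum(i) + 1 / sum(j)))
    out[paste(pair, collapse = " vs ")] <- 2 * stats::pnorm(-abs(z))
  }
  out
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
  sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
}

n_pct <- function(x) sprintf("%d (%.1f)", sum(x == 1), 100 * mean(x == 1))

#' Pipeline configuration
#'
#' @param strain a [strain_gen_config()] (its per-group sizes are taken
#'   from `cohort$n_per_group`).
#' @param cohort a [cohort_gen_config()].
#' @param seed master RNG seed for the whole pipeline.
#' @param n_boot mediation bootstrap replicates.
#' @param youden_step grid step (ms) for the activation-time cutoff scan.
#' @param lambda penalty at which the L1 active set is read off.
#' @param train_frac training fraction for the split evaluation.
#' @param responder_cutoff LVESVI fractional-change responder threshold.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(strain = strain_gen_config(),
                            cohort = cohort_gen_config(),
                            seed = 1L, n_boot = 1000L, youden_step = 17,
                            lambda = 0.08, train_frac = 0.70,
                            responder_cutoff = -0.15) {
  if (sum(cohort$n_per_group) == 0)
    stop("cohort size is zero: nothing to simulate")
  if (n_boot < 1) stop("'n_boot' must be >= 1")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes every stage end to end on generated data: strain simulation,
#' CURE-SVD and activation mapping per patient, cohort and outcome
#' generation, group-comparison tables (a baseline table and a
#' latest-activation location table), Youden cutoff selection for the
#' activation time at the LV lead, L1 covariate selection, the logistic
#' 4-year survival model with split evaluation, ROC and nomogram, the
#' Cox model, reverse Kaplan-Meier median follow-up, and the bootstrapped
#' creatinine mediation of the group-2 effect on survival time. The
#' bundle is a pure function of the configuration (including its seed).
#'
#' A self-consistency audit recomputes every reported crude percentage
#' from the emitted row-level data.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, tabular outputs are
#'   written as CSV and model/mediation objects as JSON (requires the
#'   `jsonlite` package).
#' @return a list ("report bundle") with components `cohort`, `table1`,
#'   `table2`, `cure`, `cutoff`, `lasso`, `model`, `split`, `roc`,
#'   `nomogram`, `cox`, `followup`, `mediation`, `audit`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)

  # stage: synth (strain + cohort share the master seed stream)
  scfg <- config$strain
  scfg$seed <- NULL
  scfg$n_patients_per_group <- config$cohort$n_per_group
  ds <- generate_strain_dataset(scfg)
  ccfg <- config$cohort
  ccfg$seed <- NULL
  cohort <- generate_clinical_cohort(ccfg)
  cohort <- generate_outcomes(cohort, ccfg)

  # stage: strain analysis per patient
  maps <- lapply(ds$strain, detect_activation_times)
  cohort$cure_svd <- vapply(ds$strain, compute_cure_svd, numeric(1))
  latest <- lapply(maps, classify_latest_activation)
  cohort$latest_region <- vapply(latest, `[[`, character(1), "region")
  cohort$latest_level <- vapply(latest, `[[`, character(1), "level")
  at_lead <- mapply(function(m, seg) activation_at_segment(m, seg)$tos_ms,
                    maps, cohort$lead_segment)
  cohort$tos_lead_cmr_ms <- at_lead

  # stage: response
  resp <- lvesvi_fractional_change(cohort$lvesvi_pre, cohort$lvesvi_post,
                                   config$responder_cutoff)
  cohort$responder <- resp$responder
  cutoff <- youden_optimal_cutoff(cohort$tos_lead_ms, cohort$alive_4y,
                                  step = config$youden_step)
  cohort$tos_ge_cut <- as.integer(cohort$tos_lead_ms >= cutoff$cutoff)

  # stage: group tables
  cont_vars <- c("age", "creatinine", "bnp", "qrs_ms", "qlv_ms",
                 "lvesvi_pre", "cure_svd", "tos_lead_ms", "lvesvi_fc")
  cat_vars <- c("af", "cabg", "alive_4y")
  table1 <- list(
    summary = do.call(rbind, lapply(c(cont_vars, cat_vars), function(vn) {
      by_g <- split(cohort[[vn]], cohort$group)
      f <- if (vn %in% cont_vars) med_iqr else n_pct
      data.frame(variable = vn, g1 = f(by_g[[1]]), g2 = f(by_g[[2]]),
                 g3 = f(by_g[[3]]), stringsAsFactors = FALSE)
    })),
    tests = lapply(stats::setNames(nm = c(cont_vars, cat_vars)),
                   function(vn) compare_groups(
                     cohort, vn,
                     type = if (vn %in% cont_vars) "continuous"
                            else "categorical")))

  table2 <- list(
    region = table(cohort$latest_region, cohort$group),
    level = table(cohort$latest_level, cohort$group),
    test_region = compare_groups(cohort, "latest_region",
                                 type = "categorical"))

  # stage: prognostic models
  candidates <- c("bnp", "creatinine", "cabg", "tos_ge_cut", "age",
                  "qrs_ms", "qlv_ms", "af")
  Xc <- cohort[, candidates]
  lasso <- fit_l1_logistic_path(Xc, cohort$alive_4y)
  sel <- c("bnp", "creatinine", "cabg", "tos_ge_cut")
  model <- fit_logistic(cohort[, sel], cohort$alive_4y)
  split_eval <- evaluate_split(cohort, "alive_4y", sel,
                               train_frac = config$train_frac)
  roc <- roc_auc(predict(model, cohort[, sel]), cohort$alive_4y)
  ranges <- lapply(stats::setNames(nm = sel), function(j)
    if (j %in% c("cabg", "tos_ge_cut")) c(0, 1) else range(cohort[[j]]))
  nomo <- build_nomogram(model, ranges)
  cox <- fit_cox(cohort$time_years, cohort$event, cohort[, sel])
  fup <- reverse_km_median_followup(cohort$time_years, cohort$event)

  # stage: mediation (group 2 vs group 1; group 3 excluded)
  med_data <- cohort[cohort$group %in% c(1, 2), ]
  med_data$exposure <- as.integer(med_data$group == 2)
  mediation <- bootstrap_mediation(med_data, "exposure", "creatinine",
                                   "time_years", "event",
                                   n_boot = config$n_boot)

  audit <- audit_bundle(cohort)
  bundle <- list(cohort = cohort, table1 = table1, table2 = table2,
                 cutoff = cutoff, lasso = lasso, model = model,
                 split = split_eval, roc = roc, nomogram = nomo,
                 cox = cox, followup = fup, mediation = mediation,
                 audit = audit, seed = config$seed,
                 truth = ds$truth)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# every reported crude percentage must equal numerator/denominator
# recomputed from the row-level cohort
audit_bundle <- function(cohort) {
  n <- nrow(cohort)
  deaths <- sum(cohort$event == 1)
  deaths_4y <- sum(cohort$event == 1 & cohort$time_years <= 4)
  list(n = n,
       deaths = deaths, death_rate_pct = 100 * deaths / n,
       deaths_4y = deaths_4y, death_rate_4y_pct = 100 * deaths_4y / n,
       consistent = isTRUE(all.equal(100 * mean(cohort$event == 1),
                                     100 * deaths / n)))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$table1$summary,
                   file.path(out_dir, "table1_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$cutoff$grid, file.path(out_dir, "cutoff_scan.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$roc$points, file.path(out_dir, "roc.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$nomogram$total,
                   file.path(out_dir, "nomogram_total.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    m <- bundle$mediation
    jsonlite::write_json(
      list(a = m$a, b = m$b, acme = m$acme, total = m$total,
           direct = m$direct,
           prop_mediated = as.numeric(m$prop_mediated),
           ci_acme = m$ci_acme, ci_total = m$ci_total,
           p_acme = m$p_acme, n_boot = m$n_boot),
      file.path(out_dir, "mediation.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(intercept = bundle$model$intercept,
           coef = as.list(bundle$model$coef), auc = bundle$roc$auc,
           cutoff = bundle$cutoff$cutoff,
           test_accuracy = bundle$split$accuracy, seed = bundle$seed),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  }
  writeLines(c(sprintf("seed: %d", bundle$seed),
               sprintf("n: %d", bundle$audit$n),
               sprintf("R version: %s", getRversion())),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
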