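#' Configuration for the synthetic strain-matrix generator
#'
#' Defines the conditions under which sectorized E_cc strain matrices are
#' simulated: geometry, temporal sampling, waveform amplitude, onset-delay
#' structure and noise. Each sector curve is flat at zero before its true
#' onset, descends along a raised cosine to `peak_strain`, and partially
#' recovers; true onsets are snapped to the frame grid so ground-truth
#' recovery is well defined. The latest-activated segment of each patient
#' is drawn from a group-specific distribution over circumferential
#' regions and longitudinal levels, reproducing the anterior/basal shift
#' of late activation seen in RV-paced upgrade patients relative to de
#' novo CRT patients.
#'
#' @param n_patients_per_group integer vector of length 3 (groups 1 = de
#'   novo CRT, 2 = upgrade with RV-pacing dependence, 3 = upgrade
#'   without). Defaults to the study sizes 50/29/23.
#' @param sectors_per_slice sectors per short-axis slice (>= 4).
#' @param n_slices number of slices (basal, mid, apical order).
#' @param n_frames time frames per curve (>= 8).
#' @param frame_interval_ms temporal resolution in ms (default 17, the
#'   DENSE frame interval).
#' @param peak_strain peak E_cc (negative = shortening).
#' @param rise_ms time from onset to peak strain.
#' @param recover_ms duration of the partial re-lengthening phase.
#' @param recover_frac fraction of peak strain retained at end-recovery.
#' @param base_onset_frames non-negative integers from which background
#'   sector onsets (in frames) are drawn uniformly.
#' @param bump_frames extra onset delay (frames) applied to the sectors of
#'   the latest-activated target segment; half of it to their immediate
#'   circumferential neighbours.
#' @param noise_sd SD of i.i.d. Gaussian strain noise.
#' @param scar_sectors optional integer vector of sector indices whose
#'   amplitude is attenuated.
#' @param scar_attenuation multiplicative amplitude factor for scar
#'   sectors.
#' @param latest_site_probs list of three lists (one per group), each with
#'   `region` (named probabilities over anterior / inferior /
#'   inferolateral / anterolateral) and `level` (basal / mid-ventricular /
#'   apical). Defaults follow the observed latest-activation
#'   distributions of the three groups.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list of class `"strain_gen_config"`.
#' @export
strain_gen_config <- function(n_patients_per_group = c(50L, 29L, 23L),
                              sectors_per_slice = 12L,
                              n_slices = 3L,
                              n_frames = 30L,
                              frame_interval_ms = 17,
                              peak_strain = -0.15,
                              rise_ms = 150,
                              recover_ms = 200,
                              recover_frac = 0.35,
                              base_onset_frames = 0:2,
                              bump_frames = 5L,
                              noise_sd = 0.01,
                              scar_sectors = NULL,
                              scar_attenuation = 0.4,
                              latest_site_probs = default_latest_site_probs(),
                              seed = NULL) {
  cfg <- as.list(environment())
  if (any(n_patients_per_group < 0) || length(n_patients_per_group) != 3)
    stop("'n_patients_per_group' must be 3 non-negative counts")
  if (sectors_per_slice < 4) stop("'sectors_per_slice' must be >= 4")
  if (n_frames < 8) stop("'n_frames' must be >= 8")
  if (frame_interval_ms <= 0) stop("'frame_interval_ms' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (n_slices < 1 || n_slices > 3) stop("'n_slices' must be 1..3")
  class(cfg) <- "strain_gen_config"
  cfg
}

# Latest-mechanical-activation site distributions per group; group 2
# (RV-paced upgrades) is biased anterior/basal, group 1 anterolateral/
# inferolateral mid-ventricular.
default_latest_site_probs <- function() {
  list(
    list(region = c(anterior = 0.10, inferior = 0.02,
                    inferolateral = 0.34, anterolateral = 0.54),
         level = c(basal = 0.28, "mid-ventricular" = 0.62, apical = 0.10)),
    list(region = c(anterior = 0.483, inferior = 0.034,
                    inferolateral = 0.069, anterolateral = 0.414),
         level = c(basal = 0.862, "mid-ventricular" = 0.138, apical = 0)),
    list(region = c(anterior = 0.391, inferior = 0.043,
                    inferolateral = 0.304, anterolateral = 0.262),
         level = c(basal = 0.696, "mid-ventricular" = 0.261, apical = 0.043))
  )
}

# raised-cosine shortening waveform: zero until onset, cosine descent to
# peak over rise_ms, cosine recovery to recover_frac * peak, then plateau
ecc_waveform <- function(t_ms, onset_ms, peak, rise_ms, recover_ms,
                         recover_frac) {
  u <- t_ms - onset_ms
  y <- numeric(length(t_ms))
  ph1 <- u > 0 & u <= rise_ms
  y[ph1] <- peak * (1 - cos(pi * u[ph1] / rise_ms)) / 2
  ph2 <- u > rise_ms & u <= rise_ms + recover_ms
  v <- (u[ph2] - rise_ms) / recover_ms
  y[ph2] <- peak * (recover_frac + (1 - recover_frac) * (1 + cos(pi * v)) / 2)
  y[u > rise_ms + recover_ms] <- peak * recover_frac
  y
}

# circumferential neighbours of an AHA segment within its own ring
adjacent_segments <- function(aha_id) {
  if (aha_id <= 6) (c(aha_id - 2, aha_id) %% 6) + 1
  else if (aha_id <= 12) (c(aha_id - 8, aha_id - 6) %% 6) + 7
  else (c(aha_id - 14, aha_id - 12) %% 4) + 13
}

# pick the AHA segment matching a (region, level) draw; apical ring pools
# the two lateral and two septal regions into its 4 segments
site_to_aha <- function(region, level) {
  tab <- aha_segment_table()
  if (level == "apical") {
    region <- switch(region,
                     anterior = "anterior", anteroseptal = "anteroseptal",
                     inferoseptal = "anteroseptal", inferior = "inferior",
                     inferolateral = "anterolateral",
                     anterolateral = "anterolateral")
  }
  tab$aha[tab$region == region & tab$level == level][1]
}

#' Generate a synthetic strain dataset with known activation ground truth
#'
#' One strain matrix per patient, plus the true per-sector onset times and
#' the seeded latest-activation segment, so recovery tests never have to
#' re-derive the truth.
#'
#' @param cfg a [strain_gen_config()].
#' @param groups optional integer vector of group labels (1/2/3), one per
#'   patient; defaults to `rep(1:3, cfg$n_patients_per_group)`.
#' @return list with `strain` (list of [strain_matrix()]) and `truth`
#'   (data.frame: patient_id, group, latest AHA segment / region / level)
#'   plus `onsets_ms` (patients x sectors matrix of true onsets).
#' @export
generate_strain_dataset <- function(cfg = strain_gen_config(), groups = NULL) {
  stopifnot(inherits(cfg, "strain_gen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(groups)) groups <- rep(1:3, cfg$n_patients_per_group)
  n_pat <- length(groups)
  dt <- cfg$frame_interval_ms
  nf <- cfg$n_frames
  sps <- cfg$sectors_per_slice
  slices <- c("basal", "mid", "apical")[seq_len(cfg$n_slices)]
  slice_vec <- rep(slices, each = sps)
  angle <- rep(seq(0, 360 - 360 / sps, by = 360 / sps) + 180 / sps,
               times = cfg$n_slices)
  n_sec <- length(slice_vec)
  aha <- mapply(sector_aha_id, slice_vec, angle)
  t_ms <- (seq_len(nf) - 1) * dt

  strain_list <- vector("list", n_pat)
  onsets <- matrix(0, n_pat, n_sec)
  truth <- data.frame(patient_id = sprintf("P%03d", seq_len(n_pat)),
                      group = groups, latest_aha = NA_integer_,
                      latest_region = NA_character_,
                      latest_level = NA_character_,
                      stringsAsFactors = FALSE)

  for (i in seq_len(n_pat)) {
    g <- groups[i]
    pr <- cfg$latest_site_probs[[g]]
    lv <- names(pr$level)[pr$level > 0]
    lv <- lv[lv %in% unique(aha_segment_table()$level[aha_segment_table()$aha %in% aha])]
    pl <- pr$level[lv] / sum(pr$level[lv])
    level <- sample(lv, 1, prob = pl)
    region <- sample(names(pr$region), 1, prob = pr$region)
    target <- site_to_aha(region, level)
    tab <- aha_segment_table()
    truth$latest_aha[i] <- target
    truth$latest_region[i] <- tab$region[target]
    truth$latest_level[i] <- tab$level[target]

    # activation is a propagating wavefront, so the true onset field is
    # piecewise constant over AHA segments: one base delay per segment,
    # a late-activation bump at the target segment decaying over its
    # circumferential neighbours at the same level
    segs_here <- sort(unique(aha))
    seg_base <- stats::setNames(sample(cfg$base_onset_frames,
                                       length(segs_here), replace = TRUE),
                                segs_here)
    nb_segs <- adjacent_segments(target)
    seg_base[as.character(intersect(nb_segs, segs_here))] <-
      seg_base[as.character(intersect(nb_segs, segs_here))] +
      ceiling(cfg$bump_frames / 2)
    seg_base[as.character(target)] <-
      max(cfg$base_onset_frames) + cfg$bump_frames
    on_frames <- unname(seg_base[as.character(aha)])
    onsets[i, ] <- on_frames * dt

    amp <- rep(1, n_sec)
    if (!is.null(cfg$scar_sectors))
      amp[cfg$scar_sectors] <- cfg$scar_attenuation
    M <- t(vapply(seq_len(n_sec), function(s) {
      amp[s] * ecc_waveform(t_ms, onsets[i, s], cfg$peak_strain,
                            cfg$rise_ms, cfg$recover_ms, cfg$recover_frac)
    }, numeric(nf)))
    if (cfg$noise_sd > 0)
      M <- M + matrix(stats::rnorm(n_sec * nf, 0, cfg$noise_sd), n_sec, nf)
    M[M > 0.6] <- 0.6; M[M < -0.6] <- -0.6
    strain_list[[i]] <- strain_matrix(M, dt, slice_vec, angle,
                                      patient_id = truth$patient_id[i])
  }
  list(strain = strain_list, truth = truth, onsets_ms = onsets,
       sector_aha = aha)
}

#' Configuration for the synthetic clinical cohort generator
#'
#' Group-specific covariate distributions default to the observed cohort:
#' three CRT groups (1 = de novo, 2 = upgrade with RV-pacing dependence,
#' 3 = upgrade without), skewed labs lognormal and parameterized by their
#' group medians, binary covariates by prevalence, and approximately
#' symmetric measures normal. Group-2 creatinine is the group-1 baseline
#' plus the additive mediation path `a`, so that
#' `E[creatinine | group 2] - E[creatinine | group 1] = a` exactly.
#' Survival arises from a latent Gaussian model on the time scale:
#' `T = intercept + c_direct * 1[group 2] + c_group3 * 1[group 3] +
#' b * creatinine + (optional prognostic terms) + Normal(0, sigma)`,
#' administratively censored at `censor_years` (plus optional uniform
#' early censoring). The direct effect default `c_direct = -1.447` is the
#' total effect -2.302 minus the mediated product a * b = -0.855.
#'
#' @param n_per_group integer vector of length 3; defaults 50/29/23.
#' @param age_median,age_sd per-group normal age parameters (years).
#' @param creatinine_median baseline (group 1) and group-3 lognormal
#'   medians, mg/dL; group 2 = group-1 draw + `a`.
#' @param creatinine_sdlog lognormal log-scale SD for creatinine (the
#'   default gives an SD of about 0.3 mg/dL at the group-1 median).
#' @param a exposure-to-mediator path: mean creatinine elevation in group
#'   2 relative to group 1, mg/dL.
#' @param bnp_median,bnp_sdlog per-group lognormal BNP parameters, pg/mL.
#' @param af_prev,cabg_prev per-group prevalences.
#' @param qrs_mean,qrs_sd,qlv_mean,qlv_sd per-group normal parameters, ms.
#' @param lvesvi_median,lvesvi_sdlog per-group lognormal pre-CRT LVESVI
#'   parameters, mL/m2.
#' @param tos_lead_median,tos_lead_sdlog per-group lognormal parameters
#'   for the TOS at the LV lead segment (ms; snapped to multiples of the
#'   frame interval when generated standalone).
#' @param lead_segment_probs named probabilities over AHA segments for the
#'   LV lead implant site.
#' @param b mediator-to-outcome path, years of survival per mg/dL.
#' @param c_direct direct effect of group 2 vs group 1, years.
#' @param c_group3 direct effect of group 3 vs group 1, years.
#' @param bnp_effect,cabg_effect,tos_effect optional additional prognostic
#'   paths (years per log-unit BNP; years for prior CABG; years for TOS at
#'   lead >= 34 ms). All default to 0 so the latent survival model is
#'   exactly the stated mediation structure.
#' @param survival_intercept latent-time intercept, years.
#' @param sigma outcome noise SD, years.
#' @param censor_years administrative censoring horizon, years.
#' @param early_censor_frac fraction of patients censored uniformly on
#'   (0, censor_years) instead of at the horizon.
#' @param response_assoc association between the latent survival time and
#'   the short-term response measures (SD units).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list of class `"cohort_gen_config"`.
#' @export
cohort_gen_config <- function(n_per_group = c(50L, 29L, 23L),
                              age_median = c(65.4, 74.0, 62.0),
                              age_sd = c(7.7, 11.1, 10.4),
                              creatinine_median = c(1.05, NA, 1.1),
                              creatinine_sdlog = 0.272,
                              a = 0.361,
                              bnp_median = c(210.5, 272, 304),
                              bnp_sdlog = c(0.658, 0.726, 0.332),
                              af_prev = c(0.22, 0.621, 0.174),
                              cabg_prev = c(0.22, 0.241, 0.391),
                              qrs_mean = c(160, 179, 152),
                              qrs_sd = c(25.0, 26.7, 23.7),
                              qlv_mean = c(112.5, 160, 108),
                              qlv_sd = c(43.5, 16.3, 20.8),
                              lvesvi_median = c(101.2, 71.3, 117.0),
                              lvesvi_sdlog = c(0.171, 0.220, 0.162),
                              tos_lead_median = c(106, 86, 78),
                              tos_lead_sdlog = c(0.35, 0.35, 0.30),
                              lead_segment_probs = c("1" = 0.10, "5" = 0.23,
                                                     "6" = 0.25, "11" = 0.12,
                                                     "12" = 0.30),
                              b = -2.37,
                              c_direct = -1.447,
                              c_group3 = -0.8,
                              bnp_effect = 0,
                              cabg_effect = 0,
                              tos_effect = 0,
                              survival_intercept = 9,
                              sigma = 1.5,
                              censor_years = 5,
                              early_censor_frac = 0,
                              response_assoc = 0.05,
                              seed = NULL) {
  cfg <- as.list(environment())
  if (length(n_per_group) != 3 || any(n_per_group < 0))
    stop("'n_per_group' must be 3 non-negative counts")
  for (p in c(cfg$af_prev, cfg$cabg_prev, early_censor_frac))
    if (p < 0 || p > 1) stop("prevalences and fractions must lie in [0, 1]")
  if (censor_years <= 0) stop("'censor_years' must be positive")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (any(c(creatinine_sdlog, bnp_sdlog, lvesvi_sdlog, age_sd,
            qrs_sd, qlv_sd) < 0))
    stop("scale parameters must be >= 0")
  class(cfg) <- "cohort_gen_config"
  cfg
}

#' Generate a synthetic three-group clinical cohort
#'
#' Draws patient-level covariates from the group-specific distributions of
#' a [cohort_gen_config()]. Survival and response columns are added by
#' [generate_outcomes()].
#'
#' @param cfg a [cohort_gen_config()].
#' @return data.frame with one row per patient: `patient_id`, `group`,
#'   `age`, `creatinine`, `bnp`, `af`, `cabg`, `qrs_ms`, `qlv_ms`,
#'   `lvesvi_pre`, `tos_lead_ms`, `tos_ge34`, `lead_segment`.
#' @export
generate_clinical_cohort <- function(cfg = cohort_gen_config()) {
  stopifnot(inherits(cfg, "cohort_gen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  g <- rep(1:3, cfg$n_per_group)
  n <- length(g)
  base_med <- cfg$creatinine_median[1]
  creat <- stats::rlnorm(n, log(ifelse(g == 3, cfg$creatinine_median[3],
                                       base_med)), cfg$creatinine_sdlog)
  creat <- creat + cfg$a * (g == 2)
  tos <- stats::rlnorm(n, log(cfg$tos_lead_median[g]), cfg$tos_lead_sdlog[g])
  tos <- round(tos / 17) * 17
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    group = g,
    age = stats::rnorm(n, cfg$age_median[g], cfg$age_sd[g]),
    creatinine = creat,
    bnp = stats::rlnorm(n, log(cfg$bnp_median[g]), cfg$bnp_sdlog[g]),
    af = stats::rbinom(n, 1, cfg$af_prev[g]),
    cabg = stats::rbinom(n, 1, cfg$cabg_prev[g]),
    qrs_ms = stats::rnorm(n, cfg$qrs_mean[g], cfg$qrs_sd[g]),
    qlv_ms = stats::rnorm(n, cfg$qlv_mean[g], cfg$qlv_sd[g]),
    lvesvi_pre = stats::rlnorm(n, log(cfg$lvesvi_median[g]),
                               cfg$lvesvi_sdlog[g]),
    tos_lead_ms = tos,
    tos_ge34 = as.integer(tos >= 34),
    lead_segment = as.integer(sample(names(cfg$lead_segment_probs), n,
                                     replace = TRUE,
                                     prob = cfg$lead_segment_probs)),
    stringsAsFactors = FALSE)
}

#' Add survival and post-CRT response outcomes to a cohort
#'
#' Inverts the censored Gaussian survival model used for analysis: the
#' latent survival time is linear in the group indicators, the mediator
#' (creatinine) and any optional prognostic terms, with Gaussian noise;
#' the observed time is the minimum of the latent time and the censoring
#' time, and the event flag marks death. Short-term response measures
#' (post-CRT LVESVI, BNP, change in peak VO2) are drawn with a
#' configurable association to the latent survival time.
#'
#' @param cohort data.frame from [generate_clinical_cohort()]; must
#'   contain `group` and `creatinine`.
#' @param cfg the [cohort_gen_config()] used to build it.
#' @return `cohort` with added columns `time_years`, `event`,
#'   `latent_time`, `alive_4y`, `lvesvi_post`, `lvesvi_fc`, `bnp_post`,
#'   `delta_peak_vo2`.
#' @export
generate_outcomes <- function(cohort, cfg = cohort_gen_config()) {
  stopifnot(inherits(cfg, "cohort_gen_config"))
  need <- c("group", "creatinine")
  if (!all(need %in% names(cohort)))
    stop("cohort lacks required columns: ",
         paste(setdiff(need, names(cohort)), collapse = ", "))
  n <- nrow(cohort)
  g <- cohort$group
  lp <- cfg$survival_intercept +
    cfg$c_direct * (g == 2) + cfg$c_group3 * (g == 3) +
    cfg$b * cohort$creatinine
  if (cfg$bnp_effect != 0 && "bnp" %in% names(cohort))
    lp <- lp + cfg$bnp_effect * (log(cohort$bnp) - log(272))
  if (cfg$cabg_effect != 0 && "cabg" %in% names(cohort))
    lp <- lp + cfg$cabg_effect * cohort$cabg
  if (cfg$tos_effect != 0 && "tos_ge34" %in% names(cohort))
    lp <- lp + cfg$tos_effect * cohort$tos_ge34
  latent <- lp + stats::rnorm(n, 0, cfg$sigma)
  cens <- rep(cfg$censor_years, n)
  if (cfg$early_censor_frac > 0) {
    early <- stats::runif(n) < cfg$early_censor_frac
    cens[early] <- stats::runif(sum(early), 0, cfg$censor_years)
  }
  # observed follow-up cannot be negative: the rare latent times below
  # zero are recorded as death on the first day
  time <- pmin(pmax(latent, 1 / 365), cens)
  event <- as.integer(latent <= cens)

  z <- if (stats::sd(latent) > 0) as.numeric(scale(latent)) else rep(0, n)
  fc_mu <- c(-0.18, -0.21, -0.20)[g]
  fc <- stats::rnorm(n, fc_mu, 0.15) - cfg$response_assoc * z
  lvesvi_post <- if ("lvesvi_pre" %in% names(cohort))
    cohort$lvesvi_pre * (1 + fc) else NA_real_
  bnp_post <- if ("bnp" %in% names(cohort))
    cohort$bnp * stats::rlnorm(n, log(0.7), 0.5) else NA_real_

  cohort$latent_time <- latent
  cohort$time_years <- time
  cohort$event <- event
  cohort$alive_4y <- as.integer(!(event == 1 & time <= 4))
  cohort$lvesvi_fc <- fc
  cohort$lvesvi_post <- lvesvi_post
  cohort$bnp_post <- bnp_post
  cohort$delta_peak_vo2 <- stats::rnorm(n, c(0.40, -0.26, 0.075)[g], 1.5) +
    0.3 * cfg$response_assoc * z
  cohort
}
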