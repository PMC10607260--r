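test_that("strain_matrix validates geometry and values", {
  g <- default_geometry()
  M <- matrix(0.1, 36, 30)
  expect_s3_class(strain_matrix(M, 17, g$slice, g$angle), "strain_matrix")
  expect_error(strain_matrix(M * 10, 17, g$slice, g$angle), "range")
  expect_error(strain_matrix(M[, 1:5], 17, g$slice, g$angle), "8 time frames")
  expect_error(strain_matrix(M, 0, g$slice, g$angle), "positive")
  bad <- g$angle; bad[2] <- bad[1]
  expect_error(strain_matrix(M, 17, g$slice, bad), "increasing")
  expect_error(strain_matrix(M[1:3, ], 17, g$slice[1:3], g$angle[1:3]),
               "4 sectors")
})

test_that("CURE-SVD hits its analytic limits", {
  expect_equal(compute_cure_svd(uniform_strain()), 1.0)
  g <- default_geometry()
  M <- outer(sin(g$angle * pi / 180), ref_curve(0))
  sm <- strain_matrix(M, 17, g$slice, g$angle)
  expect_equal(compute_cure_svd(sm), 0, tolerance = 1e-10)
  expect_error(
    compute_cure_svd(strain_matrix(matrix(0, 36, 30), 17, g$slice, g$angle)),
    "degenerate")
})

test_that("CURE-SVD matches the frame-wise Fourier oracle on delayed blocks", {
  # two opposing sector blocks delayed by half a cycle
  g <- default_geometry()
  on <- ifelse(((g$angle %/% 30) %% 12) < 6, 0, 136)
  sm <- onset_strain(on)
  expect_equal(compute_cure_svd(sm), cure_framewise_oracle(sm),
               tolerance = 1e-10)
  withr::with_seed(21, {
    for (i in 1:10) {
      sm <- random_strain()
      expect_equal(compute_cure_svd(sm), cure_framewise_oracle(sm),
                   tolerance = 1e-10)
    }
  })
})

test_that("CURE-SVD is invariant to rescaling, rotation and sign flip", {
  withr::with_seed(7, {
    for (i in 1:25) {
      sm <- random_strain()
      v <- compute_cure_svd(sm)
      expect_gte(v, 0); expect_lte(v, 1)
      sm2 <- sm; sm2$ecc <- sm$ecc * 0.31
      expect_equal(compute_cure_svd(sm2), v, tolerance = 1e-9)
      sm3 <- sm; sm3$ecc <- -sm$ecc
      expect_equal(compute_cure_svd(sm3), v, tolerance = 1e-9)
      # rotate sector labels by one full position within each slice
      sm4 <- sm
      for (s in unique(sm$geometry$slice)) {
        idx <- which(sm$geometry$slice == s)
        sm4$ecc[idx, ] <- sm$ecc[idx[c(length(idx), 1:(length(idx) - 1))], ]
      }
      expect_equal(compute_cure_svd(sm4), v, tolerance = 1e-9)
    }
  })
})

test_that("onset detection is exact on noiseless constructed curves", {
  g <- default_geometry()
  # flat, then a gentle strict decline starting after frame 3 -> 51 ms
  M <- matrix(rep(c(rep(0, 4), -0.01 * (1:26)), each = 36), 36, 30)
  m <- detect_activation_times(strain_matrix(M, 17, g$slice, g$angle))
  expect_true(all(m$sector_tos$tos_ms == 51))
  expect_true(all(m$segment_tos$tos_ms == 51))
  # shortening from frame 0 -> 0 ms everywhere
  m0 <- detect_activation_times(uniform_strain(onset_ms = 0))
  expect_true(all(m0$sector_tos$tos_ms == 0))
  # flat matrix: all sectors flagged at the maximal time
  mf <- detect_activation_times(
    strain_matrix(matrix(0, 36, 30), 17, g$slice, g$angle))
  expect_true(all(!mf$sector_tos$reliable))
  expect_true(all(mf$sector_tos$tos_ms == 29 * 17))
  expect_error(classify_latest_activation(mf), "unavailable")
})

test_that("TOS is quantized to the frame grid and monotone in true onset", {
  dt <- 17
  withr::with_seed(3, {
    cfg <- strain_gen_config(n_patients_per_group = c(2, 2, 2),
                             noise_sd = 0.01)
    ds <- generate_strain_dataset(cfg)
    for (s in ds$strain) {
      m <- detect_activation_times(s)
      expect_true(all(m$sector_tos$tos_ms %% dt == 0))
      expect_true(all(m$segment_tos$tos_ms %% dt == 0))
    }
  })
  # delaying one sector's onset never decreases its detected TOS
  base <- rep(17, 36)
  prev <- -Inf
  for (f in 0:6) {
    on <- base; on[5] <- f * dt
    m <- detect_activation_times(onset_strain(on))
    expect_gte(m$sector_tos$tos_ms[5], prev)
    prev <- m$sector_tos$tos_ms[5]
  }
})

test_that("segment TOS recovers generator ground truth under noise", {
  cfg <- strain_gen_config(n_patients_per_group = c(14, 13, 13),
                           noise_sd = 0.01, seed = 88)
  ds <- generate_strain_dataset(cfg)
  errs <- unlist(lapply(seq_along(ds$strain), function(i) {
    m <- detect_activation_times(ds$strain[[i]])
    truth <- tapply(ds$onsets_ms[i, ], ds$sector_aha,
                    function(x) sort(x)[ceiling(length(x) / 2)])
    m$segment_tos$tos_ms - truth[as.character(m$segment_tos$aha)]
  }))
  expect_gte(mean(abs(errs) <= 17), 0.95)
})

test_that("latest-activation classification follows the AHA convention", {
  tab <- crtcmr:::aha_segment_table()
  expect_equal(tab$region[1], "anterior")
  expect_equal(tab$level[1], "basal")
  expect_equal(tab$region[12], "anterolateral")
  expect_equal(tab$level[12], "mid-ventricular")
  # build a map whose max TOS sits in a chosen segment
  for (target in c(1L, 12L)) {
    on <- rep(0, 36)
    sa <- mapply(crtcmr:::sector_aha_id, default_geometry()$slice,
                 default_geometry()$angle)
    on[sa == target] <- 102
    m <- detect_activation_times(onset_strain(on))
    cl <- classify_latest_activation(m)
    expect_equal(cl$aha, target)
    expect_equal(cl$region, tab$region[target])
    expect_equal(cl$level, tab$level[target])
  }
})

test_that("group 2 shows the anterior latest-activation shift", {
  cfg <- strain_gen_config(n_patients_per_group = c(100, 100, 0),
                           noise_sd = 0.01, seed = 404)
  ds <- generate_strain_dataset(cfg)
  reg <- vapply(ds$strain, function(s)
    classify_latest_activation(detect_activation_times(s))$region,
    character(1))
  ant1 <- mean(reg[ds$truth$group == 1] == "anterior")
  ant2 <- mean(reg[ds$truth$group == 2] == "anterior")
  expect_gt(ant2, ant1)
  expect_gt(ant2, 0.3)  # seeded at 48.3%
  expect_lt(ant1, 0.25) # seeded at 10%
})

test_that("activation_at_segment applies the inclusive 34 ms rule", {
  on <- rep(0, 36)
  sa <- mapply(crtcmr:::sector_aha_id, default_geometry()$slice,
               default_geometry()$angle)
  for (tos in c(51, 34, 17)) {
    on2 <- on; on2[sa == 7] <- tos
    m <- detect_activation_times(onset_strain(on2),
                                 detection_params(spatial_radius = 0))
    at <- activation_at_segment(m, 7)
    expect_equal(at$tos_ms, tos)
    expect_equal(at$favorable, tos >= 34)
  }
  m <- detect_activation_times(uniform_strain())
  expect_error(activation_at_segment(m, 18), "1..17")
})

test_that("strain CSV round-trips", {
  sm <- uniform_strain(onset_ms = 51)
  path <- withr::local_tempfile(fileext = ".csv")
  write_strain_csv(sm, path)
  back <- read_strain_csv(path, patient_id = "X")
  expect_equal(back$ecc, sm$ecc, ignore_attr = TRUE)
  expect_equal(back$frame_interval_ms, 17)
  expect_equal(back$geometry$slice, sm$geometry$slice)
})
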