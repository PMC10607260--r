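#' Construct a regional circumferential strain matrix
#'
#' Bundles a sectors-by-frames matrix of circumferential Lagrangian strain
#' (E_cc, dimensionless; negative values indicate myocardial shortening)
#' with its acquisition geometry: the short-axis slice each sector belongs
#' to, its angular position, and the frame interval.
#'
#' @param ecc numeric matrix, rows = myocardial sectors, columns = time
#'   frames. Values must be finite and within \[-0.6, 0.6\].
#' @param frame_interval_ms time between frames in milliseconds (> 0).
#' @param slice character or factor of length `nrow(ecc)`; one of
#'   `"basal"`, `"mid"`, `"apical"`.
#' @param angle_deg numeric angular position of each sector centre in
#'   degrees, strictly increasing within a slice. The angular origin (0
#'   degrees) is the anterior RV-LV insertion, proceeding counterclockwise
#'   in the standard short-axis view.
#' @param patient_id optional identifier carried through to outputs.
#' @return an object of class `"strain_matrix"`.
#' @export
strain_matrix <- function(ecc, frame_interval_ms, slice, angle_deg,
                          patient_id = NA_character_) {
  ecc <- as.matrix(ecc)
  if (!is.numeric(ecc) || any(!is.finite(ecc)))
    stop("'ecc' must be a finite numeric matrix")
  if (any(abs(ecc) > 0.6))
    stop("strain values outside the physiological range [-0.6, 0.6]")
  if (ncol(ecc) < 8)
    stop("at least 8 time frames are required")
  if (!is.numeric(frame_interval_ms) || length(frame_interval_ms) != 1 ||
      frame_interval_ms <= 0)
    stop("'frame_interval_ms' must be a single positive number")
  slice <- as.character(slice)
  if (length(slice) != nrow(ecc) || length(angle_deg) != nrow(ecc))
    stop("'slice' and 'angle_deg' must have one entry per sector")
  if (!all(slice %in% c("basal", "mid", "apical")))
    stop("'slice' entries must be 'basal', 'mid' or 'apical'")
  for (s in unique(slice)) {
    idx <- which(slice == s)
    if (length(idx) < 4)
      stop("each slice needs at least 4 sectors")
    if (any(diff(angle_deg[idx]) <= 0))
      stop("'angle_deg' must be strictly increasing within a slice")
  }
  structure(
    list(ecc = ecc, frame_interval_ms = frame_interval_ms,
         geometry = data.frame(slice = slice, angle_deg = angle_deg),
         patient_id = patient_id),
    class = "strain_matrix")
}

#' @export
print.strain_matrix <- function(x, ...) {
  cat("Regional E_cc strain matrix", if (!is.na(x$patient_id))
    paste0("(", x$patient_id, ")"), "\n")
  cat(sprintf("  %d sectors x %d frames, frame interval %g ms\n",
              nrow(x$ecc), ncol(x$ecc), x$frame_interval_ms))
  cat("  slices:", paste(sprintf("%s (%d)", names(table(x$geometry$slice)),
                                 table(x$geometry$slice)), collapse = ", "), "\n")
  invisible(x)
}

#' Detection parameters for the onset-of-shortening detector
#'
#' @param slope_threshold minimum magnitude of the negative forward
#'   difference (strain units per frame) that counts as shortening.
#' @param persistence number of consecutive frames the slope criterion
#'   must hold (the default of 3 rejects isolated noise-driven dips while
#'   leaving detection on clean monotone descents unchanged).
#' @param smooth_window width (frames, odd) of the centred moving average
#'   applied to each sector curve before differencing.
#' @param spatial_radius radius (sectors) of the circular median filter
#'   applied to the detected onset field within each slice; 0 disables it.
#' @return a list of class `"detection_params"`.
#' @export
detection_params <- function(slope_threshold = 0.005, persistence = 3,
                             smooth_window = 3, spatial_radius = 1) {
  if (slope_threshold <= 0) stop("'slope_threshold' must be positive")
  if (persistence < 1) stop("'persistence' must be >= 1")
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop("'smooth_window' must be a positive odd integer")
  if (spatial_radius < 0) stop("'spatial_radius' must be >= 0")
  structure(list(slope_threshold = slope_threshold,
                 persistence = as.integer(persistence),
                 smooth_window = as.integer(smooth_window),
                 spatial_radius = as.integer(spatial_radius)),
            class = "detection_params")
}

# AHA 17-segment model: ids 1-6 basal, 7-12 mid, 13-16 apical; the true
# apex (17) has no short-axis sectors and is never assigned.
aha_segment_table <- function() {
  data.frame(
    aha = 1:17,
    level = c(rep("basal", 6), rep("mid-ventricular", 6),
              rep("apical", 4), "apex"),
    region = c(rep(c("anterior", "anteroseptal", "inferoseptal", "inferior",
                     "inferolateral", "anterolateral"), 2),
               "anterior", "anteroseptal", "inferior", "anterolateral",
               "apex"),
    stringsAsFactors = FALSE)
}

# Map a sector (slice, angle) to its AHA segment id. Basal and mid rings
# split into six 60-degree segments, the apical ring into four 90-degree
# segments. Angle 0 = anterior RV-LV insertion, counterclockwise; the
# anterolateral segment spans [0, 60) so that the anterior segment is
# centred on the anterior wall at [60, 120).
sector_aha_id <- function(slice, angle_deg) {
  a <- angle_deg %% 360
  if (slice %in% c("basal", "mid")) {
    reg <- findInterval(a, c(0, 60, 120, 180, 240, 300, 360),
                        rightmost.closed = TRUE)
    seg6 <- c(6L, 1L, 2L, 3L, 4L, 5L)[reg]  # anterolateral first at 0 deg
    if (slice == "basal") seg6 else seg6 + 6L
  } else {
    # apical: anterior [45,135), septal [135,225), inferior [225,315),
    # lateral elsewhere
    if (a >= 45 && a < 135) 13L
    else if (a >= 135 && a < 225) 14L
    else if (a >= 225 && a < 315) 15L
    else 16L
  }
}

#' Compute the CURE-SVD dyssynchrony index
#'
#' The circumferential uniformity ratio estimate on the dominant singular
#' component (CURE-SVD) summarises mechanical dyssynchrony from a
#' sectors-by-frames E_cc matrix. The matrix is reduced to its rank-1
#' spatial pattern (the leading left singular vector); within each slice
#' the spatial discrete-Fourier power at harmonic 0 (uniform contraction)
#' and harmonic 1 (one-cycle dyssynchrony) of the circumferentially
#' ordered pattern is computed, powers are summed over slices, and the
#' index is `sqrt(sum(A0) / sum(A0 + A1))`. It ranges from 0 (pure
#' first-harmonic, maximally dyssynchronous) to 1 (perfectly uniform,
#' synchronous), and is invariant to strain rescaling, sector-label
#' rotation by a full revolution, and sign flips.
#'
#' @param strain a [strain_matrix()].
#' @return a single number in \[0, 1\].
#' @export
compute_cure_svd <- function(strain) {
  stopifnot(inherits(strain, "strain_matrix"))
  M <- strain$ecc
  if (all(M == 0))
    stop("degenerate strain matrix (all zeros): CURE-SVD undefined")
  u1 <- svd(M, nu = 1, nv = 0)$u[, 1]
  a0 <- 0; a1 <- 0
  for (s in unique(strain$geometry$slice)) {
    idx <- which(strain$geometry$slice == s)
    idx <- idx[order(strain$geometry$angle_deg[idx])]
    v <- u1[idx]
    X <- stats::fft(v)
    a0 <- a0 + Mod(X[1])^2
    a1 <- a1 + Mod(X[2])^2
  }
  if (a0 + a1 == 0)
    stop("dominant spatial pattern has no power at harmonics 0 or 1")
  sqrt(a0 / (a0 + a1))
}

# centred moving average with shrinking window at the edges
smooth_ma <- function(x, window) {
  if (window <= 1) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# circular median filter within one slice over circumferential order
median_filter_circular <- function(x, radius) {
  if (radius <= 0) return(x)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- ((i - radius):(i + radius) - 1L) %% n + 1L
    out[i] <- stats::median(x[idx])
  }
  out
}

# lower median: keeps values on the frame grid when n is even
median_low <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Detect mechanical activation times (time to onset of shortening)
#'
#' Computes the per-sector time to the onset of circumferential shortening
#' (TOS): each sector curve is smoothed with a centred moving average and
#' the onset is the first frame at which the forward difference falls below
#' `-slope_threshold` for `persistence` consecutive frames. The onset field
#' is spatially regularised with a circular median filter within each slice,
#' then aggregated to AHA-17 segments by the (lower) median of member
#' sectors. Sectors that never meet the slope criterion are assigned the
#' maximal time `(n_frames - 1) * frame_interval_ms` and flagged
#' unreliable, so downstream cutoffs remain computable.
#'
#' @param strain a [strain_matrix()].
#' @param params a [detection_params()].
#' @return an object of class `"activation_map"` with components
#'   `sector_tos` (data.frame: slice, angle_deg, aha, tos_ms, reliable),
#'   `segment_tos` (data.frame: aha, region, level, tos_ms, n_sectors,
#'   reliable) and `frame_interval_ms`.
#' @export
detect_activation_times <- function(strain, params = detection_params()) {
  stopifnot(inherits(strain, "strain_matrix"))
  if (!inherits(params, "detection_params"))
    stop("'params' must be a detection_params object")
  M <- strain$ecc
  dt <- strain$frame_interval_ms
  nf <- ncol(M)
  ns <- nrow(M)
  tmax <- (nf - 1) * dt

  tos <- numeric(ns)
  reliable <- logical(ns)
  for (i in seq_len(ns)) {
    sm <- smooth_ma(M[i, ], params$smooth_window)
    d <- diff(sm)
    hit <- d < -params$slope_threshold
    f0 <- NA_integer_
    if (params$persistence == 1) {
      w <- which(hit)
      if (length(w)) f0 <- w[1] - 1L
    } else {
      run <- 0L
      for (f in seq_along(hit)) {
        run <- if (hit[f]) run + 1L else 0L
        if (run >= params$persistence) { f0 <- f - params$persistence; break }
      }
    }
    if (is.na(f0)) {
      tos[i] <- tmax; reliable[i] <- FALSE
    } else {
      tos[i] <- f0 * dt; reliable[i] <- TRUE
    }
  }

  geo <- strain$geometry
  if (params$spatial_radius > 0) {
    for (s in unique(geo$slice)) {
      idx <- which(geo$slice == s)
      idx <- idx[order(geo$angle_deg[idx])]
      tos[idx] <- median_filter_circular(tos[idx], params$spatial_radius)
    }
  }

  aha <- mapply(sector_aha_id, geo$slice, geo$angle_deg)
  sector_tos <- data.frame(slice = geo$slice, angle_deg = geo$angle_deg,
                           aha = aha, tos_ms = tos, reliable = reliable)

  segs <- sort(unique(aha))
  aha_tab <- aha_segment_table()
  segment_tos <- do.call(rbind, lapply(segs, function(g) {
    m <- sector_tos$aha == g
    data.frame(aha = g,
               region = aha_tab$region[g],
               level = aha_tab$level[g],
               tos_ms = median_low(sector_tos$tos_ms[m]),
               n_sectors = sum(m),
               reliable = mean(sector_tos$reliable[m]) >= 0.5)
  }))
  structure(list(sector_tos = sector_tos, segment_tos = segment_tos,
                 frame_interval_ms = dt, n_frames = nf,
                 patient_id = strain$patient_id),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat("Mechanical activation (TOS) map",
      if (!is.na(x$patient_id)) paste0("(", x$patient_id, ")"), "\n")
  cat(sprintf("  %d sectors, %d AHA segments, frame interval %g ms\n",
              nrow(x$sector_tos), nrow(x$segment_tos), x$frame_interval_ms))
  print(x$segment_tos, row.names = FALSE)
  invisible(x)
}

#' Classify the location of latest mechanical activation
#'
#' Returns the circumferential region and longitudinal level of the AHA
#' segment with the largest TOS. Ties are broken by the lowest AHA id;
#' segments flagged unreliable are excluded.
#'
#' @param map an `"activation_map"` from [detect_activation_times()].
#' @return list with `aha`, `region`, `level`, `tos_ms`.
#' @export
classify_latest_activation <- function(map) {
  stopifnot(inherits(map, "activation_map"))
  st <- map$segment_tos[map$segment_tos$reliable, , drop = FALSE]
  if (nrow(st) == 0)
    stop("all segments flagged unreliable: latest activation unavailable")
  st <- st[order(st$aha), ]
  i <- which.max(st$tos_ms)  # first max = lowest AHA id on ties
  list(aha = st$aha[i], region = st$region[i], level = st$level[i],
       tos_ms = st$tos_ms[i])
}

#' Mechanical activation at the LV pacing segment
#'
#' Looks up the segment-level TOS at the LV lead implant segment and flags
#' whether it meets the favorable threshold (boundary inclusive: TOS at or
#' above the cutoff is favorable).
#'
#' @param map an `"activation_map"`.
#' @param lead_segment AHA segment id of the LV lead (1-17).
#' @param cutoff_ms favorable threshold in ms (default 34).
#' @return list with `tos_ms`, `favorable`, `reliable`.
#' @export
activation_at_segment <- function(map, lead_segment, cutoff_ms = 34) {
  stopifnot(inherits(map, "activation_map"))
  if (!lead_segment %in% 1:17)
    stop("'lead_segment' must be an AHA id in 1..17")
  row <- map$segment_tos[map$segment_tos$aha == lead_segment, ]
  if (nrow(row) == 0)
    stop("no sectors map to AHA segment ", lead_segment)
  list(tos_ms = row$tos_ms, favorable = row$tos_ms >= cutoff_ms,
       reliable = row$reliable)
}

#' Write / read a strain matrix as delimited text
#'
#' The CSV layout has a header row of frame times in ms and one row per
#' sector with leading `slice` and `angle_deg` columns.
#'
#' @param strain a [strain_matrix()].
#' @param path file path.
#' @return `read_strain_csv` returns a [strain_matrix()];
#'   `write_strain_csv` returns `path` invisibly.
#' @export
write_strain_csv <- function(strain, path) {
  stopifnot(inherits(strain, "strain_matrix"))
  times <- (seq_len(ncol(strain$ecc)) - 1) * strain$frame_interval_ms
  df <- data.frame(slice = strain$geometry$slice,
                   angle_deg = strain$geometry$angle_deg,
                   strain$ecc, check.names = FALSE)
  names(df)[-(1:2)] <- times
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_strain_csv
#' @param patient_id identifier attached to the matrix read back.
#' @export
read_strain_csv <- function(path, patient_id = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  times <- as.numeric(names(df)[-(1:2)])
  dt <- unique(round(diff(times), 10))
  if (length(dt) != 1)
    stop("frame times in the header must be evenly spaced")
  strain_matrix(as.matrix(df[, -(1:2)]), frame_interval_ms = dt,
                slice = df$slice, angle_deg = df$angle_deg,
                patient_id = patient_id)
}
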