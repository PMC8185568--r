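#' Sliding-window configuration
#'
#' Fixed-length analysis windows of `window_s` seconds advanced by a
#' `step_s` stride. At the defaults (3 s window, 0.25 s step, 128 Hz) every
#' window spans 384 samples and consecutive windows share 2.75 s, giving
#' one class decision every 0.25 s.
#'
#' @param window_s Window length in seconds (default 3).
#' @param step_s Step (stride) between window starts in seconds
#'   (default 0.25).
#' @param fs Sampling rate in Hz (default 128).
#' @return An object of class `window_config` with the derived sample
#'   counts `window_n = round(window_s * fs)` and `step_n = round(step_s * fs)`.
#' @export
window_config <- function(window_s = 3, step_s = 0.25, fs = 128) {
  window_n <- as.integer(round(window_s * fs))
  step_n <- as.integer(round(step_s * fs))
  if (step_n < 1L) stop("step_s too small: step_n must be >= 1 sample")
  if (window_n < step_n) stop("window_n must be >= step_n")
  structure(list(window_s = window_s, step_s = step_s, fs = fs,
                 window_n = window_n, step_n = step_n),
            class = "window_config")
}

#' Number of sliding windows in a recording
#'
#' `K = floor((N - window_n) / step_n) + 1` for `N >= window_n`, else 0.
#'
#' @param n_samples Number of samples N in the recording.
#' @param config A [window_config].
#' @return Integer window count K.
#' @examples
#' count_windows(1280, window_config())  # 29
#' @export
count_windows <- function(n_samples, config = window_config()) {
  if (n_samples < config$window_n) return(0L)
  as.integer((n_samples - config$window_n) %/% config$step_n + 1L)
}

#' Cohort-wide per-channel normalization scales
#'
#' For each of the six channels, the maximum absolute value observed across
#' every recording in the cohort. Dividing by these scales maps all cohort
#' data into `[-1, 1]`, with the channel extreme mapping to exactly +/-1.
#'
#' @param recordings List of [imu_recording] objects.
#' @return Named numeric vector of length 6 (class `fog_scales`).
#' @export
cohort_scales <- function(recordings) {
  if (length(recordings) < 1L) stop("need at least one recording")
  stopifnot(all(vapply(recordings, inherits, logical(1), "imu_recording")))
  maxes <- vapply(recordings,
                  function(r) apply(abs(r$samples), 2, max),
                  numeric(6))
  s <- apply(matrix(maxes, nrow = 6), 1, max)
  names(s) <- IMU_CHANNELS
  zero <- names(s)[s == 0]
  if (length(zero) > 0)
    stop("channel(s) identically zero across the cohort: ",
         paste(zero, collapse = ", "))
  structure(s, class = "fog_scales")
}

#' Normalize a recording by cohort scales
#'
#' Each value is divided by its channel's cohort maximum-absolute scale and
#' rounded half-to-even to `digits` decimals (4 by default, the storage
#' precision of the pipeline). After normalization all values lie in
#' `[-1, 1]` up to rounding.
#'
#' @param recording An [imu_recording].
#' @param scales A [cohort_scales] vector (or any positive numeric
#'   6-vector).
#' @param digits Decimal places retained (default 4).
#' @return A normalized [imu_recording] with unit metadata `"normalized"`.
#' @export
normalize_recording <- function(recording, scales, digits = 4) {
  stopifnot(inherits(recording, "imu_recording"))
  scales <- as.numeric(scales)
  if (length(scales) != 6L || any(!is.finite(scales)) || any(scales <= 0))
    stop("'scales' must be 6 positive finite numbers")
  x <- round(sweep(recording$samples, 2, scales, "/"), digits)
  imu_recording(x, recording$subject_id, fs = recording$fs,
                units = c(accel = "normalized", gyro = "normalized"))
}

#' Segment a recording into sliding windows
#'
#' Window k (k = 0, 1, ...) starts at sample index `k * step_n` (0-based)
#' and covers `window_n` consecutive samples. Exactly
#' [count_windows]`(N, config)` windows are produced.
#'
#' @param recording An [imu_recording] (normally already normalized).
#' @param config A [window_config].
#' @return List with `start_index` (integer vector, 0-based sample starts)
#'   and `data` (array K x window_n x 6).
#' @export
segment_recording <- function(recording, config = window_config()) {
  stopifnot(inherits(recording, "imu_recording"))
  n <- nrow(recording$samples)
  k <- count_windows(n, config)
  if (k == 0L)
    return(list(start_index = integer(0),
                data = array(numeric(0), dim = c(0, config$window_n, 6))))
  starts0 <- (seq_len(k) - 1L) * config$step_n
  rows <- outer(starts0, seq_len(config$window_n), "+")  # K x window_n
  dat <- array(recording$samples[as.vector(rows), ],
               dim = c(k, config$window_n, 6))
  list(start_index = starts0, data = dat)
}

# Total overlap (seconds) between half-open [a1, a2) and each half-open
# annotation interval, returned per interval.
.interval_overlaps <- function(a1, a2, starts, ends) {
  pmax(0, pmin(a2, ends) - pmax(a1, starts))
}

#' Label one window span from an annotation track
#'
#' A window is labeled `FOG` when either (a) at least one FoG episode lies
#' entirely inside the window — regardless of how short, so that brief
#' episodes are captured — or (b) the total FoG time inside the window is
#' at least half the window length (1.5 s at defaults). Otherwise the
#' window takes the non-FoG class (`STOP` or `WALK`) with the larger
#' overlap, ties going to `WALK`. Intervals and the window are half-open.
#'
#' `fog_rule = "episode"` switches rule (b) to the alternative reading in
#' which a partially covered episode confers the FoG label when the
#' episode's own duration is at least half the window, however little of it
#' falls inside.
#'
#' @param start_s,end_s Window span in seconds.
#' @param track An [annotation_track] covering the span.
#' @param config A [window_config] (supplies the half-window threshold).
#' @param fog_rule `"overlap"` (default) or `"episode"`; see Details.
#' @return One of `"FOG"`, `"STOP"`, `"WALK"`.
#' @export
label_window <- function(start_s, end_s, track, config = window_config(),
                         fog_rule = c("overlap", "episode")) {
  fog_rule <- match.arg(fog_rule)
  stopifnot(inherits(track, "annotation_track"))
  iv <- track$intervals
  if (nrow(iv) == 0L)
    stop("window outside annotation coverage: track is empty")
  eps <- 1e-9
  if (start_s < min(iv$start_s) - eps || end_s > max(iv$end_s) + eps)
    stop(sprintf("window [%g, %g) outside annotation coverage [%g, %g)",
                 start_s, end_s, min(iv$start_s), max(iv$end_s)))
  ov <- .interval_overlaps(start_s, end_s, iv$start_s, iv$end_s)
  is_fog <- iv$label == "FOG"
  half <- config$window_s / 2
  contained <- is_fog & iv$start_s >= start_s - eps & iv$end_s <= end_s + eps &
    ov > 0
  fog_hit <- any(contained) ||
    if (fog_rule == "overlap") {
      sum(ov[is_fog]) >= half - eps
    } else {
      any(is_fog & ov > eps & (iv$end_s - iv$start_s) >= half - eps)
    }
  if (fog_hit) return("FOG")
  stop_ov <- sum(ov[iv$label == "STOP"])
  walk_ov <- sum(ov[iv$label == "WALK"])
  if (stop_ov > walk_ov) "STOP" else "WALK"
}

#' Build a labeled window dataset from a cohort
#'
#' Runs the full preparation pipeline: compute (or reuse) cohort
#' normalization scales, normalize every recording, segment it into
#' sliding windows and label each window from its subject's annotation
#' track.
#'
#' @param recordings List of [imu_recording] objects.
#' @param tracks List of [annotation_track] objects, one per recording,
#'   with matching `subject_id`s.
#' @param config A [window_config].
#' @param scales Optional precomputed [cohort_scales]; computed from
#'   `recordings` when `NULL`.
#' @param fog_rule Passed to [label_window].
#' @param verbose Print a per-class summary (default `TRUE`).
#' @return An object of class `fog_windows`: list with `data`
#'   (n x window_n x 6 array), `label` (factor with levels FOG, STOP,
#'   WALK), `subject` (character), `start_index` (0-based sample index),
#'   `config`, `scales`, `fog_rule`.
#' @export
build_windows <- function(recordings, tracks, config = window_config(),
                          scales = NULL, fog_rule = "overlap",
                          verbose = TRUE) {
  if (length(recordings) != length(tracks))
    stop("need one annotation track per recording")
  rec_ids <- vapply(recordings, `[[`, character(1), "subject_id")
  trk_ids <- vapply(tracks, `[[`, character(1), "subject_id")
  if (!identical(rec_ids, trk_ids))
    stop("subject_id mismatch between recordings and tracks: ",
         paste(rec_ids[rec_ids != trk_ids], collapse = ", "))
  if (is.null(scales)) scales <- cohort_scales(recordings)
  per <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- normalize_recording(recordings[[i]], scales)
    seg <- segment_recording(rec, config)
    k <- length(seg$start_index)
    labs <- character(k)
    for (j in seq_len(k)) {
      s <- seg$start_index[j] / config$fs
      labs[j] <- label_window(s, s + config$window_s, tracks[[i]],
                              config, fog_rule)
    }
    per[[i]] <- list(data = seg$data, start_index = seg$start_index,
                     label = labs, subject = rep(rec_ids[i], k))
  }
  n <- sum(vapply(per, function(p) length(p$label), integer(1)))
  data <- array(NA_real_, dim = c(n, config$window_n, 6))
  label <- character(n); subject <- character(n); start_index <- integer(n)
  at <- 0L
  for (p in per) {
    k <- length(p$label)
    if (k > 0L) {
      data[at + seq_len(k), , ] <- p$data
      label[at + seq_len(k)] <- p$label
      subject[at + seq_len(k)] <- p$subject
      start_index[at + seq_len(k)] <- p$start_index
      at <- at + k
    }
  }
  out <- structure(
    list(data = data,
         label = factor(label, levels = FOG_CLASSES),
         subject = subject, start_index = start_index,
         config = config, scales = scales, fog_rule = fog_rule),
    class = "fog_windows")
  if (verbose) {
    counts <- table(out$label)
    message(sprintf("built %d windows from %d subject(s): %s", n,
                    length(recordings),
                    paste(sprintf("%s=%d", names(counts), counts),
                          collapse = ", ")))
  }
  out
}

#' @export
print.fog_windows <- function(x, ...) {
  cat(sprintf("fog_windows: %d windows of %d samples x 6 channels from %d subject(s)\n",
              length(x$label), x$config$window_n,
              length(unique(x$subject))))
  print(table(x$label))
  invisible(x)
}

#' Subset a window dataset
#'
#' @param x A `fog_windows` object.
#' @param i Index vector over windows.
#' @param ... Unused.
#' @return A `fog_windows` holding the selected windows.
#' @export
`[.fog_windows` <- function(x, i, ...) {
  structure(
    list(data = x$data[i, , , drop = FALSE],
         label = x$label[i], subject = x$subject[i],
         start_index = x$start_index[i],
         config = x$config, scales = x$scales, fog_rule = x$fog_rule),
    class = "fog_windows")
}

#' Export a window manifest
#'
#' Writes one row per window (`subject_id`, `start_index`, `label`) as CSV;
#' the window matrices themselves are reproducible from the recording CSVs
#' plus the manifest.
#'
#' @param windows A `fog_windows` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_window_manifest <- function(windows, path) {
  stopifnot(inherits(windows, "fog_windows"))
  utils::write.csv(
    data.frame(subject_id = windows$subject,
               start_index = windows$start_index,
               label = as.character(windows$label)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
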