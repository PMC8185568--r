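#' Streaming window-by-window inference
#'
#' Emulates on-line use of a trained window classifier on a continuous
#' recording: one class decision every `step_s` (0.25 s at defaults) once
#' the first full 3-second window has been buffered, so the first
#' decision falls at t = 3.0 s. The decision at time t uses only samples
#' up to t (the window `(t - window_s, t]`), and normalization uses the
#' cohort scales stored in the model checkpoint — a training-time
#' constant, so no look-ahead is involved. On a complete recording the
#' emitted labels equal batch [segment_recording] + [predict.fog_cnn] on
#' the same windows.
#'
#' @param recording An [imu_recording] in raw (un-normalized) units.
#' @param model A fitted [fog_cnn] (or [fog_baseline]) carrying
#'   normalization scales; alternatively pass `scales` explicitly.
#' @param scales Cohort normalization scales; defaults to
#'   `model$scales`.
#' @param config Window configuration; defaults to the model's stored
#'   `window_config`.
#' @return Data frame with one row per decision: `time_s` (window end),
#'   `label`, and the three class probabilities `p_FOG`, `p_STOP`,
#'   `p_WALK`. Zero rows (with a warning) when the recording is shorter
#'   than one window.
#' @export
stream_decisions <- function(recording, model, scales = NULL,
                             config = NULL) {
  stopifnot(inherits(recording, "imu_recording"))
  if (is.null(scales)) scales <- model$scales
  if (is.null(scales))
    stop("no normalization scales: pass 'scales' or use a model trained ",
         "on a fog_windows dataset")
  if (is.null(config)) config <- model$window_config
  if (is.null(config)) config <- window_config(fs = recording$fs)
  if (!is.null(model$config)) {
    if (model$config$window_n != config$window_n ||
        model$config$n_channels != ncol(recording$samples))
      stop(sprintf(
        "incompatible checkpoint: model expects %d x %d windows, stream provides %d x %d",
        model$config$window_n, model$config$n_channels,
        config$window_n, ncol(recording$samples)))
  }
  n <- nrow(recording$samples)
  k <- count_windows(n, config)
  if (k == 0L) {
    warning(sprintf("recording (%.2f s) shorter than one %g s window: no decisions",
                    n / config$fs, config$window_s))
    return(data.frame(time_s = numeric(0), label = character(0),
                      p_FOG = numeric(0), p_STOP = numeric(0),
                      p_WALK = numeric(0)))
  }
  norm <- normalize_recording(recording, scales)
  seg <- segment_recording(norm, config)
  P <- if (inherits(model, "fog_baseline")) {
    feats <- t(vapply(seq_len(k), function(i) {
      w <- seg$data[i, , ]
      dim(w) <- dim(seg$data)[2:3]
      extract_features(w, config$fs)
    }, numeric(length(model$feature_names))))
    stats::predict(model, feats, type = "prob")
  } else {
    stats::predict(model, seg$data, type = "prob")
  }
  lab <- FOG_CLASSES[max.col(P, ties.method = "first")]
  data.frame(time_s = (seg$start_index + config$window_n) / config$fs,
             label = lab,
             p_FOG = P[, "FOG"], p_STOP = P[, "STOP"],
             p_WALK = P[, "WALK"])
}
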