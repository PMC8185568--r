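# Frequency bands (Hz) conventional in the FoG literature: normal gait and
# arm swing concentrate below ~3 Hz, freeze trembling in 3-8 Hz.
LOCOMOTOR_BAND <- c(0.5, 3)
FREEZE_BAND <- c(3, 8)

# One-sided raw periodogram of a mean-removed signal (rectangular window):
# P[f] = |FFT(x - mean)|^2 / n over frequencies 0, fs/n, ..., fs/2.
.periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2 / n
  nf <- n %/% 2 + 1L
  list(freq = (seq_len(nf) - 1L) * fs / n, power = P[seq_len(nf)])
}

# Power in the half-open band (lo, hi]: sum of periodogram ordinates.
.band_power <- function(pg, lo, hi) {
  sum(pg$power[pg$freq > lo & pg$freq <= hi])
}

.spectral_features <- function(x, fs, band_lo = LOCOMOTOR_BAND,
                               band_hi = FREEZE_BAND) {
  if (stats::var(x) < 1e-24) {
    return(c(spectral_entropy = 0, dominant_freq = 0,
             locomotor_power = 0, freeze_power = 0, freeze_index = 0))
  }
  pg <- .periodogram(x, fs)
  pos <- -1L  # drop the (zero, after mean removal) DC ordinate
  pw <- pg$power[pos]; fq <- pg$freq[pos]
  p <- pw / sum(pw)
  ent <- -sum(ifelse(p > 0, p * log(p), 0)) / log(length(p))
  dom <- fq[which.max(pw)]
  loco <- .band_power(pg, band_lo[1], band_lo[2])
  freeze <- .band_power(pg, band_hi[1], band_hi[2])
  fi <- if (loco > 0) freeze / loco else 0
  c(spectral_entropy = ent, dominant_freq = dom,
    locomotor_power = loco, freeze_power = freeze, freeze_index = fi)
}

#' Extract single-wrist time and frequency features from one window
#'
#' Computes, per channel: mean, standard deviation, variance, min, max,
#' root-mean-square, signal energy, normalized spectral entropy, dominant
#' frequency, locomotor-band power (0.5-3 Hz), freeze-band power (3-8 Hz)
#' and the freeze index (freeze power / locomotor power); plus the
#' spectral subset on the accelerometer- and gyroscope-magnitude signals.
#' Spectral quantities come from a rectangular-window periodogram of the
#' mean-removed signal. A zero-variance channel yields spectral entropy 0
#' and freeze index 0 by convention.
#'
#' @param window A window_n x 6 numeric matrix (columns ax..gz).
#' @param fs Sampling rate in Hz (default 128).
#' @param locomotor_band,freeze_band Band edges in Hz.
#' @return Named numeric feature vector (length 82 at the defaults).
#' @examples
#' w <- matrix(rnorm(384 * 6), ncol = 6)
#' f <- extract_features(w)
#' f["ax_freeze_index"]
#' @export
extract_features <- function(window, fs = 128,
                             locomotor_band = LOCOMOTOR_BAND,
                             freeze_band = FREEZE_BAND) {
  window <- as.matrix(window)
  if (nrow(window) < 64L) stop("window too short: need >= 64 samples")
  if (ncol(window) != 6L) stop("window must have 6 channels")
  feats <- list()
  for (c_i in seq_len(6)) {
    x <- window[, c_i]
    nm <- IMU_CHANNELS[c_i]
    tv <- c(mean = mean(x), sd = stats::sd(x), var = stats::var(x),
            min = min(x), max = max(x),
            rms = sqrt(mean(x^2)), energy = sum(x^2))
    sv <- .spectral_features(x, fs, locomotor_band, freeze_band)
    feats[[nm]] <- stats::setNames(c(tv, sv),
                                   paste(nm, names(c(tv, sv)), sep = "_"))
  }
  acc_mag <- sqrt(rowSums(window[, 1:3, drop = FALSE]^2))
  gyr_mag <- sqrt(rowSums(window[, 4:6, drop = FALSE]^2))
  sm_a <- .spectral_features(acc_mag, fs, locomotor_band, freeze_band)
  sm_g <- .spectral_features(gyr_mag, fs, locomotor_band, freeze_band)
  out <- c(unlist(feats, use.names = TRUE),
           stats::setNames(sm_a, paste0("accmag_", names(sm_a))),
           stats::setNames(sm_g, paste0("gyrmag_", names(sm_g))))
  names(out) <- sub("^[a-z]+\\.", "", names(out))
  out
}

#' Feature table for a window dataset
#'
#' Applies [extract_features] to every window and returns one row per
#' window with provenance columns.
#'
#' @param windows A `fog_windows` dataset.
#' @param fs Sampling rate; defaults to the dataset's window config.
#' @return Data frame: `subject_id`, `start_index`, `label`, then the
#'   feature columns.
#' @export
feature_table <- function(windows, fs = NULL) {
  stopifnot(inherits(windows, "fog_windows"))
  if (is.null(fs)) fs <- windows$config$fs
  n <- length(windows$label)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    w <- windows$data[i, , ]
    dim(w) <- dim(windows$data)[2:3]
    rows[[i]] <- extract_features(w, fs)
  }
  feats <- do.call(rbind, rows)
  cbind(data.frame(subject_id = windows$subject,
                   start_index = windows$start_index,
                   label = as.character(windows$label)),
        as.data.frame(feats))
}

#' Fit a classical feature-based baseline
#'
#' Trains a 3-class window classifier on the wrist feature set — a
#' decision tree (rpart) or gradient boosting (xgboost) — exposing the
#' same predict interface as the CNN so both can be swapped into the same
#' cross-validation folds.
#'
#' @param x A `fog_windows` dataset or a numeric feature matrix / data
#'   frame (one row per window).
#' @param labels Labels over FOG/STOP/WALK; taken from `x` when it is a
#'   `fog_windows`.
#' @param kind `"decision_tree"` or `"gradient_boosting"`.
#' @param seed Integer seed (xgboost subsampling and any tie-breaking).
#' @param ... Extra arguments passed to the underlying fitter.
#' @return An object of class `fog_baseline`.
#' @export
fog_baseline <- function(x, labels = NULL,
                         kind = c("decision_tree", "gradient_boosting"),
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  if (inherits(x, "fog_windows")) {
    if (is.null(labels)) labels <- x$label
    ft <- feature_table(x)
    feats <- as.matrix(ft[, -(1:3), drop = FALSE])
  } else {
    feats <- as.matrix(x)
  }
  if (is.null(labels)) stop("'labels' required when x is not fog_windows")
  y <- factor(as.character(labels), levels = FOG_CLASSES)
  if (anyNA(y)) stop("labels outside {FOG, STOP, WALK}")
  if (nrow(feats) != length(y)) stop("feature/label length mismatch")
  if (nlevels(droplevels(y)) < 2L)
    stop("training set must contain at least two classes")
  if (all(apply(feats, 2, function(v) stats::var(v) < 1e-24)))
    stop("degenerate features: every column is constant")
  set.seed(seed)
  fit <- switch(
    kind,
    decision_tree = {
      df <- data.frame(.y = y, feats, check.names = TRUE)
      rpart::rpart(.y ~ ., data = df, method = "class", ...)
    },
    gradient_boosting = {
      dtr <- xgboost::xgb.DMatrix(feats,
                                  label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = 3,
                      max_depth = 6, eta = 0.3, nthread = 1,
                      seed = seed),
        data = dtr, nrounds = 50, verbose = 0, ...)
    })
  structure(list(kind = kind, fit = fit, seed = seed,
                 classes = FOG_CLASSES,
                 feature_names = colnames(feats)),
            class = "fog_baseline")
}

#' @export
print.fog_baseline <- function(x, ...) {
  cat(sprintf("FoG feature baseline: %s on %d wrist features\n",
              x$kind, length(x$feature_names)))
  invisible(x)
}

#' Predict from a fitted feature baseline
#'
#' @param object A [fog_baseline].
#' @param newdata A `fog_windows` dataset or a feature matrix with the
#'   training columns.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of labels or an n x 3 probability matrix (columns FOG,
#'   STOP, WALK).
#' @export
predict.fog_baseline <- function(object, newdata,
                                 type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "fog_windows")) {
    ft <- feature_table(newdata)
    feats <- as.matrix(ft[, -(1:3), drop = FALSE])
  } else {
    feats <- as.matrix(newdata)
  }
  P <- switch(
    object$kind,
    decision_tree = {
      df <- data.frame(feats, check.names = TRUE)
      pr <- stats::predict(object$fit, df, type = "prob")
      miss <- setdiff(object$classes, colnames(pr))
      if (length(miss)) {
        add <- matrix(0, nrow(pr), length(miss),
                      dimnames = list(NULL, miss))
        pr <- cbind(pr, add)
      }
      pr[, object$classes, drop = FALSE]
    },
    gradient_boosting = {
      pr <- stats::predict(object$fit, xgboost::xgb.DMatrix(feats))
      if (!is.matrix(pr))  # older xgboost returns a flat row-major vector
        pr <- matrix(pr, ncol = 3, byrow = TRUE)
      dimnames(pr) <- list(NULL, object$classes)
      pr
    })
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}
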