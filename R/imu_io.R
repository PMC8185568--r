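#' @keywords internal
"_PACKAGE"

# Class labels, in the fixed serialization order used everywhere in the
# package (model outputs, confusion matrices, factors).
FOG_CLASSES <- c("FOG", "STOP", "WALK")

IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

#' Construct a wrist IMU recording
#'
#' An `imu_recording` holds one subject's continuous six-channel inertial
#' stream: tri-axial accelerometer (`ax`, `ay`, `az`) and tri-axial
#' gyroscope (`gx`, `gy`, `gz`), sampled at a fixed rate. Units are carried
#' as metadata only; nothing in the pipeline converts them, because
#' downstream normalization removes scale.
#'
#' @param samples Numeric matrix with N rows and 6 columns in channel order
#'   `ax, ay, az, gx, gy, gz`. No missing values are allowed.
#' @param subject_id Character scalar identifying the subject.
#' @param fs Sampling rate in Hz (default 128).
#' @param units Named character vector of unit metadata
#'   (default `c(accel = "g", gyro = "deg/s")`).
#' @return An object of class `imu_recording`: a list with elements
#'   `subject_id`, `fs`, `samples` (N x 6 matrix with channel column names)
#'   and `units`.
#' @examples
#' rec <- imu_recording(matrix(rnorm(384 * 6), ncol = 6), "S1")
#' nrow(rec$samples)
#' @export
imu_recording <- function(samples, subject_id, fs = 128,
                          units = c(accel = "g", gyro = "deg/s")) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("'samples' must be numeric")
  if (ncol(samples) != 6L)
    stop("'samples' must have exactly 6 channels, got ", ncol(samples))
  if (nrow(samples) < 1L) stop("'samples' must have at least one row")
  if (anyNA(samples)) stop("'samples' contains missing values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar")
  colnames(samples) <- IMU_CHANNELS
  structure(
    list(subject_id = as.character(subject_id), fs = fs,
         samples = samples, units = units),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("IMU recording: subject %s, %d samples x 6 channels, %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Construct an annotation track
#'
#' An `annotation_track` is an ordered set of non-overlapping labeled
#' intervals `(start_s, end_s, label)` covering (parts of) a session, with
#' labels restricted to `FOG`, `STOP` and `WALK`. Intervals are treated as
#' half-open `[start_s, end_s)` throughout the package.
#'
#' @param intervals Data frame with numeric columns `start_s`, `end_s` and a
#'   character column `label` (case-insensitive on input).
#' @param subject_id Character scalar identifying the subject.
#' @return An object of class `annotation_track` with elements `subject_id`
#'   and `intervals` (sorted by `start_s`, labels upper-case).
#' @examples
#' annotation_track(data.frame(start_s = c(0, 10), end_s = c(10, 12),
#'                             label = c("WALK", "FOG")), "S1")
#' @export
annotation_track <- function(intervals, subject_id) {
  intervals <- as.data.frame(intervals)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(intervals)))
    stop("'intervals' must have columns start_s, end_s, label")
  intervals <- intervals[, need]
  intervals$start_s <- as.numeric(intervals$start_s)
  intervals$end_s <- as.numeric(intervals$end_s)
  intervals$label <- toupper(as.character(intervals$label))
  if (anyNA(intervals)) stop("annotation intervals contain missing values")
  bad <- setdiff(unique(intervals$label), FOG_CLASSES)
  if (length(bad) > 0)
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(FOG_CLASSES, collapse = ", "), ")")
  zero <- which(intervals$start_s >= intervals$end_s)
  if (length(zero) > 0)
    stop("interval ", zero[1], " has start_s >= end_s (",
         intervals$start_s[zero[1]], ", ", intervals$end_s[zero[1]], ")")
  intervals <- intervals[order(intervals$start_s), , drop = FALSE]
  rownames(intervals) <- NULL
  if (nrow(intervals) > 1L) {
    ov <- which(intervals$end_s[-nrow(intervals)] >
                  intervals$start_s[-1] + 1e-12)
    if (length(ov) > 0) {
      i <- ov[1]
      stop(sprintf(
        "overlapping intervals: (%g, %g, %s) and (%g, %g, %s)",
        intervals$start_s[i], intervals$end_s[i], intervals$label[i],
        intervals$start_s[i + 1], intervals$end_s[i + 1],
        intervals$label[i + 1]))
    }
  }
  structure(list(subject_id = as.character(subject_id),
                 intervals = intervals),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("Annotation track: subject %s, %d intervals\n",
              x$subject_id, nrow(x$intervals)))
  print(table(factor(x$intervals$label, levels = FOG_CLASSES)))
  invisible(x)
}

#' Read an IMU recording from CSV
#'
#' The file must have one header row naming either the 6 sensor channels
#' (`ax,ay,az,gx,gy,gz`) or 7 columns with a leading time column
#' (`t,ax,...,gz`). The time column, when present, is only checked for
#' consistency with `fs` (median sample spacing within 1%; a mismatch is a
#' warning, not an error) and is never used for indexing: the sample index
#' is authoritative.
#'
#' @param path Path to a CSV file.
#' @param subject_id Subject identifier to attach; defaults to the file
#'   name without extension.
#' @param fs Sampling rate in Hz (default 128).
#' @return An [imu_recording].
#' @export
read_recording <- function(path, subject_id = NULL, fs = 128) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  hdr <- names(raw)
  has_t <- identical(hdr, c("t", IMU_CHANNELS))
  if (!has_t && !identical(hdr, IMU_CHANNELS))
    stop("unexpected header in ", path, ": expected 't,",
         paste(IMU_CHANNELS, collapse = ","), "' or '",
         paste(IMU_CHANNELS, collapse = ","), "'")
  if (nrow(raw) < 1L) stop("no data rows in ", path)
  num <- suppressWarnings(
    vapply(raw, as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, hdr))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at data row %d, column '%s' of %s",
                 bad[1], hdr[bad[2]], path))
  }
  if (has_t) {
    dt <- stats::median(diff(num[, "t"]))
    if (is.finite(dt) && abs(dt - 1 / fs) > 0.01 / fs)
      warning(sprintf(
        "median sample spacing %.6g s differs from 1/fs = %.6g s by more than 1%%",
        dt, 1 / fs))
    num <- num[, IMU_CHANNELS, drop = FALSE]
  }
  imu_recording(num, subject_id = subject_id, fs = fs)
}

#' Write an IMU recording to CSV
#'
#' Values are rounded (half-to-even) to `digits` decimal places; the
#' default of 4 matches the pipeline's storage precision, so
#' `read_recording(write_recording(x))` reproduces `x` to that precision.
#' No time column is written.
#'
#' @param recording An [imu_recording].
#' @param path Output CSV path.
#' @param digits Decimal places retained (default 4).
#' @return Invisibly, `path`.
#' @export
write_recording <- function(recording, path, digits = 4) {
  stopifnot(inherits(recording, "imu_recording"))
  df <- as.data.frame(round(recording$samples, digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotation track from CSV
#'
#' Expects columns `start_s,end_s,label` with labels `FOG`, `STOP` or
#' `WALK` (case-insensitive). Intervals are validated: positive length, no
#' overlaps, known labels.
#'
#' @param path Path to a CSV file.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return An [annotation_track]. An annotations file with only a header
#'   yields an empty track.
#' @export
read_annotations <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric", "character"),
                        check.names = FALSE)
  if (!all(c("start_s", "end_s", "label") %in% names(df)))
    stop("annotation file ", path, " must have columns start_s,end_s,label")
  annotation_track(df, subject_id = subject_id)
}

#' Write an annotation track to CSV
#'
#' @param track An [annotation_track].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  utils::write.csv(track$intervals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
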