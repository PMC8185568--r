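#' Synthetic wrist-IMU cohort configuration
#'
#' Parameters of the stylized single-wrist signal model used to emulate a
#' clinical FoG cohort: walking-with-turns blocks (arm-swing fundamental
#' near 1 Hz plus a second harmonic, gravity offset on the vertical
#' accelerometer axis, periodic yaw-rate turn pulses on the gyroscope),
#' stop blocks (gravity plus a low noise floor), and FoG episodes in which
#' the locomotor components are attenuated and a 3-8 Hz trembling tone
#' plus band-limited noise appears. Episode durations follow a lognormal
#' law quantile-matched to published percentiles (50.8% below 3 s, 64.7%
#' below 5 s), truncated to the published range 0.11-98.8 s.
#'
#' `gamma` in (0, 1] scales the FoG-distinguishing signal components
#' (trembling amplitude and locomotor attenuation): at `gamma = 1` FoG
#' windows are spectrally separable from walking; as `gamma -> 0` FoG
#' segments become indistinguishable from walking while annotations are
#' unchanged, giving a null condition for classifier controls.
#'
#' @param fs Sampling rate in Hz (default 128).
#' @param n_subjects Number of subjects (default 11).
#' @param session_s Session length in seconds (default 600).
#' @param gait_freq_mean,gait_freq_sd Per-subject gait (arm-swing)
#'   frequency distribution, Hz (default Normal(1.0, 0.1^2)).
#' @param swing_amp Arm-swing accelerometer amplitude, g (default 0.4).
#' @param gravity Gravity offset on the vertical accel axis, g (default 1).
#' @param gyro_amp Arm-swing gyroscope amplitude, deg/s (default 80).
#' @param turn_rate Peak yaw rate during turns, deg/s (default 90).
#' @param turn_every,turn_duration Turn cadence and duration, s.
#' @param tremble_amp Accelerometer amplitude of FoG trembling, g
#'   (default 0.35).
#' @param tremble_gyro_amp Gyroscope trembling amplitude, deg/s
#'   (default 40).
#' @param tremble_freq_range Per-episode trembling center frequency range,
#'   Hz (default Uniform(4, 7)).
#' @param fog_attenuation Multiplier on locomotor components during FoG at
#'   `gamma = 1` (default 0.25).
#' @param noise_sd_accel,noise_sd_gyro Additive white-noise SDs (g, deg/s).
#' @param stop_noise_sd_accel,stop_noise_sd_gyro Noise floor while
#'   stopped.
#' @param gamma Class-separation scale in (0, 1] (default 1).
#' @param episode_rate FoG episodes per minute of walking (nominal Poisson
#'   rate before disjointness thinning; default 4.1, which yields about
#'   184 episodes across the default 11-subject cohort in expectation).
#' @param episode_buffer_s Minimum walking time between episodes, s
#'   (default 2).
#' @param duration_meanlog,duration_sdlog,duration_range Episode-duration
#'   law: lognormal(meanlog, sdlog) truncated to `duration_range`.
#' @param walk_block_s,stop_block_s Ranges (s) for alternating
#'   walking/stop block durations.
#' @return An object of class `fog_generator_config`.
#' @export
generator_config <- function(fs = 128, n_subjects = 11L, session_s = 600,
                             gait_freq_mean = 1.0, gait_freq_sd = 0.1,
                             swing_amp = 0.4, gravity = 1.0,
                             gyro_amp = 80, turn_rate = 90,
                             turn_every = 15, turn_duration = 2.5,
                             tremble_amp = 0.35, tremble_gyro_amp = 40,
                             tremble_freq_range = c(4, 7),
                             fog_attenuation = 0.25,
                             noise_sd_accel = 0.03, noise_sd_gyro = 2,
                             stop_noise_sd_accel = 0.01,
                             stop_noise_sd_gyro = 0.5,
                             gamma = 1,
                             episode_rate = 4.1, episode_buffer_s = 2,
                             duration_meanlog = 1.0699,
                             duration_sdlog = 1.4302,
                             duration_range = c(0.11, 98.8),
                             walk_block_s = c(40, 80),
                             stop_block_s = c(10, 30)) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  if (min(swing_amp, gyro_amp, tremble_amp, tremble_gyro_amp, turn_rate,
          episode_rate) < 0)
    stop("rates and amplitudes must be nonnegative")
  structure(as.list(environment()), class = "fog_generator_config")
}

#' Sample FoG episode durations
#'
#' Draws from the truncated lognormal duration law of the generator
#' config (rejection sampling into the truncation range). At the default
#' parameters about 50.8% of draws fall below 3 s and 64.7% below 5 s,
#' within the published range 0.11-98.8 s.
#'
#' @param n Number of draws.
#' @param config A [generator_config].
#' @return Numeric vector of durations in seconds.
#' @examples
#' set.seed(1)
#' mean(sample_episode_duration(10000) < 3)
#' @export
sample_episode_duration <- function(n, config = generator_config()) {
  lo <- config$duration_range[1]; hi <- config$duration_range[2]
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(n - length(out), config$duration_meanlog,
                       config$duration_sdlog)
    out <- c(out, d[d >= lo & d <= hi])
  }
  out[seq_len(n)]
}

# Per-subject gait idiosyncrasies, drawn once per subject.
.subject_params <- function(config) {
  list(gait_freq = max(0.5, stats::rnorm(1, config$gait_freq_mean,
                                         config$gait_freq_sd)),
       swing_amp = config$swing_amp * exp(stats::rnorm(1, 0, 0.15)),
       gyro_amp = config$gyro_amp * exp(stats::rnorm(1, 0, 0.15)),
       phase = stats::runif(1, 0, 2 * pi),
       turn_every = config$turn_every * stats::runif(1, 0.8, 1.2))
}

# Locomotor (walking) signal components at absolute times t, as an n x 6
# matrix without noise. Phase is a function of absolute time so walking
# resumes coherently after stops and episodes.
.walk_components <- function(t, sp, config) {
  w <- 2 * pi * sp$gait_freq
  A <- sp$swing_amp; G <- sp$gyro_amp; ph <- sp$phase
  turn_phase <- (t %% sp$turn_every)
  in_turn <- turn_phase < config$turn_duration
  turn <- ifelse(in_turn,
                 config$turn_rate *
                   sin(pi * turn_phase / config$turn_duration)^2,
                 0)
  # alternate turn direction
  turn <- turn * ifelse(((t %/% sp$turn_every) %% 2) == 0, 1, -1)
  cbind(
    ax = A * sin(w * t + ph) + 0.3 * A * sin(2 * w * t + 2 * ph),
    ay = 0.6 * A * sin(w * t + ph + 1.2),
    az = 0.25 * A * sin(2 * w * t + ph),
    gx = G * cos(w * t + ph),
    gy = 0.5 * G * cos(w * t + ph + 0.7),
    gz = turn)
}

.noise6 <- function(n, sd_acc, sd_gyr) {
  cbind(matrix(stats::rnorm(3 * n, 0, sd_acc), n, 3),
        matrix(stats::rnorm(3 * n, 0, sd_gyr), n, 3))
}

.gravity6 <- function(n, config) {
  cbind(matrix(0, n, 2), rep(config$gravity, n), matrix(0, n, 3))
}

#' Generate a walking-with-turns signal segment
#'
#' @param duration_s Segment duration in seconds (>= 1/fs).
#' @param sp Subject parameters (internal; pass `NULL` to draw fresh ones
#'   from the current RNG).
#' @param config A [generator_config].
#' @param t0 Absolute segment start time in seconds (keeps the arm-swing
#'   phase continuous across a session).
#' @return n x 6 numeric matrix (ax..gz).
#' @export
make_walk_segment <- function(duration_s, sp = NULL,
                              config = generator_config(), t0 = 0) {
  n <- max(1L, round(duration_s * config$fs))
  if (is.null(sp)) sp <- .subject_params(config)
  t <- t0 + (seq_len(n) - 1L) / config$fs
  .walk_components(t, sp, config) + .gravity6(n, config) +
    .noise6(n, config$noise_sd_accel, config$noise_sd_gyro)
}

#' Generate a FoG (freezing) signal segment
#'
#' Locomotor components are attenuated and a trembling tone at the
#' episode's center frequency (drawn from `tremble_freq_range`) plus
#' band-limited 3-8 Hz noise is added, both scaled by `gamma`.
#'
#' @inheritParams make_walk_segment
#' @param center_freq Trembling center frequency in Hz; drawn uniformly
#'   from `config$tremble_freq_range` when `NULL`.
#' @return n x 6 numeric matrix.
#' @export
make_fog_segment <- function(duration_s, sp = NULL,
                             config = generator_config(), t0 = 0,
                             center_freq = NULL) {
  n <- max(1L, round(duration_s * config$fs))
  if (is.null(sp)) sp <- .subject_params(config)
  if (is.null(center_freq))
    center_freq <- stats::runif(1, config$tremble_freq_range[1],
                                config$tremble_freq_range[2])
  g <- config$gamma
  atten <- 1 - g * (1 - config$fog_attenuation)
  t <- t0 + (seq_len(n) - 1L) / config$fs
  base <- .walk_components(t, sp, config) * atten
  tone_ph <- stats::runif(1, 0, 2 * pi)
  tone <- sin(2 * pi * center_freq * t + tone_ph)
  # band-limited 3-8 Hz noise: sum of random-phase sinusoids
  nb <- 8L
  bfreq <- stats::runif(nb, 3, 8)
  bph <- stats::runif(nb, 0, 2 * pi)
  bnoise <- rowSums(vapply(seq_len(nb),
                           function(i) sin(2 * pi * bfreq[i] * t + bph[i]),
                           numeric(n))) / sqrt(nb)
  ta <- g * config$tremble_amp
  tg <- g * config$tremble_gyro_amp
  trem <- cbind(ax = ta * (tone + 0.5 * bnoise),
                ay = 0.8 * ta * (sin(2 * pi * center_freq * t + bph[1]) +
                                   0.5 * bnoise),
                az = 0.4 * ta * bnoise,
                gx = tg * (cos(2 * pi * center_freq * t + tone_ph) +
                             0.5 * bnoise),
                gy = 0.6 * tg * bnoise,
                gz = 0.3 * tg * bnoise)
  base + trem + .gravity6(n, config) +
    .noise6(n, config$noise_sd_accel, config$noise_sd_gyro)
}

#' Generate a stop (standing) signal segment
#'
#' Gravity offset plus a low-amplitude noise floor.
#'
#' @inheritParams make_walk_segment
#' @return n x 6 numeric matrix.
#' @export
make_stop_segment <- function(duration_s, sp = NULL,
                              config = generator_config(), t0 = 0) {
  n <- max(1L, round(duration_s * config$fs))
  .gravity6(n, config) +
    .noise6(n, config$stop_noise_sd_accel, config$stop_noise_sd_gyro)
}

#' Synthesize one annotated session
#'
#' Alternating walking and stop blocks; FoG episodes are inserted within
#' walking blocks by a Poisson process (exponential gaps plus a minimum
#' walking buffer) with durations from [sample_episode_duration], thinned
#' so episodes stay disjoint and inside their block. The annotation track
#' tiles the session exactly.
#'
#' @param subject_id Subject identifier.
#' @param config A [generator_config].
#' @param sp Subject parameters; drawn from the current RNG when `NULL`.
#' @return List with `recording` ([imu_recording]), `track`
#'   ([annotation_track]) and `episodes` (data frame of realized FoG
#'   start/duration seconds).
#' @export
synthesize_session <- function(subject_id, config = generator_config(),
                               sp = NULL) {
  fs <- config$fs
  if (is.null(sp)) sp <- .subject_params(config)
  session_n <- round(config$session_s * fs)
  buffer_n <- round(config$episode_buffer_s * fs)
  segs <- list()  # list of (label, n, center_freq or NA)
  t_n <- 0L; walk_turn <- TRUE
  while (t_n < session_n) {
    if (walk_turn) {
      block_n <- min(round(stats::runif(1, config$walk_block_s[1],
                                        config$walk_block_s[2]) * fs),
                     session_n - t_n)
      pos <- 0L
      if (config$episode_rate > 0) {
        repeat {
          gap_n <- buffer_n +
            round(stats::rexp(1, config$episode_rate / 60) * fs)
          d_n <- max(1L, round(sample_episode_duration(1, config) * fs))
          if (pos + gap_n + d_n + buffer_n > block_n) break
          if (gap_n > 0)
            segs[[length(segs) + 1L]] <- list("WALK", gap_n, NA)
          cf <- stats::runif(1, config$tremble_freq_range[1],
                             config$tremble_freq_range[2])
          segs[[length(segs) + 1L]] <- list("FOG", d_n, cf)
          pos <- pos + gap_n + d_n
        }
      }
      if (block_n - pos > 0)
        segs[[length(segs) + 1L]] <- list("WALK", block_n - pos, NA)
    } else {
      block_n <- min(round(stats::runif(1, config$stop_block_s[1],
                                        config$stop_block_s[2]) * fs),
                     session_n - t_n)
      if (block_n > 0)
        segs[[length(segs) + 1L]] <- list("STOP", block_n, NA)
    }
    t_n <- t_n + block_n
    walk_turn <- !walk_turn
  }
  samples <- matrix(NA_real_, session_n, 6)
  iv <- data.frame(start_s = numeric(0), end_s = numeric(0),
                   label = character(0))
  at <- 0L
  for (sg in segs) {
    n <- sg[[2]]
    t0 <- at / fs
    block <- switch(sg[[1]],
                    WALK = make_walk_segment(n / fs, sp, config, t0),
                    FOG = make_fog_segment(n / fs, sp, config, t0,
                                           center_freq = sg[[3]]),
                    STOP = make_stop_segment(n / fs, sp, config, t0))
    samples[at + seq_len(n), ] <- block[seq_len(n), ]
    iv <- rbind(iv, data.frame(start_s = t0, end_s = (at + n) / fs,
                               label = sg[[1]]))
    at <- at + n
  }
  ep <- iv[iv$label == "FOG", , drop = FALSE]
  list(recording = imu_recording(samples, subject_id, fs = fs),
       track = annotation_track(iv, subject_id),
       episodes = data.frame(subject_id = rep(subject_id, nrow(ep)),
                             start_s = ep$start_s,
                             duration_s = ep$end_s - ep$start_s))
}

#' Synthesize a cohort
#'
#' Generates `n_subjects` annotated sessions with per-subject gait
#' parameters. A cohort is a pure function of `(config, seed)`. The
#' default configuration targets roughly 184 FoG episodes across the
#' 11-subject cohort in expectation, mirroring the cohort the generator
#' emulates.
#'
#' @param config A [generator_config].
#' @param seed Integer seed.
#' @return An object of class `fog_cohort`: list with `recordings`,
#'   `tracks`, and `manifest` (config, seed, realized episode table and
#'   count).
#' @examples
#' coh <- synthesize_cohort(generator_config(n_subjects = 2, session_s = 60),
#'                          seed = 1)
#' coh$manifest$n_episodes
#' @export
synthesize_cohort <- function(config = generator_config(), seed = 1L) {
  set.seed(as.integer(seed))
  recs <- vector("list", config$n_subjects)
  trks <- vector("list", config$n_subjects)
  eps <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", i)
    sp <- .subject_params(config)
    ses <- synthesize_session(sid, config, sp)
    recs[[i]] <- ses$recording
    trks[[i]] <- ses$track
    eps[[i]] <- ses$episodes
  }
  episodes <- do.call(rbind, eps)
  structure(
    list(recordings = recs, tracks = trks,
         manifest = list(config = config, seed = as.integer(seed),
                         episodes = episodes,
                         n_episodes = nrow(episodes))),
    class = "fog_cohort")
}

#' @export
print.fog_cohort <- function(x, ...) {
  cat(sprintf("Synthetic wrist-IMU cohort: %d subjects, %g s sessions, %d FoG episodes (seed %d)\n",
              length(x$recordings), x$manifest$config$session_s,
              x$manifest$n_episodes, x$manifest$seed))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' One recording CSV and one annotation CSV per subject, plus
#' `manifest.json` recording the configuration, seed and realized episode
#' table.
#'
#' @param cohort A `fog_cohort`.
#' @param dir Output directory (created if needed).
#' @param digits Decimal precision of the recording CSVs (default 4).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, digits = 4) {
  stopifnot(inherits(cohort, "fog_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$recordings)) {
    sid <- cohort$recordings[[i]]$subject_id
    write_recording(cohort$recordings[[i]],
                    file.path(dir, paste0(sid, "_imu.csv")), digits)
    write_annotations(cohort$tracks[[i]],
                      file.path(dir, paste0(sid, "_annotations.csv")))
  }
  jsonlite::write_json(
    list(seed = cohort$manifest$seed,
         n_episodes = cohort$manifest$n_episodes,
         episodes = cohort$manifest$episodes,
         config = unclass(cohort$manifest$config)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort]
#'
#' @param dir Cohort directory.
#' @param fs Sampling rate of the recordings (default 128).
#' @return A `fog_cohort` (manifest restored from `manifest.json` when
#'   present).
#' @export
read_cohort <- function(dir, fs = 128) {
  rec_files <- sort(list.files(dir, "_imu\\.csv$", full.names = TRUE))
  if (!length(rec_files)) stop("no recording CSVs under ", dir)
  ids <- sub("_imu\\.csv$", "", basename(rec_files))
  recs <- lapply(seq_along(rec_files), function(i)
    read_recording(rec_files[i], subject_id = ids[i], fs = fs))
  trks <- lapply(ids, function(sid)
    read_annotations(file.path(dir, paste0(sid, "_annotations.csv")),
                     subject_id = sid))
  mf <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(mf))
    jsonlite::read_json(mf, simplifyVector = TRUE)
  structure(list(recordings = recs, tracks = trks, manifest = manifest),
            class = "fog_cohort")
}
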