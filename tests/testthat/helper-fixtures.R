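# Shared fixtures and independent oracles used across the test files.

# Small CNN geometry used wherever the architecture itself is not under
# test: short windows keep the training loops fast.
tiny_config <- function(window_n = 64L, dropout_rate = 0.2) {
  model_config(conv_filters = c(8L, 4L), kernel_size = 5L,
               pool = list(list("max", 2L), list("avg", 2L)),
               dropout_rate = dropout_rate, window_n = window_n)
}

# Two-tone separable window set: FOG windows carry a 6 Hz tone (freeze
# band), WALK a 1 Hz tone, STOP near-silence. Returns a fog_windows-like
# array plus labels.
tone_windows <- function(n_per_class = 20, window_n = 64L, fs = 128,
                         noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  t <- (seq_len(window_n) - 1) / fs
  one <- function(freq, amp) {
    w <- matrix(stats::rnorm(window_n * 6, 0, noise_sd), window_n, 6)
    ph <- stats::runif(1, 0, 2 * pi)
    w[, 1:2] <- w[, 1:2] + amp * sin(2 * pi * freq * t + ph)
    w[, 4] <- w[, 4] + amp * cos(2 * pi * freq * t + ph)
    w
  }
  mk <- function(freq, amp, n) {
    arr <- array(NA_real_, c(n, window_n, 6))
    for (i in seq_len(n)) arr[i, , ] <- one(freq, amp)
    arr
  }
  data <- array(NA_real_, c(3 * n_per_class, window_n, 6))
  data[seq_len(n_per_class), , ] <- mk(6, 1, n_per_class)
  data[n_per_class + seq_len(n_per_class), , ] <- mk(1, 1, n_per_class)
  data[2 * n_per_class + seq_len(n_per_class), , ] <-
    mk(2, 0.01, n_per_class)
  list(data = data,
       labels = factor(rep(c("FOG", "WALK", "STOP"), each = n_per_class),
                       levels = c("FOG", "STOP", "WALK")))
}

# A tiny annotated cohort for pipeline tests.
tiny_cohort <- function(n_subjects = 2, session_s = 40, seed = 1, ...) {
  synthesize_cohort(generator_config(n_subjects = n_subjects,
                                     session_s = session_s, ...),
                    seed = seed)
}

# Independent brute-force window count: enumerate valid start indices.
count_windows_brute <- function(n, window_n, step_n) {
  starts <- seq(0, max(0, n), by = step_n)
  sum(starts + window_n <= n)
}

# Independent continuous-interval labeling oracle, written as a plain
# loop over intervals (no shared code with label_window).
label_window_brute <- function(start_s, end_s, iv, window_s) {
  fog <- 0; stp <- 0; wlk <- 0; contained <- FALSE
  for (r in seq_len(nrow(iv))) {
    o <- min(end_s, iv$end_s[r]) - max(start_s, iv$start_s[r])
    if (o <= 0) next
    if (iv$label[r] == "FOG") {
      fog <- fog + o
      if (iv$start_s[r] >= start_s && iv$end_s[r] <= end_s)
        contained <- TRUE
    } else if (iv$label[r] == "STOP") stp <- stp + o
    else wlk <- wlk + o
  }
  if (contained || fog >= window_s / 2) return("FOG")
  if (stp > wlk) "STOP" else "WALK"
}

# Sample-level labeling oracle: label each sample midpoint from the
# track, then apply the containment / half-window rule on sample counts.
# Exact when all boundaries are multiples of 1/fs.
label_window_samples <- function(start_s, end_s, iv, window_s, fs) {
  n <- round((end_s - start_s) * fs)
  mids <- start_s + (seq_len(n) - 0.5) / fs
  lab_of <- function(tm) {
    r <- which(iv$start_s <= tm & tm < iv$end_s)
    if (length(r) == 0) NA_character_ else iv$label[r[1]]
  }
  labs <- vapply(mids, lab_of, character(1))
  fog_s <- sum(labs == "FOG", na.rm = TRUE) / fs
  contained <- any(iv$label == "FOG" & iv$start_s >= start_s &
                     iv$end_s <= end_s & iv$end_s > iv$start_s &
                     iv$start_s < end_s & iv$end_s > start_s)
  if (contained || fog_s >= window_s / 2) return("FOG")
  stp <- sum(labs == "STOP", na.rm = TRUE)
  wlk <- sum(labs == "WALK", na.rm = TRUE)
  if (stp > wlk) "STOP" else "WALK"
}

# Random annotation track tiling [0, len_s) with boundaries on the
# sample grid, for oracle comparisons.
random_grid_track <- function(len_s, fs = 128, mean_block_s = 4) {
  cuts <- 0
  while (utils::tail(cuts, 1) < len_s) {
    step <- max(1, round(stats::rexp(1, 1 / mean_block_s) * fs)) / fs
    cuts <- c(cuts, min(len_s, utils::tail(cuts, 1) + step))
  }
  k <- length(cuts) - 1
  data.frame(start_s = cuts[-length(cuts)], end_s = cuts[-1],
             label = sample(c("FOG", "STOP", "WALK"), k, replace = TRUE,
                            prob = c(0.3, 0.3, 0.4)))
}
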