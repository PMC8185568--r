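test_that("cohort scales are the max absolute value per channel", {
  r1 <- imu_recording(cbind(c(2, -1), 0.1, 0.1, 0.1, 0.1, c(0.2, 0.3)), "A")
  r2 <- imu_recording(cbind(c(-5, 1), 0.2, 0.3, 0.1, 0.1, c(0.1, 0.1)), "B")
  s <- cohort_scales(list(r1, r2))
  expect_equal(unname(s["ax"]), 5)        # abs maxima 2 and 5
  expect_equal(unname(s["gz"]), 0.3)

  r3 <- imu_recording(cbind(-7.5, 1, 1, 1, 1, 1), "C")
  expect_equal(unname(cohort_scales(list(r3))["ax"]), 7.5)

  r0 <- imu_recording(cbind(1, 1, 1, 1, 1, 0), "D")
  expect_error(cohort_scales(list(r0)), "gz")
})

test_that("normalization divides by the scale and rounds to 4 decimals", {
  s <- rep(9.81, 6)
  rec <- imu_recording(matrix(c(9.81, 0.123456 * 9.81, -9.81 / 2,
                                rep(1, 3)), 1, 6), "S")
  nm <- normalize_recording(rec, s)
  expect_equal(unname(nm$samples[1, 1]), 1.0)
  expect_equal(unname(nm$samples[1, 2]), 0.1235)
  expect_equal(unname(nm$samples[1, 3]), -0.5)
  expect_true(all(abs(nm$samples) <= 1.0001))
})

test_that("normalization is idempotent up to rounding", {
  coh <- tiny_cohort(n_subjects = 2, session_s = 20, seed = 3)
  s <- cohort_scales(coh$recordings)
  normed <- lapply(coh$recordings, normalize_recording, scales = s)
  s2 <- cohort_scales(normed)
  renormed <- lapply(normed, normalize_recording, scales = s2)
  for (i in seq_along(normed))
    expect_lt(max(abs(renormed[[i]]$samples - normed[[i]]$samples)),
              1e-4 + 1e-12)
})

test_that("window counts match the closed form and brute force", {
  cfg <- window_config()  # 384 / 32 samples
  expect_equal(count_windows(384, cfg), 1L)
  expect_equal(count_windows(383, cfg), 0L)
  expect_equal(count_windows(1280, cfg), 29L)

  set.seed(11)
  for (i in 1:1000) {
    wn <- sample(2:500, 1)
    sn <- sample(seq_len(wn), 1)
    n <- sample(0:2000, 1)
    cfg_i <- window_config(window_s = wn, step_s = sn, fs = 1)
    expect_identical(count_windows(n, cfg_i),
                     as.integer(count_windows_brute(n, wn, sn)))
  }
})

test_that("segmentation enumerates starts by step and slices exactly", {
  cfg <- window_config()
  rec <- imu_recording(matrix(rnorm(448 * 6), ncol = 6), "S")
  seg <- segment_recording(rec, cfg)
  expect_equal(seg$start_index, c(0L, 32L, 64L))
  expect_equal(dim(seg$data), c(3, 384, 6))
  for (k in 1:3) {
    w <- seg$data[k, , ]
    expect_equal(w, unname(rec$samples[seg$start_index[k] + 1:384, ]))
  }
  rec1 <- imu_recording(matrix(rnorm(384 * 6), ncol = 6), "S")
  seg1 <- segment_recording(rec1, cfg)
  expect_equal(length(seg1$start_index), 1L)
  expect_equal(seg1$data[1, , ], unname(rec1$samples))
})

test_that("window labeling follows the containment and half-window rules", {
  trk <- annotation_track(data.frame(
    start_s = c(0, 10.2, 10.7), end_s = c(10.2, 10.7, 20),
    label = c("WALK", "FOG", "WALK")), "S")
  # short episode fully inside the window
  expect_equal(label_window(9, 12, trk), "FOG")

  trk2 <- annotation_track(data.frame(
    start_s = c(0, 7, 10), end_s = c(7, 10, 20),
    label = c("WALK", "FOG", "WALK")), "S")
  # overlap 1.0 s < 1.5 s and not contained -> majority non-FoG class
  expect_equal(label_window(9, 12, trk2), "WALK")

  trk3 <- annotation_track(data.frame(
    start_s = c(0, 7, 10.7), end_s = c(7, 10.7, 20),
    label = c("WALK", "FOG", "WALK")), "S")
  # overlap 1.7 s >= 1.5 s
  expect_equal(label_window(9, 12, trk3), "FOG")

  trk4 <- annotation_track(data.frame(
    start_s = 0, end_s = 30, label = "STOP"), "S")
  expect_equal(label_window(9, 12, trk4), "STOP")

  # the episode-duration reading differs for long, barely-touching episodes
  expect_equal(label_window(9, 12, trk2, fog_rule = "episode"), "FOG")
  expect_error(label_window(25, 28, trk2), "coverage")
})

test_that("labeling agrees with continuous and sample-level brute force", {
  set.seed(21)
  cfg <- window_config()
  for (i in 1:300) {
    iv <- random_grid_track(30, fs = 128)
    trk <- annotation_track(iv, "S")
    start <- sample(0:(27 * 128), 1) / 128
    got <- label_window(start, start + 3, trk, cfg)
    expect_identical(got, label_window_brute(start, start + 3,
                                             trk$intervals, 3))
    expect_identical(got, label_window_samples(start, start + 3,
                                               trk$intervals, 3, 128))
  }
})

test_that("build_windows labels every window of an annotated session", {
  iv <- data.frame(start_s = c(0, 12, 14, 22), end_s = c(12, 14, 22, 30),
                   label = c("WALK", "FOG", "WALK", "STOP"))
  trk <- annotation_track(iv, "S1")
  rec <- imu_recording(matrix(rnorm(3840 * 6), ncol = 6), "S1")
  ws <- build_windows(list(rec), list(trk), verbose = FALSE)
  expect_equal(length(ws$label), 109L)  # K for N = 3840
  # brute-force every span
  exp_lab <- vapply(seq_along(ws$start_index), function(k) {
    s <- ws$start_index[k] / 128
    label_window_brute(s, s + 3, iv, 3)
  }, character(1))
  expect_identical(as.character(ws$label), exp_lab)
  expect_true(any(exp_lab == "FOG"))
  # class counts sum to K, one label per window
  expect_equal(sum(table(ws$label)), 109)
})

test_that("sessions without FoG yield no FOG windows; subjects partition", {
  coh <- tiny_cohort(n_subjects = 2, session_s = 30, seed = 5,
                     episode_rate = 0)
  ws <- build_windows(coh$recordings, coh$tracks, verbose = FALSE)
  expect_equal(sum(ws$label == "FOG"), 0L)
  expect_setequal(unique(ws$subject), c("S01", "S02"))
  # windows of each subject reference that subject's recording length
  for (sid in c("S01", "S02")) {
    ks <- sum(ws$subject == sid)
    rec <- coh$recordings[[match(sid, c("S01", "S02"))]]
    expect_equal(ks, count_windows(nrow(rec$samples), ws$config))
  }
  # subject mismatch errors
  t2 <- coh$tracks
  t2[[1]]$subject_id <- "WRONG"
  expect_error(build_windows(coh$recordings, t2, verbose = FALSE),
               "mismatch")
})
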