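test_that("default architecture matches the published geometry", {
  cfg <- model_config()
  g <- fogwatch:::.nn_geometry(cfg)
  expect_equal(cfg$conv_filters, c(100L, 40L))
  expect_equal(cfg$kernel_size, c(10L, 10L))
  # 384 -> conv 375 -> maxpool3 125 -> conv 116 -> avgpool2 58 -> 2320
  expect_equal(g$stages[[1]]$L_conv, 375L)
  expect_equal(g$stages[[1]]$L_pool, 125L)
  expect_equal(g$stages[[2]]$L_conv, 116L)
  expect_equal(g$stages[[2]]$L_pool, 58L)
  expect_equal(g$flat, 2320L)
  set.seed(1)
  p <- fogwatch:::.nn_init(cfg, g)
  expect_equal(ncol(p$dense$W), 3L)         # three output nodes
  expect_equal(ncol(p$conv[[1]]$W), 100L)
  expect_equal(ncol(p$conv[[2]]$W), 40L)
})

test_that("impossible geometries raise configuration errors", {
  expect_error(model_config(kernel_size = 400), "conv stage 1")
  expect_error(
    model_config(conv_filters = c(10, 10, 10, 10, 10),
                 kernel_size = 12,
                 pool = rep(list(list("max", 6)), 5)),
    "stage")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  cfg <- model_config(conv_filters = c(4, 3), kernel_size = 3,
                      pool = list(list("max", 2), list("avg", 2)),
                      dropout_rate = 0, window_n = 20, n_channels = 2)
  geom <- fogwatch:::.nn_geometry(cfg)
  params <- fogwatch:::.nn_init(cfg, geom)
  X <- array(rnorm(5 * 20 * 2), c(5, 20, 2))
  y <- factor(sample(c("FOG", "STOP", "WALK"), 5, TRUE),
              levels = c("FOG", "STOP", "WALK"))
  Y <- fogwatch:::.onehot(y, c("FOG", "STOP", "WALK"))
  fw <- fogwatch:::.nn_forward(params, X, cfg, geom, keep = TRUE)
  gr <- fogwatch:::.nn_backward(params, X, Y, fw, cfg, geom)
  lossfn <- function(p)
    fogwatch:::.nn_loss(fogwatch:::.nn_forward(p, X, cfg, geom)$P, Y)
  eps <- 1e-6
  check_tensor <- function(getter, setter, ga) {
    for (j in sample(length(ga), min(8, length(ga)))) {
      pp <- setter(params, j, eps)
      pm <- setter(params, j, -eps)
      num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      expect_lt(abs(num - ga[j]), 1e-6)
    }
  }
  check_tensor(NULL, function(p, j, e) { p$conv[[1]]$W[j] <- p$conv[[1]]$W[j] + e; p },
               gr$conv[[1]]$W)
  check_tensor(NULL, function(p, j, e) { p$conv[[2]]$W[j] <- p$conv[[2]]$W[j] + e; p },
               gr$conv[[2]]$W)
  check_tensor(NULL, function(p, j, e) { p$conv[[1]]$b[j] <- p$conv[[1]]$b[j] + e; p },
               gr$conv[[1]]$b)
  check_tensor(NULL, function(p, j, e) { p$dense$W[j] <- p$dense$W[j] + e; p },
               gr$dense$W)
})

test_that("separable tone classes are learned to near-perfect accuracy", {
  tw <- tone_windows(n_per_class = 25)
  # dropout off: this probes raw capacity to separate the two tones
  fit <- fog_cnn(tw$data, tw$labels, config = tiny_config(dropout_rate = 0),
                 control = train_control(max_epochs = 20, batch_size = 16,
                                         patience = 20, learning_rate = 3e-3,
                                         seed = 7))
  acc <- mean(predict(fit, tw$data) == tw$labels)
  expect_gte(acc, 0.99)
  # memorization: training exemplars map to their own labels
  idx <- sample(length(tw$labels), 10)
  expect_equal(as.character(predict(fit, tw$data[idx, , , drop = FALSE])),
               as.character(tw$labels[idx]))
})

test_that("training is deterministic given the seed", {
  tw <- tone_windows(n_per_class = 10, seed = 3)
  ctl <- train_control(max_epochs = 3, batch_size = 16, seed = 99)
  f1 <- fog_cnn(tw$data, tw$labels, config = tiny_config(), control = ctl)
  f2 <- fog_cnn(tw$data, tw$labels, config = tiny_config(), control = ctl)
  expect_identical(f1$history$train_loss[1], f2$history$train_loss[1])
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("predictions are simplex-valued, repeatable, order-preserving", {
  tw <- tone_windows(n_per_class = 5, seed = 4)
  fit <- fog_cnn(tw$data, tw$labels, config = tiny_config(),
                 control = train_control(max_epochs = 2, batch_size = 8,
                                         seed = 1))
  X <- array(rnorm(200 * 64 * 6), c(200, 64, 6))
  P <- predict(fit, X, type = "prob")
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(rowSums(P), rep(1, 200), tolerance = 1e-6)
  # dropout inactive at inference: identical repeated passes
  expect_identical(P, predict(fit, X, type = "prob"))
  # batch predictions preserve order and equal single-window calls
  P5 <- predict(fit, X[1:5, , , drop = FALSE], type = "prob")
  for (i in 1:5)
    expect_equal(unname(P5[i, ]),
                 unname(predict(fit, X[i, , ], type = "prob")[1, ]))
  expect_error(predict(fit, X[, 1:10, ]), "shape|match")
})

test_that("training rejects degenerate inputs", {
  tw <- tone_windows(n_per_class = 5)
  one_class <- rep(factor("FOG", levels = c("FOG", "STOP", "WALK")), 15)
  expect_error(fog_cnn(tw$data, one_class, config = tiny_config()),
               "two classes")
  expect_error(fog_cnn(array(0, c(0, 64, 6)),
                       factor(character(0),
                              levels = c("FOG", "STOP", "WALK")),
                       config = tiny_config()))
})

test_that("early stopping restores the best validation weights", {
  tw <- tone_windows(n_per_class = 15, seed = 6)
  ctl <- train_control(max_epochs = 25, batch_size = 16, patience = 3,
                       seed = 2)
  fit <- fog_cnn(tw$data, tw$labels, config = tiny_config(), control = ctl)
  h <- fit$history
  expect_lte(nrow(h), 25)
  expect_equal(fit$best_val_loss, min(h$val_loss))
  expect_equal(h$val_loss[fit$best_epoch], min(h$val_loss))
  # stopped within patience epochs of the best
  expect_lte(nrow(h), fit$best_epoch + ctl$patience)
})

test_that("shuffled labels plateau near the entropy of three classes", {
  tw <- tone_windows(n_per_class = 20, seed = 8)
  set.seed(1)
  shuffled <- sample(tw$labels)
  fit <- fog_cnn(tw$data, shuffled, config = tiny_config(),
                 control = train_control(max_epochs = 10, batch_size = 16,
                                         validation_fraction = 0.25,
                                         seed = 3))
  expect_lt(abs(fit$best_val_loss - log(3)), 0.3)
})

test_that("hyperparameter search returns the inner-validation argmin", {
  tw <- tone_windows(n_per_class = 12, seed = 5)
  ws <- structure(list(data = tw$data, label = tw$labels,
                       subject = rep("S01", length(tw$labels)),
                       start_index = seq_along(tw$labels),
                       config = window_config(), scales = rep(1, 6),
                       fog_rule = "overlap"),
                  class = "fog_windows")
  ctl <- train_control(max_epochs = 3, batch_size = 16, seed = 11)
  # budget 1 with only the default-candidate returns it
  res1 <- fog_cnn_search(ws, control = ctl,
                         candidates = list(tiny_config()))
  expect_equal(res1$best_config$conv_filters, c(8L, 4L))
  # two candidates: the returned one has the lower logged loss
  res2 <- fog_cnn_search(ws, control = ctl,
                         candidates = list(
                           tiny_config(),
                           model_config(conv_filters = 4, kernel_size = 3,
                                        pool = list(list("max", 2)),
                                        dropout_rate = 0.2,
                                        window_n = 64)))
  expect_equal(res2$best_val_loss, min(res2$trials$val_loss, na.rm = TRUE))
  # random search with a fixed seed draws an identical trial sequence
  ra <- fog_cnn_search(ws, n_trials = 2, control = ctl, depth = 2:3,
                       filter_range = c(4L, 8L), kernel_range = c(3L, 5L))
  rb <- fog_cnn_search(ws, n_trials = 2, control = ctl, depth = 2:3,
                       filter_range = c(4L, 8L), kernel_range = c(3L, 5L))
  expect_identical(ra$trials, rb$trials)
})

test_that("checkpoints round-trip through JSON", {
  tw <- tone_windows(n_per_class = 6, seed = 9)
  fit <- fog_cnn(tw$data, tw$labels, config = tiny_config(),
                 control = train_control(max_epochs = 2, batch_size = 8,
                                         seed = 4))
  fit$scales <- structure(setNames(rep(2, 6),
                                   c("ax", "ay", "az", "gx", "gy", "gz")),
                          class = "fog_scales")
  fit$window_config <- window_config(window_s = 0.5, fs = 128)
  p <- withr::local_tempfile(fileext = ".json")
  write_fog_cnn(fit, p)
  back <- read_fog_cnn(p)
  X <- tw$data[1:4, , , drop = FALSE]
  expect_equal(predict(back, X, type = "prob"),
               predict(fit, X, type = "prob"), tolerance = 1e-12)
  expect_equal(as.numeric(back$scales), rep(2, 6))
  expect_equal(back$window_config$window_n, 64L)
})
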