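#' CNN architecture configuration
#'
#' The default architecture mirrors the single-wrist FoG detector: two 1D
#' convolution stages over the 384 x 6 window (valid padding, stride 1,
#' ReLU) with 100 and 40 filters and kernel size 10; the first stage is
#' followed by max-pooling of size 3, the second by average-pooling of
#' size 2; the pooled maps are flattened, passed through 50% dropout and a
#' dense softmax layer with three output nodes (FoG, Stop,
#' Walking-with-turns). Stage lengths at the defaults:
#' 384 -> 375 -> 125 -> 116 -> 58, flattened to 2320 features.
#'
#' @param conv_filters Integer vector, filters per convolution stage
#'   (default `c(100, 40)`).
#' @param kernel_size Kernel size, scalar (recycled) or one per stage
#'   (default 10).
#' @param pool List of `list(type =, size =)` per stage, `type` in
#'   `"max"`/`"avg"`; default max-3 then avg-2.
#' @param dropout_rate Dropout fraction before the dense layer
#'   (default 0.5).
#' @param n_classes Number of output classes (default 3).
#' @param window_n Input window length in samples (default 384).
#' @param n_channels Input channels (default 6).
#' @param global_pool If `TRUE`, replace flattening by global average
#'   pooling over the final feature maps (one value per feature detector).
#' @return An object of class `fog_cnn_config`.
#' @export
model_config <- function(conv_filters = c(100L, 40L), kernel_size = 10L,
                         pool = list(list(type = "max", size = 3L),
                                     list(type = "avg", size = 2L)),
                         dropout_rate = 0.5, n_classes = 3L,
                         window_n = 384L, n_channels = 6L,
                         global_pool = FALSE) {
  conv_filters <- as.integer(conv_filters)
  kernel_size <- as.integer(rep_len(kernel_size, length(conv_filters)))
  if (length(pool) != length(conv_filters))
    stop("'pool' must have one entry per convolution stage")
  pool <- lapply(pool, function(p) {
    if (is.character(p[[1]])) list(type = match.arg(p[[1]], c("max", "avg")),
                                   size = as.integer(p[[2]]))
    else stop("pool entries must be list(type =, size =)")
  })
  if (any(kernel_size < 1L)) stop("kernel_size must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  cfg <- structure(
    list(conv_filters = conv_filters, kernel_size = kernel_size,
         pool = pool, dropout_rate = dropout_rate,
         n_classes = as.integer(n_classes),
         window_n = as.integer(window_n),
         n_channels = as.integer(n_channels),
         global_pool = isTRUE(global_pool)),
    class = "fog_cnn_config")
  .nn_geometry(cfg)  # validate geometry now, with a stage-naming error
  cfg
}

#' Training control for the CNN
#'
#' Adam on the categorical cross-entropy, with early stopping on a held
#' out validation split: training halts once the validation loss has
#' failed to improve for `patience` consecutive epochs, and the weights of
#' the best validation epoch are restored.
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Epoch cap (default 200).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param validation_fraction Fraction of the training windows held out
#'   for validation (default 0.1).
#' @param seed Integer seed controlling weight initialization, the
#'   validation split, batch order and dropout masks.
#' @param class_weights `NULL` (default, unweighted), `"balanced"` for
#'   inverse-frequency weights, or a named numeric vector over classes.
#' @return An object of class `fog_train_control`.
#' @export
train_control <- function(learning_rate = 1e-3, batch_size = 64L,
                          max_epochs = 200L, patience = 5L,
                          validation_fraction = 0.1, seed = 1L,
                          class_weights = NULL) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  if (patience < 1L) stop("patience must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 class_weights = class_weights),
            class = "fog_train_control")
}

.as_window_array <- function(x, window_n, n_channels) {
  if (inherits(x, "fog_windows")) x <- x$data
  if (is.matrix(x)) {
    x <- array(x, dim = c(1, nrow(x), ncol(x)))
  }
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("windows must be a fog_windows object, an n x L x C array, ",
         "or a single L x C matrix")
  if (dim(x)[2] != window_n || dim(x)[3] != n_channels)
    stop(sprintf("window shape %d x %d does not match model input %d x %d",
                 dim(x)[2], dim(x)[3], window_n, n_channels))
  x
}

.onehot <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  Y
}

#' Fit the freezing-of-gait CNN
#'
#' Trains the 1D convolutional window classifier on labeled 3-second IMU
#' windows. The run is fully deterministic given `control$seed`: the seed
#' fixes weight initialization, the validation split, the batch order of
#' every epoch and the dropout masks.
#'
#' @param x A `fog_windows` dataset (from [build_windows]) or an
#'   n x window_n x 6 array.
#' @param labels Window labels (factor or character over FOG/STOP/WALK);
#'   taken from `x` when it is a `fog_windows` object.
#' @param config A [model_config].
#' @param control A [train_control].
#' @param verbose Print one line per epoch (default `FALSE`).
#' @return An object of class `fog_cnn` with elements `config`, `control`,
#'   `params` (fitted weights), `history` (per-epoch train/validation
#'   loss), `best_epoch`, `classes`, and — when `x` is a `fog_windows` —
#'   the cohort `scales` and `window_config` needed for self-contained
#'   inference.
#' @examples
#' \donttest{
#' coh <- synthesize_cohort(generator_config(n_subjects = 2, session_s = 30), seed = 1)
#' ws <- build_windows(coh$recordings, coh$tracks, verbose = FALSE)
#' fit <- fog_cnn(ws, control = train_control(max_epochs = 2))
#' table(predict(fit, ws), ws$label)
#' }
#' @export
fog_cnn <- function(x, labels = NULL, config = model_config(),
                    control = train_control(), verbose = FALSE) {
  if (inherits(x, "fog_windows") && is.null(labels)) labels <- x$label
  if (is.null(labels)) stop("'labels' required when x is not fog_windows")
  X <- .as_window_array(x, config$window_n, config$n_channels)
  y <- factor(as.character(labels), levels = FOG_CLASSES)
  if (anyNA(y)) stop("labels outside {FOG, STOP, WALK}")
  n <- dim(X)[1]
  if (n == 0L) stop("empty training set")
  if (length(y) != n) stop("length of labels does not match windows")
  if (nlevels(droplevels(y)) < 2L)
    stop("training set must contain at least two classes")

  geom <- .nn_geometry(config)
  set.seed(control$seed)
  params <- .nn_init(config, geom)

  n_val <- max(1L, round(control$validation_fraction * n))
  if (n_val >= n) stop("validation split leaves no training data")
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , , drop = FALSE]
  Ytr <- .onehot(y[tr_idx], FOG_CLASSES)
  Xval <- X[val_idx, , , drop = FALSE]
  Yval <- .onehot(y[val_idx], FOG_CLASSES)

  w_class <- NULL
  if (!is.null(control$class_weights)) {
    w_class <- if (identical(control$class_weights, "balanced")) {
      tab <- table(factor(y[tr_idx], levels = FOG_CLASSES))
      w <- length(tr_idx) / (3 * pmax(as.numeric(tab), 1))
      stats::setNames(w, FOG_CLASSES)
    } else control$class_weights[FOG_CLASSES]
  }
  row_w <- function(Y) if (is.null(w_class)) NULL else
    as.numeric(Y %*% w_class)

  state <- .adam_init(params)
  ntr <- length(tr_idx)
  bs <- min(control$batch_size, ntr)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L

  val_loss_of <- function(p) {
    tot <- 0; m <- nrow(Xval)
    for (b in split(seq_len(m), ceiling(seq_len(m) / 256))) {
      fw <- .nn_forward(p, Xval[b, , , drop = FALSE], config, geom)
      tot <- tot + .nn_loss(fw$P, Yval[b, , drop = FALSE],
                            row_w(Yval[b, , drop = FALSE])) * length(b)
    }
    tot / m
  }

  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample.int(ntr)
    ep_loss <- 0
    for (b in split(ord, ceiling(seq_along(ord) / bs))) {
      Xb <- Xtr[b, , , drop = FALSE]
      Yb <- Ytr[b, , drop = FALSE]
      fw <- .nn_forward(params, Xb, config, geom, train = TRUE, keep = TRUE)
      wb <- row_w(Yb)
      ep_loss <- ep_loss + .nn_loss(fw$P, Yb, wb) * length(b)
      grads <- .nn_backward(params, Xb, Yb, fw, config, geom, wb)
      st <- .adam_step(params, grads, state, control$learning_rate)
      params <- st$params; state <- st$state
    }
    vl <- val_loss_of(params)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss / ntr,
                                val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / ntr, vl))
    if (vl < best - 1e-8) {
      best <- vl; best_params <- params; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }

  structure(
    list(config = config, control = control, params = best_params,
         geometry = geom, history = history, best_epoch = best_epoch,
         best_val_loss = best, classes = FOG_CLASSES,
         n_train = ntr, n_val = n_val,
         scales = if (inherits(x, "fog_windows")) x$scales,
         window_config = if (inherits(x, "fog_windows")) x$config,
         call = match.call()),
    class = "fog_cnn")
}

#' Predict from a fitted FoG CNN
#'
#' Dropout is inactive at inference, so repeated calls on the same input
#' are identical. Class decisions are the argmax over the softmax
#' probabilities, ties broken by label order (FOG, STOP, WALK).
#'
#' @param object A fitted [fog_cnn].
#' @param newdata A `fog_windows`, an n x window_n x 6 array, or a single
#'   window_n x 6 matrix.
#' @param type `"class"` (default) for labels, `"prob"` for the n x 3
#'   probability matrix.
#' @param batch_size Inference batch size (default 256).
#' @param ... Unused.
#' @return Factor of class labels, or a probability matrix with columns
#'   FOG, STOP, WALK.
#' @export
predict.fog_cnn <- function(object, newdata, type = c("class", "prob"),
                            batch_size = 256L, ...) {
  type <- match.arg(type)
  X <- .as_window_array(newdata, object$config$window_n,
                        object$config$n_channels)
  n <- dim(X)[1]
  P <- matrix(NA_real_, n, object$config$n_classes,
              dimnames = list(NULL, object$classes))
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- .nn_forward(object$params, X[b, , , drop = FALSE],
                      object$config, object$geometry)
    P[b, ] <- fw$P
  }
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.fog_cnn <- function(x, ...) {
  g <- x$geometry
  arch <- paste(vapply(seq_along(g$stages), function(i) {
    st <- g$stages[[i]]
    sprintf("conv(%d,k%d)->%s%d", st$F, st$k, st$pool_type, st$pool_size)
  }, character(1)), collapse = " -> ")
  cat("FoG window CNN\n")
  cat("  architecture:", arch,
      sprintf("-> %s(%d) -> dense(%d)\n",
              if (x$config$global_pool) "gap" else "flatten",
              g$flat, x$config$n_classes))
  cat(sprintf("  trained %d epochs (best %d, val loss %.4f) on %d windows\n",
              nrow(x$history), x$best_epoch, x$best_val_loss, x$n_train))
  invisible(x)
}

#' @export
summary.fog_cnn <- function(object, ...) {
  npar <- sum(rapply(object$params, length, how = "unlist"))
  out <- list(model = object, n_parameters = npar,
              history = object$history)
  class(out) <- "summary.fog_cnn"
  out
}

#' @export
print.summary.fog_cnn <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d trainable parameters\n", x$n_parameters))
  cat("  training history (last 5 epochs):\n")
  print(utils::tail(x$history, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.fog_cnn <- function(object, ...) object$params

#' Plot the training history of a FoG CNN
#'
#' @param x A fitted [fog_cnn].
#' @param ... Passed to [graphics::matplot].
#' @return Invisibly, `x`.
#' @export
plot.fog_cnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Random hyperparameter search for the CNN
#'
#' Samples candidate architectures from the stated search space — network
#' depth in \{2, 3, 4, 5\}, kernel size in \[3, 12\], filters per stage in
#' \[10, 100\] — trains each on the given windows, and returns the
#' configuration with the lowest validation loss (the inner validation
#' split of `control`; test folds are never consulted).
#'
#' @param windows A `fog_windows` training set.
#' @param n_trials Number of sampled candidates (default 5).
#' @param control A [train_control]; its seed also fixes the candidate
#'   draw, so searches are reproducible.
#' @param depth,kernel_range,filter_range Search-space bounds.
#' @param candidates Optional explicit list of [model_config]s, bypassing
#'   sampling.
#' @param verbose Print one line per trial.
#' @return List with `best_config`, `best_val_loss` and `trials` (a data
#'   frame logging every candidate and its validation loss).
#' @export
fog_cnn_search <- function(windows, n_trials = 5L,
                           control = train_control(),
                           depth = 2:5, kernel_range = c(3L, 12L),
                           filter_range = c(10L, 100L),
                           candidates = NULL, verbose = FALSE) {
  if (is.null(candidates)) {
    set.seed(control$seed)
    candidates <- vector("list", n_trials)
    wn <- dim(windows$data)[2]
    for (i in seq_len(n_trials)) {
      d <- sample(depth, 1)
      k <- sample(seq(kernel_range[1], kernel_range[2]), 1)
      f <- sample(seq(filter_range[1], filter_range[2]), d, replace = TRUE)
      pool <- c(list(list(type = "max", size = 3L)),
                rep(list(list(type = "avg", size = 2L)), d - 1L))
      cfg <- try(model_config(conv_filters = f, kernel_size = k,
                              pool = pool, window_n = wn), silent = TRUE)
      candidates[[i]] <- cfg
    }
  }
  ok <- !vapply(candidates, inherits, logical(1), "try-error")
  if (!any(ok)) stop("no geometrically valid candidate configuration")
  trials <- data.frame(trial = seq_along(candidates),
                       depth = NA_integer_, kernel = NA_integer_,
                       filters = NA_character_, val_loss = NA_real_)
  best <- Inf; best_cfg <- NULL
  for (i in seq_along(candidates)) {
    if (!ok[i]) next
    cfg <- candidates[[i]]
    fit <- fog_cnn(windows, config = cfg, control = control)
    trials$depth[i] <- length(cfg$conv_filters)
    trials$kernel[i] <- cfg$kernel_size[1]
    trials$filters[i] <- paste(cfg$conv_filters, collapse = "/")
    trials$val_loss[i] <- fit$best_val_loss
    if (verbose)
      message(sprintf("trial %d: depth %d kernel %d filters %s -> val %.4f",
                      i, trials$depth[i], trials$kernel[i],
                      trials$filters[i], fit$best_val_loss))
    if (fit$best_val_loss < best) {
      best <- fit$best_val_loss; best_cfg <- cfg
    }
  }
  list(best_config = best_cfg, best_val_loss = best, trials = trials)
}

#' Save or load a fitted FoG CNN as a JSON checkpoint
#'
#' The checkpoint is self-contained for inference: it stores the fitted
#' weights together with the architecture, training control, label order,
#' window geometry and — when known — the cohort normalization scales.
#'
#' @param model A fitted [fog_cnn].
#' @param path Checkpoint path (JSON).
#' @return `write_fog_cnn` returns `path` invisibly; `read_fog_cnn`
#'   returns the restored `fog_cnn`.
#' @export
write_fog_cnn <- function(model, path) {
  stopifnot(inherits(model, "fog_cnn"))
  ser_mat <- function(m) list(dim = dim(m), data = as.numeric(m))
  payload <- list(
    format = "fogwatch-cnn-1",
    config = unclass(model$config),
    control = unclass(model$control),
    classes = model$classes,
    scales = as.numeric(model$scales),
    window_config = if (!is.null(model$window_config))
      unclass(model$window_config),
    best_epoch = model$best_epoch,
    best_val_loss = model$best_val_loss,
    history = model$history,
    params = list(
      conv = lapply(model$params$conv,
                    function(s) list(W = ser_mat(s$W), b = s$b)),
      dense = list(W = ser_mat(model$params$dense$W),
                   b = model$params$dense$b)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fog_cnn
#' @export
read_fog_cnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "fogwatch-cnn-1"))
    stop("not a fogwatch CNN checkpoint: ", path)
  num <- function(x) as.numeric(unlist(x))
  cfg <- model_config(
    conv_filters = num(p$config$conv_filters),
    kernel_size = num(p$config$kernel_size),
    pool = lapply(p$config$pool, function(q)
      list(type = q$type, size = as.integer(q$size))),
    dropout_rate = p$config$dropout_rate,
    n_classes = p$config$n_classes,
    window_n = p$config$window_n,
    n_channels = p$config$n_channels,
    global_pool = isTRUE(p$config$global_pool))
  ctrl <- train_control(
    learning_rate = p$control$learning_rate,
    batch_size = p$control$batch_size,
    max_epochs = p$control$max_epochs,
    patience = p$control$patience,
    validation_fraction = p$control$validation_fraction,
    seed = p$control$seed,
    class_weights = if (!is.null(p$control$class_weights))
      unlist(p$control$class_weights))
  de_mat <- function(m) matrix(num(m$data), nrow = m$dim[[1]],
                               ncol = m$dim[[2]])
  params <- list(
    conv = lapply(p$params$conv, function(s)
      list(W = de_mat(s$W), b = num(s$b))),
    dense = list(W = de_mat(p$params$dense$W), b = num(p$params$dense$b)))
  wc <- if (!is.null(p$window_config))
    window_config(p$window_config$window_s, p$window_config$step_s,
                  p$window_config$fs)
  scales <- if (length(p$scales))
    structure(stats::setNames(num(p$scales), IMU_CHANNELS),
              class = "fog_scales")
  hist <- as.data.frame(lapply(
    c("epoch", "train_loss", "val_loss"),
    function(nm) num(lapply(p$history, `[[`, nm))),
    col.names = c("epoch", "train_loss", "val_loss"))
  structure(
    list(config = cfg, control = ctrl, params = params,
         geometry = .nn_geometry(cfg), history = hist,
         best_epoch = p$best_epoch, best_val_loss = p$best_val_loss,
         classes = unlist(p$classes), n_train = NA_integer_,
         n_val = NA_integer_, scales = scales, window_config = wc,
         call = NULL),
    class = "fog_cnn")
}
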