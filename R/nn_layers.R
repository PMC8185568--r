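# Internal neural-network engine: 1D convolution / pooling / dense layers
# with explicit forward and backward passes. Convolutions are lowered to
# GEMM via an im2col index map so all heavy lifting lands in BLAS. Arrays
# are (batch, length, channels); R's column-major order makes the batch
# index fastest, so reshapes below are plain dim<- changes, not copies of
# permuted data.

# Index matrix mapping (batch, position, tap, channel) of an im2col patch
# matrix to linear indices of the (B, L, C) input array. Rows run over
# (batch, output position), columns over (tap, channel).
.im2col_idx <- function(B, L, C, k) {
  Lo <- L - k + 1L
  r <- seq_len(B * Lo)
  b <- (r - 1L) %% B + 1L
  p <- (r - 1L) %/% B + 1L
  base <- b + (p - 2L) * B                       # b + (p-2)*B
  j <- seq_len(k * C)
  kk <- (j - 1L) %% k + 1L
  cc <- (j - 1L) %/% k + 1L
  off <- kk * B + (cc - 1L) * (B * L)
  outer(base, off, "+")
}

# im2col index matrices are a pure function of (batch, geometry); cache
# them per batch size so each epoch reuses the same integer maps.
.cached_idx <- function(cache, B, st, stage_i) {
  key <- sprintf("s%d_b%d", stage_i, B)
  if (is.null(cache[[key]]))
    cache[[key]] <- .im2col_idx(B, st$L_in, st$C_in, st$k)
  cache[[key]]
}

# Valid-padding stride-1 1D convolution, weights W: (k*C_in) x F.
.conv_forward <- function(X, W, bias, idx) {
  Xcol <- X[idx]
  dim(Xcol) <- dim(idx)
  Y <- Xcol %*% W
  Y <- sweep(Y, 2, bias, "+")
  list(Y = Y, Xcol = Xcol)
}

# Scatter dXcol (B*Lo x k*C) back onto the input array: one shifted
# accumulation per kernel tap.
.col2im <- function(dXcol, B, L, C, k) {
  Lo <- L - k + 1L
  dim(dXcol) <- c(B, Lo, k, C)
  dX <- array(0, dim = c(B, L, C))
  for (kk in seq_len(k)) {
    span <- kk:(kk + Lo - 1L)
    sl <- dXcol[, , kk, , drop = FALSE]
    dim(sl) <- c(B, Lo, C)
    dX[, span, ] <- dX[, span, ] + sl
  }
  dX
}

.conv_backward <- function(dY, Xcol, W, dimX, k, need_dx = TRUE) {
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dX <- if (need_dx) {
    dXcol <- tcrossprod(dY, W)
    .col2im(dXcol, dimX[1], dimX[2], dimX[3], k)
  }
  list(dX = dX, dW = dW, db = db)
}

# Non-overlapping pooling of size s along the length axis of (B, Lo, F);
# a trailing remainder shorter than s is dropped.
.pool_forward <- function(Y3, s, type) {
  d <- dim(Y3)
  B <- d[1]; Lo <- d[2]; F <- d[3]
  Lp <- Lo %/% s
  if (Lp * s < Lo) Y3 <- Y3[, seq_len(Lp * s), , drop = FALSE]
  dim(Y3) <- c(B, s, Lp, F)
  slices <- vector("list", s)
  for (si in seq_len(s)) {
    sl <- Y3[, si, , , drop = FALSE]
    dim(sl) <- c(B, Lp, F)
    slices[[si]] <- sl
  }
  if (type == "max") {
    out <- slices[[1]]
    for (si in seq_len(s)[-1]) out <- pmax(out, slices[[si]])
    taken <- array(FALSE, dim = c(B, Lp, F))
    masks <- vector("list", s)
    for (si in seq_len(s)) {
      m <- (slices[[si]] == out) & !taken
      taken <- taken | m
      masks[[si]] <- m
    }
    list(out = out, masks = masks, Lp = Lp)
  } else {
    out <- slices[[1]]
    for (si in seq_len(s)[-1]) out <- out + slices[[si]]
    list(out = out / s, masks = NULL, Lp = Lp)
  }
}

.pool_backward <- function(dOut, s, type, Lo, masks) {
  d <- dim(dOut)
  B <- d[1]; Lp <- d[2]; F <- d[3]
  dA <- array(0, dim = c(B, s, Lp, F))
  for (si in seq_len(s)) {
    dA[, si, , ] <- if (type == "max") dOut * masks[[si]] else dOut / s
  }
  dim(dA) <- c(B, s * Lp, F)
  if (s * Lp < Lo) {
    dY3 <- array(0, dim = c(B, Lo, F))
    dY3[, seq_len(s * Lp), ] <- dA
    dY3
  } else dA
}

# Stage-by-stage output lengths for a model config on a given input
# length; errors if any stage collapses below one sample.
.nn_geometry <- function(config) {
  L <- config$window_n
  stages <- list()
  C_in <- config$n_channels
  for (i in seq_along(config$conv_filters)) {
    k <- config$kernel_size[i]
    Lc <- L - k + 1L
    if (Lc < 1L)
      stop(sprintf(
        "conv stage %d: kernel size %d exceeds input length %d", i, k, L))
    s <- config$pool[[i]]$size
    Lp <- Lc %/% s
    if (Lp < 1L)
      stop(sprintf("pool stage %d: length %d collapses under pool size %d",
                   i, Lc, s))
    stages[[i]] <- list(L_in = L, C_in = C_in, L_conv = Lc, L_pool = Lp,
                        k = k, F = config$conv_filters[i],
                        pool_type = config$pool[[i]]$type,
                        pool_size = s)
    L <- Lp
    C_in <- config$conv_filters[i]
  }
  flat <- if (isTRUE(config$global_pool)) C_in else L * C_in
  list(stages = stages, flat = flat, final_len = L, final_filters = C_in,
       cache = new.env(parent = emptyenv()))
}

# He-initialized parameters; consumes the current RNG stream.
.nn_init <- function(config, geom) {
  params <- list(conv = list())
  for (i in seq_along(geom$stages)) {
    st <- geom$stages[[i]]
    fan_in <- st$k * st$C_in
    params$conv[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * st$F, sd = sqrt(2 / fan_in)),
                 nrow = fan_in),
      b = numeric(st$F))
  }
  params$dense <- list(
    W = matrix(stats::rnorm(geom$flat * config$n_classes,
                            sd = sqrt(2 / geom$flat)),
               nrow = geom$flat),
    b = numeric(config$n_classes))
  params
}

# Forward pass over a batch array (B, L, C). With train = TRUE a dropout
# mask drawn from the current RNG is applied before the dense layer
# (inverted dropout, so inference needs no rescaling). Returns caches for
# the backward pass when `keep` is TRUE.
.nn_forward <- function(params, X, config, geom, train = FALSE,
                        keep = FALSE) {
  B <- dim(X)[1]
  caches <- if (keep) vector("list", length(geom$stages))
  A <- X
  for (i in seq_along(geom$stages)) {
    st <- geom$stages[[i]]
    idx <- .cached_idx(geom$cache, B, st, i)
    cf <- .conv_forward(A, params$conv[[i]]$W, params$conv[[i]]$b, idx)
    relu_mask <- cf$Y > 0
    Y <- cf$Y * relu_mask
    Y3 <- Y
    dim(Y3) <- c(B, st$L_conv, st$F)
    pf <- .pool_forward(Y3, st$pool_size, st$pool_type)
    if (keep)
      caches[[i]] <- list(Xcol = cf$Xcol, relu_mask = relu_mask,
                          dimA = dim(A), masks = pf$masks)
    A <- pf$out
  }
  if (isTRUE(config$global_pool)) {
    pooled_len <- dim(A)[2]
    H <- apply(A, c(1, 3), mean)
  } else {
    pooled_len <- NULL
    H <- A
    dim(H) <- c(B, geom$flat)
  }
  drop_mask <- NULL
  if (train && config$dropout_rate > 0) {
    drop_mask <- matrix(
      stats::runif(length(H)) >= config$dropout_rate,
      nrow = B) / (1 - config$dropout_rate)
    H <- H * drop_mask
  }
  logits <- sweep(H %*% params$dense$W, 2, params$dense$b, "+")
  m <- apply(logits, 1, max)
  E <- exp(logits - m)
  P <- E / rowSums(E)
  list(P = P, H = H, caches = caches, drop_mask = drop_mask,
       pooled_len = pooled_len, pooled_dim = dim(A))
}

# Mean (optionally class-weighted) categorical cross-entropy.
.nn_loss <- function(P, y_onehot, w = NULL) {
  ll <- -rowSums(y_onehot * log(pmax(P, 1e-12)))
  if (is.null(w)) mean(ll) else sum(w * ll) / sum(w)
}

# Backward pass; fw must come from .nn_forward(..., keep = TRUE).
.nn_backward <- function(params, X, y_onehot, fw, config, geom, w = NULL) {
  B <- dim(X)[1]
  if (is.null(w)) {
    dlogits <- (fw$P - y_onehot) / B
  } else {
    dlogits <- (fw$P - y_onehot) * (w / sum(w))
  }
  grads <- list(conv = vector("list", length(geom$stages)))
  grads$dense <- list(W = crossprod(fw$H, dlogits), b = colSums(dlogits))
  dH <- tcrossprod(dlogits, params$dense$W)
  if (!is.null(fw$drop_mask)) dH <- dH * fw$drop_mask
  if (isTRUE(config$global_pool)) {
    pd <- fw$pooled_dim
    dA <- array(0, dim = pd)
    for (l in seq_len(pd[2])) dA[, l, ] <- dH / pd[2]
  } else {
    dA <- dH
    dim(dA) <- fw$pooled_dim
  }
  for (i in rev(seq_along(geom$stages))) {
    st <- geom$stages[[i]]
    ca <- fw$caches[[i]]
    dY3 <- .pool_backward(dA, st$pool_size, st$pool_type, st$L_conv,
                          ca$masks)
    dY <- dY3
    dim(dY) <- c(B * st$L_conv, st$F)
    dY <- dY * ca$relu_mask
    cb <- .conv_backward(dY, ca$Xcol, params$conv[[i]]$W, ca$dimA, st$k,
                         need_dx = i > 1L)
    grads$conv[[i]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  grads
}

# Adam optimizer state and update over the nested parameter list.
.adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (i in seq_along(params$conv)) {
    for (nm in c("W", "b")) {
      u <- upd(params$conv[[i]][[nm]], grads$conv[[i]][[nm]],
               state$m$conv[[i]][[nm]], state$v$conv[[i]][[nm]])
      params$conv[[i]][[nm]] <- u$p
      state$m$conv[[i]][[nm]] <- u$m
      state$v$conv[[i]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(params$dense[[nm]], grads$dense[[nm]],
             state$m$dense[[nm]], state$v$dense[[nm]])
    params$dense[[nm]] <- u$p
    state$m$dense[[nm]] <- u$m
    state$v$dense[[nm]] <- u$v
  }
  list(params = params, state = state)
}
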