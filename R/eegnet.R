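#' Build a compact convolutional EEG decoder (EEGNet architecture)
#'
#' Constructs the standard EEGNet layer graph: a temporal convolution bank
#' (F1 filters, 64-tap kernels at 128 Hz), batch-norm, a depthwise spatial
#' convolution over channels (depth multiplier D, max-norm constrained),
#' batch-norm + ELU + average pooling (4) + dropout, a separable
#' convolution (16-tap depthwise followed by a pointwise convolution to F2
#' filters), batch-norm + ELU + average pooling (8) + dropout, and a dense
#' softmax head. All convolutions are bias-free; a freshly built model is
#' therefore bias-free after canonicalization (batch-norm shifts are zero
#' at initialization).
#'
#' @param n_channels,n_times input geometry (channels x samples).
#' @param F1 number of temporal filters (default 8).
#' @param D spatial depth multiplier (default 2).
#' @param F2 number of pointwise filters (default 16).
#' @param kern_t temporal kernel length in samples (default 64).
#' @param kern_sep separable depthwise kernel length (default 16).
#' @param pool1,pool2 average-pooling factors (defaults 4 and 8).
#' @param dropout dropout rate (default 0.25, the subject-independent
#'   recommendation).
#' @param n_classes number of output classes (default 2).
#' @param seed optional RNG seed for weight initialization (Glorot
#'   uniform); two builds with the same seed have identical weights.
#' @return object of class `eegnet`.
#' @export
build_eegnet <- function(n_channels, n_times, F1 = 8L, D = 2L, F2 = 16L,
                         kern_t = 64L, kern_sep = 16L, pool1 = 4L,
                         pool2 = 8L, dropout = 0.25, n_classes = 2L,
                         seed = NULL) {
  if (n_times < kern_t)
    stop("n_times must be at least the temporal kernel length")
  if (!is.null(seed)) set.seed(seed)
  M <- F1 * D
  t1 <- n_times %/% pool1
  t2 <- t1 %/% pool2
  if (t2 < 1) stop("n_times too short for the pooling chain")
  n_flat <- F2 * t2
  glorot <- function(fan_in, fan_out, dims) {
    lim <- sqrt(6 / (fan_in + fan_out))
    array(runif(prod(dims), -lim, lim), dim = dims)
  }
  params <- list(
    Wt  = glorot(kern_t, kern_t * F1, c(kern_t, F1)),
    bn1 = list(gamma = rep(1, F1), beta = rep(0, F1),
               mean = rep(0, F1), var = rep(1, F1)),
    Ws  = glorot(n_channels, n_channels * D, c(n_channels, D, F1)),
    bn2 = list(gamma = rep(1, M), beta = rep(0, M),
               mean = rep(0, M), var = rep(1, M)),
    Wsep = glorot(kern_sep, kern_sep, c(kern_sep, M)),
    Wpw  = glorot(M, F2, c(M, F2)),
    bn3 = list(gamma = rep(1, F2), beta = rep(0, F2),
               mean = rep(0, F2), var = rep(1, F2)),
    Wd = glorot(n_flat, n_classes, c(n_flat, n_classes)),
    bd = rep(0, n_classes),
    b1 = rep(0, F1), b2 = rep(0, M), b3 = rep(0, F2)
  )
  structure(list(
    dims = list(C = as.integer(n_channels), Tn = as.integer(n_times),
                F1 = as.integer(F1), D = as.integer(D), F2 = as.integer(F2),
                M = as.integer(M), kern_t = as.integer(kern_t),
                kern_sep = as.integer(kern_sep), pool1 = as.integer(pool1),
                pool2 = as.integer(pool2), t1 = as.integer(t1),
                t2 = as.integer(t2), n_flat = as.integer(n_flat),
                n_classes = as.integer(n_classes),
                padL_t = as.integer((kern_t - 1) %/% 2),
                padL_s = as.integer((kern_sep - 1) %/% 2)),
    params = params, dropout = dropout, canonical = FALSE,
    bn_eps = 1e-3), class = "eegnet")
}

#' @export
print.eegnet <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<eegnet> C=%d T=%d F1=%d D=%d F2=%d%s, %d parameters\n",
    d$C, d$Tn, d$F1, d$D, d$F2,
    if (x$canonical) " (canonical)" else "", eegnet_n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of an eegnet model
#' @param model eegnet
#' @return integer count (batch-norm running statistics excluded).
#' @export
eegnet_n_params <- function(model) {
  p <- model$params
  bn <- function(b) length(b$gamma) + length(b$beta)
  length(p$Wt) + length(p$Ws) + length(p$Wsep) + length(p$Wpw) +
    length(p$Wd) + length(p$bd) +
    (if (model$canonical) length(p$b1) + length(p$b2) + length(p$b3)
     else bn(p$bn1) + bn(p$bn2) + bn(p$bn3))
}

#' Ordered layer identifiers of the network
#'
#' @param model eegnet
#' @return character vector of layer ids, in forward order. Convolutional
#'   layers (valid CRP/activation-map targets) are `"temporal_conv"`,
#'   `"spatial_conv"`, `"sep_conv"` and `"pointwise_conv"`; the pointwise
#'   convolution is the network's last (16-filter) convolution.
#' @export
eegnet_layers <- function(model) {
  if (model$canonical)
    c("temporal_conv", "spatial_conv", "elu1", "pool1", "dropout1",
      "sep_conv", "pointwise_conv", "elu2", "pool2", "dropout2",
      "flatten", "dense")
  else
    c("temporal_conv", "bn1", "spatial_conv", "bn2", "elu1", "pool1",
      "dropout1", "sep_conv", "pointwise_conv", "bn3", "elu2", "pool2",
      "dropout2", "flatten", "dense")
}

elu_fun <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}

# mean-pool along the first dimension by factor p (tail truncated)
pool_fwd <- function(X, p) {
  d <- dim(X)
  Tt <- d[1] - d[1] %% p
  if (Tt < d[1]) X <- X[seq_len(Tt), , , drop = FALSE]
  Y <- colMeans(matrix(X, nrow = p))
  dim(Y) <- c(Tt %/% p, d[2], d[3])
  Y
}

pool_bwd <- function(dY, p, T_orig) {
  d <- dim(dY)
  v <- rep(as.vector(dY) / p, each = p)
  dim(v) <- c(d[1] * p, d[2], d[3])
  if (d[1] * p < T_orig) {
    out <- array(0, c(T_orig, d[2], d[3]))
    out[seq_len(d[1] * p), , ] <- v
    v <- out
  }
  v
}

# thin wrappers over the flat-tensor convolution kernels
conv_fwd <- function(X, W, padL) {
  d <- dim(X)
  y <- cpp_conv_fwd(X, d[1], prod(d[-1]), W, padL)
  dim(y) <- c(d[1], prod(d[-1]), ncol(W))
  y
}

# internal forward pass; x is [n, C, T]
eegnet_forward <- function(model, x, training = FALSE,
                           return_cache = FALSE) {
  d <- model$dims
  p <- model$params
  stopifnot(length(dim(x)) == 3, dim(x)[2] == d$C, dim(x)[3] == d$Tn)
  n <- dim(x)[1]
  eps <- model$bn_eps
  dims4 <- c(d$Tn, d$C, n, d$F1)
  L1 <- d$Tn * d$C * n                   # elements per temporal filter

  X0m <- aperm(x, c(3, 2, 1))                      # [T, C, n]
  dim(X0m) <- c(d$Tn, d$C * n)
  A1 <- cpp_conv_fwd(X0m, d$Tn, d$C * n, p$Wt, d$padL_t)  # flat TCnF1
  if (model$canonical) {
    for (f in seq_len(d$F1))
      if (p$b1[f] != 0) {
        rng <- ((f - 1) * L1 + 1):(f * L1)
        A1[rng] <- A1[rng] + p$b1[f]
      }
    A1bn <- A1; bn1s <- NULL
  } else {
    bn1s <- cpp_bn_fwd(A1, p$bn1$gamma, p$bn1$beta, p$bn1$mean,
                       p$bn1$var, eps, training)
    A1bn <- bn1s$y                       # flat [T, C, n, F1]
  }

  Z <- cpp_spatial_fwd(A1bn, p$Ws, dims4)          # flat [T, M, n]
  dim(Z) <- c(d$Tn, d$M, n)
  if (model$canonical) {
    bn2s <- NULL
    for (m in seq_len(d$M))
      if (p$b2[m] != 0) Z[, m, ] <- Z[, m, ] + p$b2[m]
    Z2 <- Z
  } else {
    Zm <- aperm(Z, c(1, 3, 2))
    bn2s <- cpp_bn_fwd(Zm, p$bn2$gamma, p$bn2$beta, p$bn2$mean,
                       p$bn2$var, eps, training)
    Zy <- bn2s$y; dim(Zy) <- c(d$Tn, n, d$M)
    Z2 <- aperm(Zy, c(1, 3, 2))
  }

  E1 <- elu_fun(Z2)
  P1 <- pool_fwd(E1, d$pool1)                      # [t1, M, n]
  if (training && model$dropout > 0) {
    mask1 <- (runif(length(P1)) >= model$dropout) / (1 - model$dropout)
    dim(mask1) <- dim(P1)
    D1 <- P1 * mask1
  } else {
    mask1 <- NULL; D1 <- P1
  }

  S <- array(0, dim(D1))                           # depthwise time conv
  for (m in seq_len(d$M))
    S[, m, ] <- cpp_conv_fwd(D1[, m, , drop = TRUE], d$t1, n,
                             p$Wsep[, m, drop = FALSE], d$padL_s)

  Sm <- aperm(S, c(2, 1, 3)); dim(Sm) <- c(d$M, d$t1 * n)
  PWm <- crossprod(p$Wpw, Sm)                      # [F2, t1*n]
  if (model$canonical) {
    bn3s <- NULL
    PWy <- PWm + p$b3
  } else {
    bn3s <- cpp_bn_fwd(t(PWm), p$bn3$gamma, p$bn3$beta, p$bn3$mean,
                       p$bn3$var, eps, training)
    PWy <- matrix(bn3s$y, d$t1 * n, d$F2)
    PWy <- t(PWy)
  }
  PW3 <- aperm(array(PWy, c(d$F2, d$t1, n)), c(2, 1, 3))  # [t1, F2, n]

  E2 <- elu_fun(PW3)
  P2 <- pool_fwd(E2, d$pool2)                      # [t2, F2, n]
  if (training && model$dropout > 0) {
    mask2 <- (runif(length(P2)) >= model$dropout) / (1 - model$dropout)
    dim(mask2) <- dim(P2)
    D2 <- P2 * mask2
  } else {
    mask2 <- NULL; D2 <- P2
  }
  flat <- aperm(D2, c(1, 2, 3)); dim(flat) <- c(d$n_flat, n)
  logitm <- crossprod(p$Wd, flat) + p$bd           # [n_classes, n]

  probs <- apply(logitm, 2, function(v) {
    e <- exp(v - max(v)); e / sum(e)
  })
  out <- list(logits = t(logitm), probs = t(probs))
  if (return_cache)
    out$cache <- list(X0m = X0m, A1 = A1, A1bn = A1bn, bn1s = bn1s,
                      Z = Z, Z2 = Z2, bn2s = bn2s, E1 = E1, P1 = P1,
                      mask1 = mask1, D1 = D1, S = S, Sm = Sm, PWm = PWm,
                      PW3 = PW3, bn3s = bn3s, E2 = E2, P2 = P2,
                      mask2 = mask2, D2 = D2, flat = flat,
                      logitm = logitm, n = n, dims4 = dims4)
  out
}

#' Class predictions from an eegnet model
#'
#' @param model eegnet
#' @param x array `[n, C, T]` or an [epoch_set()].
#' @return list with `logits` `[n, n_classes]`, `probs` and hard `class`
#'   (0-based).
#' @export
eegnet_predict <- function(model, x) {
  if (inherits(x, "epoch_set")) x <- x$data
  out <- eegnet_forward(model, x, training = FALSE)
  out$class <- max.col(out$probs) - 1L
  out
}

#' Activation maps of a convolutional layer
#'
#' Runs the forward pass up to (and including) the requested convolutional
#' layer and returns its filter activation maps. The model is
#' canonicalized first, so batch-norm scaling is part of the returned
#' maps.
#'
#' @param model eegnet
#' @param x array `[n, C, T]` or [epoch_set()].
#' @param layer_id one of `"temporal_conv"`, `"spatial_conv"`,
#'   `"sep_conv"`, `"pointwise_conv"`.
#' @return array `[n, n_filters, map_len]`.
#' @export
forward_activations <- function(model, x, layer_id = "pointwise_conv") {
  if (inherits(x, "epoch_set")) x <- x$data
  conv_layers <- c("temporal_conv", "spatial_conv", "sep_conv",
                   "pointwise_conv")
  if (!layer_id %in% conv_layers)
    stop("layer_id must be a convolutional layer: ",
         paste(conv_layers, collapse = ", "))
  model <- canonicalize(model)
  cc <- eegnet_forward(model, x, training = FALSE, return_cache = TRUE)$cache
  d <- model$dims
  n <- dim(x)[1]
  switch(layer_id,
    temporal_conv = {
      A <- cc$A1bn                       # flat [T, C, n, F1]
      dim(A) <- cc$dims4
      A <- aperm(A, c(3, 4, 2, 1))       # [n, F1, C, T]
      dim(A) <- c(n, d$F1, d$C * d$Tn)
      A
    },
    spatial_conv = aperm(cc$Z2, c(3, 2, 1)),
    sep_conv = aperm(cc$S, c(3, 2, 1)),
    pointwise_conv = aperm(cc$PW3, c(3, 2, 1)))
}
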