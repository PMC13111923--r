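# Training: softmax cross-entropy, Adam, batch-norm in batch-statistics
# mode, inverted dropout, and the EEGNet max-norm constraints on the
# spatial filters (1.0) and the dense kernel (0.25).

elu_grad <- function(dY, Yelu) {
  idx <- Yelu <= 0
  dY[idx] <- dY[idx] * (Yelu[idx] + 1)
  dY
}

# gradients for one cached forward pass; dlogitm is [n_classes, n]
eegnet_backward <- function(model, cache, dlogitm) {
  d <- model$dims; p <- model$params; eps <- model$bn_eps
  n <- cache$n
  g <- list()
  g$Wd <- cache$flat %*% t(dlogitm)
  g$bd <- rowSums(dlogitm)
  dflat <- p$Wd %*% dlogitm
  dD2 <- array(dflat, c(d$t2, d$F2, n))
  dP2 <- if (is.null(cache$mask2)) dD2 else dD2 * cache$mask2
  dE2 <- pool_bwd(dP2, d$pool2, d$t1)
  dPW3 <- elu_grad(dE2, cache$E2)
  dPWy <- aperm(dPW3, c(2, 1, 3)); dim(dPWy) <- c(d$F2, d$t1 * n)
  bb3 <- cpp_bn_bwd(t(dPWy), cache$bn3s$y, cache$bn3s$mu,
                    cache$bn3s$var, p$bn3$gamma, p$bn3$beta, eps)
  g$g3 <- bb3$dgamma; g$be3 <- bb3$dbeta
  dPWm <- matrix(bb3$dx, d$t1 * n, d$F2)
  dPWm <- t(dPWm)                                    # [F2, t1*n]
  dSm <- p$Wpw %*% dPWm
  g$Wpw <- cache$Sm %*% t(dPWm)
  dS <- aperm(array(dSm, c(d$M, d$t1, n)), c(2, 1, 3))
  dD1 <- array(0, dim(dS))
  g$Wsep <- array(0, dim(p$Wsep))
  for (m in seq_len(d$M)) {
    dsm <- dS[, m, , drop = TRUE]
    dD1[, m, ] <- cpp_conv_gradin(dsm, d$t1, n,
                                  p$Wsep[, m, drop = FALSE], d$padL_s)
    g$Wsep[, m] <- cpp_conv_gradw(cache$D1[, m, , drop = TRUE], dsm,
                                  d$t1, n, d$kern_sep, 1L, d$padL_s)
  }
  dP1 <- if (is.null(cache$mask1)) dD1 else dD1 * cache$mask1
  dE1 <- pool_bwd(dP1, d$pool1, d$Tn)
  dZ2 <- elu_grad(dE1, cache$E1)
  dZm <- aperm(dZ2, c(1, 3, 2))
  bb2 <- cpp_bn_bwd(dZm, cache$bn2s$y, cache$bn2s$mu, cache$bn2s$var,
                    p$bn2$gamma, p$bn2$beta, eps)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  dZy <- bb2$dx; dim(dZy) <- c(d$Tn, n, d$M)
  dZ <- aperm(dZy, c(1, 3, 2))
  dA1bn <- cpp_spatial_gradin(dZ, p$Ws, cache$dims4)
  g$Ws <- cpp_spatial_gradw(cache$A1bn, dZ, cache$dims4, d$D)
  bb1 <- cpp_bn_bwd(dA1bn, cache$A1bn, cache$bn1s$mu, cache$bn1s$var,
                    p$bn1$gamma, p$bn1$beta, eps)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  g$Wt <- cpp_conv_gradw(cache$X0m, bb1$dx, d$Tn, d$C * n, d$kern_t,
                         d$F1, d$padL_t)
  g
}

.param_paths <- list(
  Wt = c("Wt"), g1 = c("bn1", "gamma"), be1 = c("bn1", "beta"),
  Ws = c("Ws"), g2 = c("bn2", "gamma"), be2 = c("bn2", "beta"),
  Wsep = c("Wsep"), Wpw = c("Wpw"),
  g3 = c("bn3", "gamma"), be3 = c("bn3", "beta"),
  Wd = c("Wd"), bd = c("bd"))

#' Train an eegnet model
#'
#' Minimizes softmax cross-entropy with Adam (library-default moments,
#' learning rate 0.001) for a fixed number of epochs without validation
#' stops, with the architecture's max-norm constraints applied after each
#' update. Dropout masks, batch shuffling and (if `seed` is given) weight
#' initialization all draw from R's RNG, so runs are reproducible.
#'
#' @param model eegnet (non-canonical).
#' @param x array `[n, C, T]` or [epoch_set()].
#' @param y 0/1 labels (taken from the epoch set when omitted).
#' @param epochs training epochs (full passes; default 500).
#' @param batch_size minibatch size (default 128).
#' @param lr Adam learning rate.
#' @param seed optional seed set before training.
#' @return trained eegnet; the mean loss per epoch is attached as
#'   attribute `"loss"`.
#' @export
train_eegnet <- function(model, x, y = NULL, epochs = 500L,
                         batch_size = 128L, lr = 1e-3, seed = NULL) {
  if (model$canonical) stop("cannot train a canonicalized model")
  if (inherits(x, "epoch_set")) {
    if (is.null(y)) y <- x$labels
    x <- x$data
  }
  stopifnot(length(y) == dim(x)[1])
  if (length(unique(y)) < 2) stop("training fold contains a single class")
  if (!is.null(seed)) set.seed(seed)
  n <- dim(x)[1]
  p <- model$params
  mstate <- list(); vstate <- list()
  for (nm in names(.param_paths)) {
    val <- model$params[[.param_paths[[nm]]]]
    mstate[[nm]] <- val * 0; vstate[[nm]] <- val * 0
  }
  b1m <- 0.9; b2m <- 0.999; aeps <- 1e-8; tstep <- 0
  mom <- 0.99
  losses <- numeric(epochs)
  onehot <- rbind(1 - y, y)
  if (model$dims$n_classes != 2)
    onehot <- t(sapply(seq_len(model$dims$n_classes) - 1L,
                       function(k) as.numeric(y == k)))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      nb <- length(idx)
      fw <- eegnet_forward(model, x[idx, , , drop = FALSE],
                           training = TRUE, return_cache = TRUE)
      probs <- t(fw$probs)                       # [n_classes, nb]
      yb <- onehot[, idx, drop = FALSE]
      ep_loss <- ep_loss - sum(yb * log(pmax(probs, 1e-12))) / n
      dlog <- (probs - yb) / nb
      g <- eegnet_backward(model, fw$cache, dlog)
      tstep <- tstep + 1
      corr <- sqrt(1 - b2m^tstep) / (1 - b1m^tstep)
      for (nm in names(.param_paths)) {
        gr <- g[[nm]]
        mstate[[nm]] <- b1m * mstate[[nm]] + (1 - b1m) * gr
        vstate[[nm]] <- b2m * vstate[[nm]] + (1 - b2m) * gr * gr
        upd <- lr * corr * mstate[[nm]] / (sqrt(vstate[[nm]]) + aeps)
        model$params[[.param_paths[[nm]]]] <-
          model$params[[.param_paths[[nm]]]] - upd
      }
      # max-norm constraints
      Ws <- model$params$Ws
      for (f1 in seq_len(model$dims$F1)) for (dd in seq_len(model$dims$D)) {
        nrm <- sqrt(sum(Ws[, dd, f1]^2))
        if (nrm > 1) Ws[, dd, f1] <- Ws[, dd, f1] / nrm
      }
      model$params$Ws <- Ws
      Wd <- model$params$Wd
      nrms <- sqrt(colSums(Wd^2))
      over <- nrms > 0.25
      if (any(over))
        Wd[, over] <- sweep(Wd[, over, drop = FALSE], 2,
                            nrms[over] / 0.25, "/")
      model$params$Wd <- Wd
      # running statistics for inference
      for (bn_nm in c("bn1", "bn2", "bn3")) {
        st <- switch(bn_nm, bn1 = fw$cache$bn1s, bn2 = fw$cache$bn2s,
                     bn3 = fw$cache$bn3s)
        model$params[[bn_nm]]$mean <-
          mom * model$params[[bn_nm]]$mean + (1 - mom) * st$mu
        model$params[[bn_nm]]$var <-
          mom * model$params[[bn_nm]]$var + (1 - mom) * st$var
      }
    }
    losses[ep] <- ep_loss
  }
  attr(model, "loss") <- losses
  model
}

#' Subject-independent leave-one-out training
#'
#' Trains one model per held-out subject (and repetition) on the pooled
#' epochs of all remaining subjects, evaluating accuracy on the held-out
#' subject only. Two seed regimes are supported: `"unique"` assigns every
#' fold its own seed, `"same"` gives all folds of a repetition one shared
#' seed (so folds with identical training data yield identical models).
#'
#' @param cohort preprocessed [epoch_set()] with >= 2 subjects.
#' @param seed_mode `"unique"` or `"same"`.
#' @param n_reps number of LOO-CV repetitions.
#' @param epochs,batch_size,lr passed to [train_eegnet()].
#' @param base_seed integer from which all fold seeds are derived.
#' @param hyper optional named list of [build_eegnet()] hyperparameters.
#' @return list of train-run records: `subject`, `rep`, `seed`,
#'   `seed_mode`, `model`, `accuracy`, `n_test`.
#' @export
train_loo <- function(cohort, seed_mode = c("unique", "same"),
                      n_reps = 1L, epochs = 500L, batch_size = 128L,
                      lr = 1e-3, base_seed = 1L, hyper = list()) {
  stopifnot(inherits(cohort, "epoch_set"))
  seed_mode <- match.arg(seed_mode)
  subjects <- unique(cohort$subjects)
  if (length(subjects) < 2) stop("need at least 2 subjects for LOO-CV")
  runs <- list()
  for (r in seq_len(n_reps)) {
    for (si in seq_along(subjects)) {
      su <- subjects[si]
      seed <- base_seed + 7919L * (r - 1L) +
        (if (seed_mode == "unique") si else 0L)
      tr <- subset_epochs(cohort, cohort$subjects != su)
      te <- subset_epochs(cohort, cohort$subjects == su)
      set.seed(seed)
      args <- c(list(n_channels = n_channels(cohort),
                     n_times = n_times(cohort)), hyper)
      model <- do.call(build_eegnet, args)
      model <- train_eegnet(model, tr, epochs = epochs,
                            batch_size = batch_size, lr = lr)
      pred <- eegnet_predict(model, te)
      acc <- mean(pred$class == te$labels)
      runs[[length(runs) + 1L]] <-
        list(subject = su, rep = r, seed = seed, seed_mode = seed_mode,
             model = model, accuracy = acc, n_test = n_epochs(te))
    }
  }
  runs
}
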