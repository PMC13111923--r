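#' Canonical EEG frequency bands
#'
#' Half-open `[lo, hi)` bands: delta 0-4, theta 4-8, alpha 8-12,
#' beta 12-30, gamma 30-60 Hz.
#'
#' @return object of class `band_scheme` (named list of `c(lo, hi)`).
#' @export
band_scheme <- function() {
  structure(list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 12),
                 beta = c(12, 30), gamma = c(30, 60)),
            class = "band_scheme")
}

# real-DFT synthesis matrix: x = B %*% c(re, im) for a length-T signal,
# where (re, im) are the one-sided FFT coefficients (nb = T/2 + 1 bins).
rdft_basis <- function(Tn) {
  nb <- Tn %/% 2 + 1L
  t <- 0:(Tn - 1L)
  f <- 0:(nb - 1L)
  ang <- 2 * pi * outer(t, f) / Tn
  w <- rep(2, nb); w[1] <- 1
  if (Tn %% 2 == 0) w[nb] <- 1
  Bre <- sweep(cos(ang), 2, w / Tn, "*")
  Bim <- sweep(-sin(ang), 2, w / Tn, "*")
  cbind(Bre, Bim)                                  # [T, 2*nb]
}

#' Attach a discrete-Fourier virtual inspection layer
#'
#' Inserts an invertible DFT/inverse-DFT pair before the network's input:
#' the forward pass transforms each channel to its one-sided Fourier
#' coefficients and synthesizes the time signal back, so predictions are
#' unchanged, while relevance can be read out at the coefficient layer in
#' the frequency domain. The model is canonicalized first.
#'
#' @param model eegnet
#' @return model with the VIL basis attached (`model$vil`).
#' @export
attach_vil <- function(model) {
  model <- canonicalize(model)
  model$vil <- list(basis = rdft_basis(model$dims$Tn),
                    n_bins = model$dims$Tn %/% 2 + 1L)
  model
}

# one-sided FFT coefficients per channel: x [n, C, T] ->
# list(re, im) arrays [n, C, nb]
rfft_epochs <- function(x) {
  n <- dim(x)[1]; C <- dim(x)[2]; Tn <- dim(x)[3]
  nb <- Tn %/% 2 + 1L
  Xm <- aperm(x, c(3, 2, 1)); dim(Xm) <- c(Tn, C * n)
  Z <- mvfft(Xm)[seq_len(nb), , drop = FALSE]
  re <- Re(Z); im <- Im(Z)
  dim(re) <- c(nb, C, n); dim(im) <- c(nb, C, n)
  list(re = aperm(re, c(3, 2, 1)), im = aperm(im, c(3, 2, 1)))
}

# VIL round-trip reconstruction of x through the synthesis matrix
vil_reconstruct <- function(model, x) {
  if (is.null(model$vil)) stop("no VIL attached")
  z <- rfft_epochs(x)
  n <- dim(x)[1]; C <- dim(x)[2]; Tn <- dim(x)[3]
  nb <- model$vil$n_bins
  rem <- aperm(z$re, c(3, 2, 1)); dim(rem) <- c(nb, C * n)
  imm <- aperm(z$im, c(3, 2, 1)); dim(imm) <- c(nb, C * n)
  Xrec <- model$vil$basis %*% rbind(rem, imm)      # [T, C*n]
  dim(Xrec) <- c(Tn, C, n)
  aperm(Xrec, c(3, 2, 1))
}

#' Forward pass through the VIL-augmented model
#'
#' @param model VIL-attached eegnet (see [attach_vil()]).
#' @param x array `[n, C, T]` or [epoch_set()].
#' @return as [eegnet_predict()], computed on the DFT round-tripped input.
#' @export
predict_with_vil <- function(model, x) {
  if (inherits(x, "epoch_set")) x <- x$data
  eegnet_predict(model, vil_reconstruct(model, x))
}

#' Relevance in the frequency domain
#'
#' Computes the (optionally filter-conditioned) time-domain heatmap and
#' propagates it one step further through the virtual inspection layer:
#' the DFT synthesis is a bias-free invertible linear map, through which
#' relevance is redistributed proportionally to each coefficient's signal
#' contribution (exactly conserving the per-sample total). Per-bin
#' relevance is the sum of the bin's real and imaginary coefficient
#' relevances.
#'
#' @param model VIL-attached eegnet.
#' @param x array `[n, C, T]` or [epoch_set()]; `sfreq` is taken from the
#'   epoch set, else 128 Hz is assumed unless given.
#' @param class_y class seed (ignored when `condition` given).
#' @param condition optional [crp_condition()].
#' @param composite a [crp_composite()].
#' @param sfreq sampling rate used to label the frequency axis.
#' @return `freq_relevance`: array `[n, n_channels, n_bins]` with
#'   attributes `freqs` (Hz), `domain` (`"frequency"`), `total`
#'   (per-sample sums) and `time_total` (per-sample time-domain sums).
#' @export
relevance_in_frequency <- function(model, x, class_y = NULL,
                                   condition = NULL,
                                   composite = crp_composite(),
                                   sfreq = NULL) {
  if (inherits(x, "epoch_set")) { if (is.null(sfreq)) sfreq <- x$sfreq
    x <- x$data }
  if (is.null(sfreq)) sfreq <- 128
  if (is.null(model$vil)) model <- attach_vil(model)
  if (!is.null(condition)) class_y <- condition$class_y
  if (is.null(class_y)) stop("class_y or condition required")
  Rt <- lrp(model, x, class_y, composite, condition)
  n <- dim(x)[1]; C <- dim(x)[2]; Tn <- dim(x)[3]
  nb <- model$vil$n_bins
  # z-rule through the synthesis matrix: Rz = z * (B^T (Rt / x))
  Xm <- aperm(x, c(3, 2, 1)); dim(Xm) <- c(Tn, C * n)
  Rm <- aperm(unclass(Rt), c(3, 2, 1)); dim(Rm) <- c(Tn, C * n)
  G <- Rm / Xm
  G[Xm == 0] <- 0
  BtG <- crossprod(model$vil$basis, G)             # [2*nb, C*n]
  z <- rfft_epochs(x)
  rem <- aperm(z$re, c(3, 2, 1)); dim(rem) <- c(nb, C * n)
  imm <- aperm(z$im, c(3, 2, 1)); dim(imm) <- c(nb, C * n)
  Rz <- rbind(rem, imm) * BtG
  Rbin <- Rz[seq_len(nb), , drop = FALSE] +
    Rz[nb + seq_len(nb), , drop = FALSE]
  dim(Rbin) <- c(nb, C, n)
  out <- aperm(Rbin, c(3, 2, 1))                   # [n, C, nb]
  structure(out, class = "freq_relevance", domain = "frequency",
            freqs = (0:(nb - 1L)) * sfreq / Tn,
            total = apply(out, 1, sum),
            time_total = attr(Rt, "total"))
}

#' Aggregate frequency relevance into bands
#'
#' Sums per-bin relevance into the named frequency bands. With
#' `positive_only` (the display convention for topographic relevance
#' maps), negative bin relevances are dropped before summing. Bins above
#' the band union are assigned to no band; their mass is reported in the
#' `out_of_band` attribute.
#'
#' @param fr `freq_relevance` (`[n, C, n_bins]`) or a `[C, n_bins]`
#'   matrix with a `freqs` attribute.
#' @param bands a [band_scheme()].
#' @param positive_only drop negative relevance before summing.
#' @return array `[n, C, n_bands]` (or `[C, n_bands]` for matrix input)
#'   with band names; attribute `out_of_band` holds the mass of
#'   unassigned bins.
#' @export
band_aggregate <- function(fr, bands = band_scheme(),
                           positive_only = TRUE) {
  freqs <- attr(fr, "freqs")
  if (is.null(freqs)) stop("input lacks a freqs attribute")
  x <- unclass(fr)
  two_d <- length(dim(x)) == 2
  if (two_d) dim(x) <- c(1L, dim(x))
  if (positive_only) x <- pos(x)
  nbnd <- length(bands)
  out <- array(0, c(dim(x)[1], dim(x)[2], nbnd),
               dimnames = list(NULL, NULL, names(bands)))
  assigned <- rep(FALSE, length(freqs))
  for (b in seq_len(nbnd)) {
    sel <- freqs >= bands[[b]][1] & freqs < bands[[b]][2]
    assigned <- assigned | sel
    if (any(sel))
      out[, , b] <- apply(x[, , sel, drop = FALSE], c(1, 2), sum)
  }
  oob <- if (any(!assigned))
    sum(x[, , !assigned, drop = FALSE]) else 0
  if (two_d) out <- out[1, , , drop = TRUE]
  structure(out, out_of_band = oob)
}
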