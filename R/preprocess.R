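#' Continuous EEG container
#'
#' Minimal holder for continuous (non-epoched) multichannel EEG used by the
#' filtering/resampling front end.
#'
#' @param data numeric matrix `[n_channels, n_times]`, microvolt.
#' @param sfreq sampling frequency, Hz.
#' @param channels channel names.
#' @return object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(data, sfreq, channels = NULL) {
  stopifnot(is.matrix(data), is.numeric(sfreq), sfreq > 0)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(channels) == nrow(data))
  structure(list(data = data, sfreq = sfreq,
                 channels = as.character(channels)),
            class = "continuous_eeg")
}

#' Preprocessing configuration
#'
#' The standard chain: mains notch, 1-60 Hz band-pass, resampling to
#' 128 Hz, 3-s non-overlapping windows, common average reference and
#' per-channel standardization in acquisition-stream batches of 128
#' windows (mimicking an online system).
#'
#' @param notch_hz mains frequency to suppress (Hz).
#' @param band band-pass edges `c(lo, hi)` in Hz.
#' @param resample_hz target sampling rate (Hz); `band[2]` must stay below
#'   its Nyquist frequency.
#' @param window_s epoch window length (s); `window_s * resample_hz` must
#'   be an integer.
#' @param batch_size standardization batch size (windows).
#' @return object of class `preproc_config`.
#' @export
preproc_config <- function(notch_hz = 50, band = c(1, 60),
                           resample_hz = 128, window_s = 3,
                           batch_size = 128) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[2] >= resample_hz / 2)
    stop("band upper edge must be below the post-resampling Nyquist ",
         "frequency (", resample_hz / 2, " Hz)")
  if (abs(window_s * resample_hz - round(window_s * resample_hz)) > 1e-9)
    stop("window_s * resample_hz must be an integer")
  structure(list(notch_hz = notch_hz, band = band,
                 resample_hz = resample_hz, window_s = window_s,
                 batch_size = as.integer(batch_size)),
            class = "preproc_config")
}

#' Notch + band-pass filter and resample continuous EEG
#'
#' Zero-phase second-order IIR notch at the mains frequency, zero-phase
#' FIR band-pass (forward-backward overlap-add filtering), then exact
#' Fourier-domain resampling to the target rate (the signal is already
#' band-limited below the new Nyquist by the band-pass).
#'
#' @param raw a [continuous_eeg()].
#' @param cfg a [preproc_config()].
#' @return filtered [continuous_eeg()] at `cfg$resample_hz`.
#' @export
filter_and_resample <- function(raw, cfg) {
  stopifnot(inherits(raw, "continuous_eeg"), inherits(cfg, "preproc_config"))
  fs <- raw$sfreq
  if (fs <= 2 * cfg$band[2])
    stop("input sampling rate must exceed twice the band-pass upper edge")
  nyq <- fs / 2
  bstop <- signal::butter(2, c(cfg$notch_hz - 2, cfg$notch_hz + 2) / nyq,
                          type = "stop")
  # FIR band-pass; tap count driven by the low transition edge
  ntaps <- min(2000L, as.integer(2 * round(1.65 * fs / cfg$band[1])))
  bpass <- signal::fir1(ntaps, cfg$band / nyq, type = "pass")
  x <- raw$data
  out <- matrix(0, nrow(x), ncol(x))
  for (c in seq_len(nrow(x))) {
    y <- signal::filtfilt(bstop, x[c, ])
    y <- signal::fftfilt(bpass, y)          # forward
    y <- rev(signal::fftfilt(bpass, rev(y)))  # backward (zero phase)
    out[c, ] <- y
  }
  if (cfg$resample_hz != fs) {
    frac <- .rat(cfg$resample_hz / fs)
    out <- t(apply(out, 1, resample_fft, p = frac$p, q = frac$q))
  }
  continuous_eeg(out, cfg$resample_hz, raw$channels)
}

# small rational approximation p/q of a rate ratio
.rat <- function(r, tol = 1e-9) {
  for (q in 1:10000) {
    p <- r * q
    if (abs(p - round(p)) < tol * q) return(list(p = as.integer(round(p)),
                                                 q = q))
  }
  stop("cannot express resampling ratio as a small rational")
}

# Fourier-domain resampling by rational factor p/q (input trimmed to a
# multiple of q); amplitude-exact for signals band-limited below the
# output Nyquist frequency.
resample_fft <- function(x, p, q) {
  T1 <- (length(x) %/% q) * q
  x <- x[seq_len(T1)]
  T2 <- T1 %/% q * p
  X <- fft(x)
  Y <- complex(length.out = T2)
  nb <- min(T1, T2) %/% 2
  Y[1] <- X[1]
  Y[2:nb] <- X[2:nb]
  Y[T2 - (2:nb) + 2] <- Conj(X[2:nb])
  if (T2 %% 2 == 0) Y[nb + 1] <- Re(X[nb + 1])
  Re(fft(Y, inverse = TRUE)) / T1
}

#' Cut continuous EEG into non-overlapping windows
#'
#' Left-aligned, half-open, non-overlapping windows of `cfg$window_s`
#' seconds; a trailing partial window is dropped.
#'
#' @param cont a [continuous_eeg()] (already at the target rate).
#' @param cfg a [preproc_config()].
#' @param label class label assigned to every window (0/1).
#' @param subject subject id assigned to every window.
#' @return [epoch_set()]
#' @export
window_epochs <- function(cont, cfg, label = 0L, subject = "S01") {
  stopifnot(inherits(cont, "continuous_eeg"))
  wlen <- as.integer(round(cfg$window_s * cont$sfreq))
  n_win <- ncol(cont$data) %/% wlen
  if (n_win < 1) stop("signal shorter than one window")
  d <- array(0, dim = c(n_win, nrow(cont$data), wlen))
  for (w in seq_len(n_win))
    d[w, , ] <- cont$data[, ((w - 1L) * wlen + 1L):(w * wlen)]
  epoch_set(d, rep(as.integer(label), n_win), rep(subject, n_win),
            cont$channels, cont$sfreq)
}

#' Common average reference
#'
#' Subtracts, at every time point, the instantaneous mean across channels.
#' Idempotent; requires at least two channels.
#'
#' @param epochs [epoch_set()] (or [continuous_eeg()]).
#' @return same class as the input, re-referenced.
#' @export
common_average_reference <- function(epochs) {
  if (inherits(epochs, "continuous_eeg")) {
    if (nrow(epochs$data) < 2) stop("need at least 2 channels")
    epochs$data <- sweep(epochs$data, 2, colMeans(epochs$data))
    return(epochs)
  }
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_channels(epochs) < 2) stop("need at least 2 channels")
  d <- epochs$data
  m <- apply(d, c(1, 3), mean)              # [n_epochs, n_times]
  for (c in seq_len(dim(d)[2])) d[, c, ] <- d[, c, ] - m
  epochs$data <- d
  epochs
}

#' Per-channel standardization in acquisition-stream batches
#'
#' Splits the epoch stream into consecutive batches of `batch_size` epochs
#' and, within each batch, centres and scales every channel to mean 0 /
#' standard deviation 1 over the batch's pooled time points. The trailing
#' partial batch is standardized on its own statistics. Zero-variance
#' channels are guarded by a small variance floor.
#'
#' @param epochs [epoch_set()] in acquisition-stream order.
#' @param batch_size batch length in epochs.
#' @return standardized [epoch_set()] (unitless after this step).
#' @export
batch_standardize <- function(epochs, batch_size = 128L) {
  stopifnot(inherits(epochs, "epoch_set"), batch_size >= 1)
  d <- epochs$data
  n <- dim(d)[1]
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    blk <- d[idx, , , drop = FALSE]
    for (c in seq_len(dim(d)[2])) {
      v <- blk[, c, ]
      mu <- mean(v)
      sdv <- sqrt(max(mean((v - mu)^2), 1e-12))
      d[idx, c, ] <- (v - mu) / sdv
    }
  }
  epochs$data <- d
  epochs
}
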