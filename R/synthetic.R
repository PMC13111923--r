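#' Configuration for a synthetic multi-subject EEG cohort
#'
#' Describes a binary-class cohort with planted spatial/spectral class
#' signatures on top of 1/f background noise and stereotyped artifact
#' sources (eye blinks, mains hum, muscle bursts). Per-subject variability
#' is modelled as a multiplicative amplitude jitter and an additive
#' centre-frequency jitter, drawn once per subject, so that
#' subject-independent training sees realistic between-subject variance.
#'
#' @param n_subjects number of subjects.
#' @param n_epochs_per_class epochs per class per subject.
#' @param montage character vector of 10-20 channel names (see
#'   [standard_montage()]).
#' @param sfreq sampling frequency, Hz.
#' @param epoch_len epoch length, seconds (`sfreq * epoch_len` must be an
#'   integer number of samples).
#' @param signal_spec list of planted class signatures; each entry is a list
#'   with fields `class` (0/1), `center` (Hz), `bandwidth` (Hz; the epoch's
#'   oscillation frequency is drawn uniformly from the band), `channels`
#'   (target channel names), `amplitude` (microvolt) and optionally
#'   `envelope` (`"constant"` or `"gauss_burst"` for a Gaussian-windowed
#'   burst centred mid-epoch) and `prob` (probability that an epoch of
#'   the class expresses the signature; default 1 — below 1 the class is
#'   a mixture of alternative signatures, useful for planting several
#'   concepts per class) and `phase` (fixed carrier phase in radians;
#'   default is a random phase per epoch — a fixed phase emulates a
#'   time-locked component whose activation maps are coherent across
#'   epochs).
#' @param noise_spec list with `exponent` (pink-noise spectral exponent,
#'   power ~ 1/f^exponent), `amplitude` (per-channel standard deviation,
#'   microvolt), optionally `band` (Hz limits of the background,
#'   default `c(1, 60)`: the generator emulates windows after the
#'   standard notch/band-pass preprocessing chain), and optionally
#'   `epoch_amp_jitter` (fraction; every
#'   epoch's noise amplitude is additionally scaled per channel by
#'   U(1-j, 1+j), emulating the non-stationarity of ongoing EEG — with
#'   it, broadband variance is an unreliable class cue and decoders must
#'   rely on band-specific power).
#' @param artifact_spec list of artifact sources; each entry has `kind`
#'   (`"blink"`, `"line_noise"` or `"muscle"`), `channels` (loading
#'   channels), `rate` (events/s, blink and muscle) or `freq` (Hz,
#'   line noise), and `amplitude` (microvolt).
#' @param subject_variability list with `amp_jitter` (fraction; amplitudes
#'   are scaled per subject by U(1-j, 1+j)) and `freq_jitter` (Hz; additive
#'   per-subject offset of signal centre frequencies).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 16,
                          n_epochs_per_class = 40,
                          montage = standard_montage()$channel,
                          sfreq = 128,
                          epoch_len = 3,
                          signal_spec = default_signal_spec(),
                          noise_spec = list(exponent = 1, amplitude = 10),
                          artifact_spec = default_artifact_spec(),
                          subject_variability = list(amp_jitter = 0.2,
                                                     freq_jitter = 1),
                          seed = 1L) {
  n_times <- sfreq * epoch_len
  if (abs(n_times - round(n_times)) > 1e-9)
    stop("sfreq * epoch_len must be an integer number of samples")
  if (anyDuplicated(montage)) stop("montage channels must be unique")
  for (s in signal_spec) {
    miss <- setdiff(s$channels, montage)
    if (length(miss))
      stop("signal_spec channel(s) not in montage: ",
           paste(miss, collapse = ", "))
    if (s$amplitude < 0) stop("amplitudes must be >= 0")
    if (!s$class %in% c(0, 1)) stop("signal_spec class must be 0/1")
  }
  for (a in artifact_spec) {
    miss <- setdiff(a$channels, montage)
    if (length(miss))
      stop("artifact_spec channel(s) not in montage: ",
           paste(miss, collapse = ", "))
    if (a$amplitude < 0) stop("amplitudes must be >= 0")
    if (!a$kind %in% c("blink", "line_noise", "muscle"))
      stop("unknown artifact kind: ", a$kind)
  }
  if (noise_spec$amplitude < 0) stop("amplitudes must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_epochs_per_class = as.integer(n_epochs_per_class),
                 montage = montage, sfreq = sfreq, epoch_len = epoch_len,
                 n_times = as.integer(round(n_times)),
                 signal_spec = signal_spec, noise_spec = noise_spec,
                 artifact_spec = artifact_spec,
                 subject_variability = subject_variability,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_signal_spec <- function() {
  list(
    list(class = 0, center = 10, bandwidth = 2,
         channels = c("T7", "FC5", "CP5"), amplitude = 4,
         envelope = "constant"),
    list(class = 1, center = 10, bandwidth = 2,
         channels = c("T8", "FC6", "CP6"), amplitude = 4,
         envelope = "constant")
  )
}

#' @rdname cohort_config
#' @export
default_artifact_spec <- function() {
  list(
    list(kind = "blink", channels = c("Fp1", "Fp2", "AF3", "AF4"),
         rate = 0.3, amplitude = 40),
    list(kind = "line_noise", channels = standard_montage()$channel,
         freq = 50, amplitude = 2)
  )
}

# biphasic blink template over `len` samples (~400 ms)
blink_template <- function(len) {
  u <- seq(0, 1, length.out = len)
  exp(-(u - 0.35)^2 / (2 * 0.012)) - 0.45 * exp(-(u - 0.62)^2 / (2 * 0.02))
}

# one epoch of 1/f^exponent noise with unit standard deviation,
# band-limited to `band` (Hz) as after the standard band-pass chain
pink_epoch <- function(n_times, exponent, sfreq = 128, band = c(1, 60)) {
  nb <- n_times %/% 2
  # random phases/amplitudes in the frequency domain, shaped by f^(-exp/2)
  re <- rnorm(nb); im <- rnorm(nb)
  f <- seq_len(nb)
  fhz <- f * sfreq / n_times
  shape <- f^(-exponent / 2)
  shape[fhz < band[1] | fhz > band[2]] <- 0
  spec <- complex(real = re * shape, imaginary = im * shape)
  full <- c(0, spec, rev(Conj(spec[seq_len(nb - 1)])))
  x <- Re(fft(full, inverse = TRUE)) / n_times
  s <- sd(x)
  if (s > 0) x / s else x
}

#' Generate a synthetic EEG cohort
#'
#' Builds the cohort described by a [cohort_config()]: per-epoch pink-noise
#' background plus linearly mixed planted class signals and artifact
#' sources. The generated data are a deterministic function of the config
#' (including its seed). The full source decomposition (per-source loading
#' vectors and time courses) is retrievable with [ground_truth()].
#'
#' @param config a `cohort_config`.
#' @return an [epoch_set()] carrying the ground-truth mixing as an
#'   attribute; epochs are ordered by subject, class order shuffled within
#'   subject (acquisition-stream order).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  C <- length(config$montage)
  Tn <- config$n_times
  n_per <- 2L * config$n_epochs_per_class
  n_tot <- config$n_subjects * n_per
  tt <- seq_len(Tn) / config$sfreq

  sv <- config$subject_variability
  amp_mult <- runif(config$n_subjects, 1 - sv$amp_jitter, 1 + sv$amp_jitter)
  amp_mult <- pmax(amp_mult, 0)
  freq_off <- runif(config$n_subjects, -sv$freq_jitter, sv$freq_jitter)

  labels <- integer(n_tot)
  subjects <- character(n_tot)
  data <- array(0, dim = c(n_tot, C, Tn))

  sources <- list()
  for (i in seq_along(config$signal_spec)) {
    s <- config$signal_spec[[i]]
    load <- setNames(numeric(C), config$montage)
    load[s$channels] <- 1
    sources[[paste0("signal_", i)]] <-
      list(name = paste0("signal_", i), kind = "signal", class = s$class,
           loading = load, time_course = matrix(0, n_tot, Tn))
  }
  for (i in seq_along(config$artifact_spec)) {
    a <- config$artifact_spec[[i]]
    k <- length(a$channels)
    w <- if (k > 1) 1 - 0.4 * (seq_len(k) - 1) / (k - 1) else 1
    load <- setNames(numeric(C), config$montage)
    load[a$channels] <- w
    sources[[paste0(a$kind, "_", i)]] <-
      list(name = paste0(a$kind, "_", i), kind = a$kind, class = NA,
           loading = load, time_course = matrix(0, n_tot, Tn))
  }

  blink_len <- max(4L, round(0.4 * config$sfreq))
  blink_shape <- blink_template(blink_len)

  ep <- 0L
  for (su in seq_len(config$n_subjects)) {
    lab <- rep(c(0L, 1L), each = config$n_epochs_per_class)
    lab <- lab[sample.int(n_per)]
    for (j in seq_len(n_per)) {
      ep <- ep + 1L
      labels[ep] <- lab[j]
      subjects[ep] <- sprintf("S%02d", su)
      x <- matrix(0, C, Tn)
      # 1/f background
      if (config$noise_spec$amplitude > 0) {
        ej <- config$noise_spec$epoch_amp_jitter
        if (is.null(ej)) ej <- 0
        nband <- config$noise_spec$band
        if (is.null(nband)) nband <- c(1, 60)
        for (c in seq_len(C))
          x[c, ] <- config$noise_spec$amplitude *
            runif(1, 1 - ej, 1 + ej) *
            pink_epoch(Tn, config$noise_spec$exponent, config$sfreq,
                       nband)
      } else {
        # keep the RNG stream aligned across noise settings
        for (c in seq_len(C)) invisible(rnorm(2 * (Tn %/% 2)))
      }
      # planted class signals
      for (i in seq_along(config$signal_spec)) {
        s <- config$signal_spec[[i]]
        f <- s$center + freq_off[su] + runif(1, -s$bandwidth / 2,
                                             s$bandwidth / 2)
        phi <- runif(1, 0, 2 * pi)
        if (!is.null(s$phase)) phi <- s$phase
        u <- runif(1)
        p_expr <- if (is.null(s$prob)) 1 else s$prob
        if (s$class != lab[j] || u > p_expr) next
        env <- switch(if (is.null(s$envelope)) "constant" else s$envelope,
                      constant = rep(1, Tn),
                      gauss_burst = {
                        ctr <- if (is.null(s$burst_center))
                          config$epoch_len / 2 else s$burst_center
                        exp(-(tt - ctr)^2 /
                              (2 * (config$epoch_len / 8)^2))
                      },
                      stop("unknown envelope"))
        tc <- s$amplitude * amp_mult[su] * env * sin(2 * pi * f * tt + phi)
        src <- sources[[paste0("signal_", i)]]
        src$time_course[ep, ] <- tc
        sources[[paste0("signal_", i)]] <- src
        x <- x + outer(src$loading, tc)
      }
      # artifact sources
      for (i in seq_along(config$artifact_spec)) {
        a <- config$artifact_spec[[i]]
        key <- paste0(a$kind, "_", i)
        tc <- numeric(Tn)
        if (a$kind == "blink") {
          n_ev <- rpois(1, a$rate * config$epoch_len)
          if (n_ev > 0) {
            onsets <- sort(sample.int(max(1L, Tn - blink_len), n_ev,
                                      replace = TRUE))
            for (o in onsets) {
              idx <- o:(o + blink_len - 1L)
              tc[idx] <- tc[idx] + blink_shape
            }
          }
          tc <- a$amplitude * amp_mult[su] * tc
        } else if (a$kind == "line_noise") {
          phi <- runif(1, 0, 2 * pi)
          tc <- a$amplitude * sin(2 * pi * a$freq * tt + phi)
        } else if (a$kind == "muscle") {
          n_ev <- rpois(1, a$rate * config$epoch_len)
          hf <- c(0, diff(rnorm(Tn)))
          hf <- hf / max(sd(hf), 1e-12)
          env <- numeric(Tn)
          if (n_ev > 0) {
            cen <- runif(n_ev, 0, config$epoch_len)
            for (m in cen)
              env <- env + exp(-(tt - m)^2 / (2 * 0.05^2))
          }
          tc <- a$amplitude * amp_mult[su] * hf * env
        }
        src <- sources[[key]]
        src$time_course[ep, ] <- tc
        sources[[key]] <- src
        x <- x + outer(src$loading, tc)
      }
      data[ep, , ] <- x
    }
  }

  out <- epoch_set(data, labels, subjects, config$montage, config$sfreq)
  attr(out, "ground_truth") <- list(sources = sources, config = config)
  attr(out, "config") <- config
  out
}

#' Ground-truth source decomposition of a synthetic cohort
#'
#' Returns the planted sources (per-source spatial loading vector and
#' per-epoch time courses) so that downstream relevance analyses can be
#' validated against known mixing: the generated data equal the pink-noise
#' background plus `sum_s loading_s %o% time_course_s`.
#'
#' @param x either an epoch set produced by [generate_cohort()] or a
#'   `cohort_config` (in which case the cohort is regenerated).
#' @return list with elements `sources` (list of `name`, `kind`, `class`,
#'   `loading`, `time_course`) and `config`.
#' @export
ground_truth <- function(x) {
  if (inherits(x, "cohort_config")) x <- generate_cohort(x)
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) stop("no ground truth attached; cohort not generated ",
                        "by generate_cohort()")
  gt
}
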