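# Cluster-level neuroscientific views: PSD + relevance curves, per-band
# topographic map data, and functional grouping of scalp regions.

# mean one-sided periodogram of a set of epochs: [C, n_bins]
mean_periodogram <- function(epochs, sample_ids = NULL) {
  x <- epochs$data
  if (!is.null(sample_ids)) x <- x[sample_ids, , , drop = FALSE]
  z <- rfft_epochs(x)
  Tn <- n_times(epochs)
  p <- (z$re^2 + z$im^2) / (Tn * epochs$sfreq)
  nb <- dim(p)[3]
  w <- rep(2, nb); w[1] <- 1
  if (Tn %% 2 == 0) w[nb] <- 1
  psd <- apply(p, c(2, 3), mean)
  sweep(psd, 2, w, "*")
}

# pool the selected samples and mean frequency relevance of a cluster
cluster_pool <- function(concepts, labels = NULL, cluster_id = NULL) {
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(concepts))
    concepts <- concepts[labels == cluster_id]
  }
  if (length(concepts) == 0) stop("empty cluster")
  sample_ids <- sort(unique(unlist(lapply(concepts,
                                          function(cp) cp$sample_ids))))
  fr <- Reduce(`+`, lapply(concepts, function(cp) cp$mean_freq_rel)) /
    length(concepts)
  list(concepts = concepts, sample_ids = sample_ids, freq_rel = fr,
       freqs = concepts[[1]]$freqs)
}

#' PSD and relevance-percentage curves for a cluster
#'
#' Mean channel-averaged power spectral density of the cluster's
#' representative samples (mean periodogram on the epoch's native DFT
#' grid) together with the per-bin relevance expressed as a percentage of
#' the total positive relevance.
#'
#' @param concepts concepts of one cluster (list), e.g. filtered by
#'   cluster label.
#' @param epochs the cohort [epoch_set()] the concepts' sample ids refer
#'   to.
#' @param fmax upper display frequency (Hz, default 45); the relevance
#'   percentage above `fmax` is reported as `remainder_pct`.
#' @return list with `freqs`, `psd` (channel-averaged), `relevance_pct`
#'   (per bin, sums to 100 with the remainder), `remainder_pct`.
#' @export
psd_relevance_curves <- function(concepts, epochs, fmax = 45) {
  pool <- cluster_pool(concepts)
  psd <- colMeans(mean_periodogram(epochs, pool$sample_ids))
  relpos <- colSums(pos(pool$freq_rel))            # per bin over channels
  total <- sum(relpos)
  pct <- if (total > 0) 100 * relpos / total else relpos
  sel <- pool$freqs <= fmax
  list(freqs = pool$freqs[sel], psd = psd[sel],
       relevance_pct = pct[sel],
       remainder_pct = sum(pct[!sel]))
}

#' Per-band topographic map data for a cluster
#'
#' For each frequency band: channel band power scaled by the band's
#' cross-channel average power (compensating the 1/f spectral decay so
#' bands are comparable), and the positive-only channel band relevance,
#' which is deliberately left unscaled. Channel 2-D positions come from
#' the standard projected montage.
#'
#' @param concepts concepts of one cluster.
#' @param epochs cohort [epoch_set()].
#' @param bands a [band_scheme()].
#' @return object of class `band_topo`: list with `power` and `relevance`
#'   (matrices `[n_channels, n_bands]`), `positions` `[n_channels, 2]`,
#'   `channels`, `bands`.
#' @export
band_topo <- function(concepts, epochs, bands = band_scheme()) {
  pool <- cluster_pool(concepts)
  psd <- mean_periodogram(epochs, pool$sample_ids)  # [C, nb]
  freqs <- pool$freqs
  C <- n_channels(epochs)
  nbnd <- length(bands)
  pow <- matrix(0, C, nbnd, dimnames = list(epochs$channels, names(bands)))
  for (b in seq_len(nbnd)) {
    sel <- freqs >= bands[[b]][1] & freqs < bands[[b]][2]
    if (any(sel)) pow[, b] <- rowSums(psd[, sel, drop = FALSE])
  }
  avg <- colMeans(pow)
  pow_scaled <- sweep(pow, 2, ifelse(avg > 0, avg, 1), "/")
  fr <- structure(pool$freq_rel, freqs = freqs)
  rel <- band_aggregate(fr, bands, positive_only = TRUE)
  dimnames(rel) <- dimnames(pow)
  structure(list(power = pow_scaled, relevance = rel,
                 positions = channel_positions(epochs$channels),
                 channels = epochs$channels, bands = bands),
            class = "band_topo")
}

#' Functional grouping of relevance by scalp region and band
#'
#' Averages the cluster's band relevance over anatomically motivated
#' channel groups. Negative relevance is discarded (clipped to zero, with
#' zeros kept in the mean's denominator) so the view reflects positive
#' evidence only; `use_abs` switches to averaging absolute relevance
#' instead.
#'
#' @param concepts concepts of one cluster.
#' @param regions named list of channel groups (see [default_regions()]).
#' @param bands a [band_scheme()].
#' @param channels channel names of the relevance rows.
#' @param use_abs average `|relevance|` instead of clipped relevance.
#' @return matrix `[n_regions, n_bands]` of mean relevance per region and
#'   band.
#' @export
functional_grouping <- function(concepts, regions, bands = band_scheme(),
                                channels, use_abs = FALSE) {
  validate_regions(regions, channels)
  pool <- cluster_pool(concepts)
  fr <- pool$freq_rel                               # [C, nb] signed
  freqs <- pool$freqs
  fr <- if (use_abs) abs(fr) else pos(fr)
  out <- matrix(0, length(regions), length(bands),
                dimnames = list(names(regions), names(bands)))
  for (r in seq_along(regions)) {
    rows <- match(regions[[r]], channels)
    for (b in seq_along(bands)) {
      sel <- freqs >= bands[[b]][1] & freqs < bands[[b]][2]
      out[r, b] <- mean(fr[rows, sel, drop = FALSE])
    }
  }
  out
}
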