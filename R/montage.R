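#' Standard 10-20 montage with 2-D scalp positions
#'
#' Returns the package's default 32-channel montage: standard 10-20/10-10
#' electrode names together with approximate 2-D positions from the usual
#' polar projection of the scalp (x grows to the right, y to the front,
#' head radius 1). The positions are what topographic-map views need; they
#' are not a biophysical forward model.
#'
#' @param channels optional character vector restricting (and ordering) the
#'   returned montage to a subset of the known channel names.
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
standard_montage <- function(channels = NULL) {
  pos <- matrix(c(
    -0.31,  0.95,   0.31,  0.95,                     # Fp1 Fp2
    -0.35,  0.80,   0.35,  0.80,                     # AF3 AF4
    -0.81,  0.59,  -0.42,  0.54,  0.00,  0.50,       # F7 F3 Fz
     0.42,  0.54,   0.81,  0.59,                     # F4 F8
    -0.71,  0.30,  -0.22,  0.27,   0.22,  0.27,  0.71, 0.30,  # FC5 FC1 FC2 FC6
    -1.00,  0.00,  -0.50,  0.00,   0.00,  0.00,      # T7 C3 Cz
     0.50,  0.00,   1.00,  0.00,                     # C4 T8
    -0.71, -0.30,  -0.22, -0.27,   0.22, -0.27,  0.71, -0.30, # CP5 CP1 CP2 CP6
    -0.81, -0.59,  -0.42, -0.54,   0.00, -0.50,      # P7 P3 Pz
     0.42, -0.54,   0.81, -0.59,                     # P4 P8
    -0.35, -0.80,   0.35, -0.80,                     # PO3 PO4
    -0.31, -0.95,   0.00, -1.00,   0.31, -0.95       # O1 Oz O2
  ), ncol = 2, byrow = TRUE)
  nm <- c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
          "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
          "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
          "PO3", "PO4", "O1", "Oz", "O2")
  out <- data.frame(channel = nm, x = pos[, 1], y = pos[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(channels)) {
    miss <- setdiff(channels, nm)
    if (length(miss))
      stop("unknown channel position(s): ", paste(miss, collapse = ", "))
    out <- out[match(channels, out$channel), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Channel positions for a set of channels
#'
#' @param channels character vector of 10-20 channel names.
#' @return matrix [n_channels, 2] of (x, y) positions, rownames = channels.
#' @export
channel_positions <- function(channels) {
  m <- standard_montage(channels)
  out <- as.matrix(m[, c("x", "y")])
  rownames(out) <- m$channel
  out
}

#' Functional region map over a montage
#'
#' Groups channels into left/right frontal, temporal and occipital regions
#' of interest. The temporal groups follow the convention of including the
#' fronto-central and centro-parietal lateral sites (FC5/C5/CP5 and their
#' right homologues) next to T7/T8; region definitions are intersected with
#' the montage at hand, so montages lacking e.g. C5/C6 still work.
#'
#' @param channels montage channel names the regions must be drawn from.
#' @return named list of character vectors (disjoint, all present in
#'   `channels`).
#' @export
default_regions <- function(channels) {
  full <- list(
    frontal_left   = c("Fp1", "AF3", "F7", "F3"),
    frontal_right  = c("Fp2", "AF4", "F8", "F4"),
    temporal_left  = c("FC5", "C5", "CP5", "T7"),
    temporal_right = c("FC6", "C6", "CP6", "T8"),
    occipital_left  = c("PO3", "O1"),
    occipital_right = c("PO4", "O2")
  )
  out <- lapply(full, intersect, y = channels)
  empty <- names(out)[vapply(out, length, 1L) == 0L]
  if (length(empty))
    stop("region(s) with no channel in montage: ",
         paste(empty, collapse = ", "))
  out
}

validate_regions <- function(regions, channels) {
  stopifnot(is.list(regions), length(regions) > 0, !is.null(names(regions)))
  all_ch <- unlist(regions)
  miss <- setdiff(all_ch, channels)
  if (length(miss))
    stop("region channel(s) not in montage: ", paste(miss, collapse = ", "))
  if (anyDuplicated(all_ch))
    stop("regions must be disjoint")
  if (any(vapply(regions, length, 1L) == 0L))
    stop("empty region")
  invisible(regions)
}
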