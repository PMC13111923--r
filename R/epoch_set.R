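#' Epoched EEG container
#'
#' Bundles an epoched EEG tensor with its labels, subject ids, channel
#' names and sampling rate. This is the canonical exchange object of the
#' package: the synthetic generator produces it, the preprocessing chain
#' transforms it, and the network trains on it.
#'
#' @param data numeric array `[n_epochs, n_channels, n_times]`, in microvolt.
#' @param labels integer vector of class labels in `{0, 1}`.
#' @param subjects vector of subject identifiers, one per epoch.
#' @param channels character vector of unique channel names.
#' @param sfreq sampling frequency in Hz.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, subjects, channels, sfreq) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n <- dim(data)[1]
  if (length(labels) != n || length(subjects) != n)
    stop("labels/subjects length must match n_epochs")
  if (length(channels) != dim(data)[2])
    stop("channels length must match dim(data)[2]")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!all(is.finite(data))) stop("non-finite values in data")
  stopifnot(is.numeric(sfreq), length(sfreq) == 1, sfreq > 0)
  structure(list(data = data, labels = as.integer(labels),
                 subjects = subjects, channels = as.character(channels),
                 sfreq = sfreq),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat(sprintf("  subjects: %s\n",
              paste(unique(x$subjects), collapse = ", ")))
  cat(sprintf("  class balance: %s\n",
              paste(sprintf("%d:%d", 0:1, tabulate(x$labels + 1L, 2L)),
                    collapse = " ")))
  invisible(x)
}

#' Subset an epoch set by epoch index
#'
#' @param x epoch_set
#' @param i epoch indices (logical or integer)
#' @param ... unused
#' @export
subset_epochs <- function(x, i, ...) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$data[i, , , drop = FALSE], x$labels[i], x$subjects[i],
            x$channels, x$sfreq)
}

#' Epoch-set geometry accessors
#' @param x epoch_set
#' @return integer count.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' @rdname n_epochs
#' @export
n_channels <- function(x) dim(x$data)[2]

#' @rdname n_epochs
#' @export
n_times <- function(x) dim(x$data)[3]

#' Write an epoch set to the canonical HDF5 layout
#'
#' Layout: datasets `/data` (n_epochs x n_channels x n_times), `/labels`,
#' `/subjects`, `/channels` and `/sfreq`.
#'
#' @param x epoch_set
#' @param path output file path (overwritten if it exists)
#' @return `path`, invisibly.
#' @export
write_epochs_h5 <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(x$data, path, "data")
  rhdf5::h5write(x$labels, path, "labels")
  rhdf5::h5write(as.character(x$subjects), path, "subjects")
  rhdf5::h5write(x$channels, path, "channels")
  rhdf5::h5write(x$sfreq, path, "sfreq")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an epoch set from the canonical HDF5 layout
#'
#' @param path HDF5 file written by [write_epochs_h5()].
#' @return epoch_set
#' @export
read_epochs_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  epoch_set(rhdf5::h5read(path, "data"),
            as.integer(rhdf5::h5read(path, "labels")),
            as.vector(rhdf5::h5read(path, "subjects")),
            as.vector(rhdf5::h5read(path, "channels")),
            as.numeric(rhdf5::h5read(path, "sfreq")))
}
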