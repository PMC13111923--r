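#' Infomax ICA decomposition of cluster data
#'
#' Decomposes concatenated time-domain EEG into independent components:
#' channels are first scaled to unit variance, whitened by PCA (retaining
#' the numerically non-degenerate subspace — common-average-referenced
#' data lose one dimension), and rotated by extended infomax ICA. Sources
#' are normalized to unit variance; the stored unmixing/mixing matrices
#' reproduce them from (and project them back to) channel space.
#'
#' @param X matrix `[n_channels, n_times]` (e.g. the horizontally
#'   concatenated representative samples of a cluster), or an
#'   [epoch_set()] whose epochs are concatenated.
#' @param sample_ids optional epoch subset when `X` is an epoch set.
#' @param n_comp maximum number of components (default: the retained
#'   rank).
#' @param maxit infomax iterations.
#' @return object of class `eeg_ica`: `pre_scale` (per-channel 1/sd),
#'   `center`, `whitening` `[rank, C]`, `unmixing` `[rank, C]`, `mixing`
#'   `[C, rank]`, `topographies` (= mixing), `sources`
#'   `[rank, n_times]`, `channels`.
#' @export
fit_ica <- function(X, sample_ids = NULL, n_comp = NULL, maxit = 200) {
  channels <- NULL
  if (inherits(X, "epoch_set")) {
    channels <- X$channels
    d <- X$data
    if (!is.null(sample_ids)) d <- d[sample_ids, , , drop = FALSE]
    X <- matrix(aperm(d, c(2, 3, 1)), nrow = dim(d)[2])
  }
  stopifnot(is.matrix(X))
  C <- nrow(X); Tn <- ncol(X)
  if (Tn < 10 * C) stop("need n_times >> n_channels for a stable ICA")
  if (is.null(channels)) channels <- paste0("ch", seq_len(C))
  sds <- apply(X, 1, sd)
  if (any(sds <= 0)) stop("zero-variance channel")
  pre <- 1 / sds
  X1 <- X * pre
  ctr <- rowMeans(X1)
  X1 <- X1 - ctr
  cv <- tcrossprod(X1) / (Tn - 1)
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-8)
  if (!is.null(n_comp)) rank <- min(rank, n_comp)
  Wh <- diag(1 / sqrt(eg$values[seq_len(rank)]), rank) %*%
    t(eg$vectors[, seq_len(rank), drop = FALSE])   # [rank, C]
  Y <- Wh %*% X1                                   # white sources
  im <- ica::icaimax(t(Y), nc = rank, center = FALSE, maxit = maxit,
                     fun = "ext")
  S <- t(im$S)                                     # [rank, Tn]
  ssd <- apply(S, 1, sd)
  S <- S / ssd
  # rotation in whitened space: S = Rot %*% Y
  Rot <- S %*% t(Y) %*% solve(tcrossprod(Y))
  unmix <- Rot %*% Wh %*% diag(pre, C)             # sources from raw X
  mix <- mpinv(unmix)                              # [C, rank]
  structure(list(pre_scale = pre, center = ctr, whitening = Wh,
                 rotation = Rot, unmixing = unmix, mixing = mix,
                 topographies = mix, sources = S, channels = channels,
                 rank = rank),
            class = "eeg_ica")
}

mpinv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * tol
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Project relevance into ICA component space
#'
#' Applies the precomputed unmixing chain to a channels-by-time relevance
#' quantity and aggregates each component's share by the sum of absolute
#' projected values, yielding one non-negative scalar per component
#' (its importance for the classification).
#'
#' @param ica an `eeg_ica`.
#' @param R relevance matrix `[n_channels, n_times]`, co-shaped with the
#'   data the ICA was fitted on (or any time extent).
#' @return numeric vector of per-component relevance, with attribute
#'   `projected` (the `[rank, n_times]` projected relevance).
#' @export
project_relevance <- function(ica, R) {
  stopifnot(inherits(ica, "eeg_ica"), is.matrix(R),
            nrow(R) == length(ica$pre_scale))
  P <- ica$unmixing %*% R
  structure(rowSums(abs(P)), projected = P)
}

#' Label ICA components through a pluggable classifier
#'
#' Components are labelled by an external labeler function (signature
#' `function(ica) -> data.frame(label, confidence)`), e.g. an adapter to
#' an ICLabel-style classifier or, for synthetic data, the ground-truth
#' labeler from [ground_truth_labeler()]. Without a labeler every
#' component is `"unlabelled"` and the pipeline continues.
#'
#' @param ica an `eeg_ica`.
#' @param labeler optional labeler function.
#' @return data.frame with one row per component: `component`, `label`,
#'   `confidence`.
#' @export
label_components <- function(ica, labeler = NULL) {
  n <- ica$rank
  if (is.null(labeler))
    return(data.frame(component = seq_len(n), label = "unlabelled",
                      confidence = NA_real_))
  out <- labeler(ica)
  stopifnot(nrow(out) == n)
  cbind(data.frame(component = seq_len(n)), out)
}

#' Ground-truth component labeler for synthetic cohorts
#'
#' Builds a labeler that matches each ICA component topography against
#' the planted source loadings by absolute cosine similarity and assigns
#' the matched source's kind (`blink` -> `"eye"`, `line_noise` ->
#' `"line noise"`, `muscle` -> `"muscle"`, planted signals -> `"brain"`);
#' components below the similarity threshold are `"other"`.
#'
#' @param truth result of [ground_truth()].
#' @param threshold minimum |cosine| to accept a match (default 0.7).
#' @return labeler function for [label_components()].
#' @export
ground_truth_labeler <- function(truth, threshold = 0.7) {
  loadings <- lapply(truth$sources, function(s) s$loading)
  kinds <- vapply(truth$sources, function(s) s$kind, "")
  label_of <- c(signal = "brain", blink = "eye",
                line_noise = "line noise", muscle = "muscle")
  function(ica) {
    labs <- character(ica$rank); conf <- numeric(ica$rank)
    for (i in seq_len(ica$rank)) {
      topo <- ica$topographies[, i]
      sims <- vapply(loadings, function(L) {
        den <- sqrt(sum(L^2) * sum(topo^2))
        if (den == 0) 0 else abs(sum(L * topo)) / den
      }, 0)
      j <- which.max(sims)
      if (sims[j] >= threshold) {
        labs[i] <- label_of[[kinds[j]]]
        conf[i] <- sims[j]
      } else {
        labs[i] <- "other"
        conf[i] <- sims[j]
      }
    }
    data.frame(label = labs, confidence = conf)
  }
}

#' ICA relevance analysis of a cluster
#'
#' Convenience driver: fits ICA on the cluster's pooled representative
#' samples, projects the cluster's pooled time-domain relevance into
#' component space, labels components, and ranks them by relevance.
#'
#' @param concepts concepts of one cluster.
#' @param epochs cohort [epoch_set()].
#' @param relevance array `[n, C, T]` of time-domain relevance for the
#'   cohort (e.g. from [lrp()] under the cluster's class), from which the
#'   cluster samples are pooled.
#' @param labeler optional component labeler.
#' @param maxit infomax iterations.
#' @return data.frame ranked by component relevance, plus the `eeg_ica`
#'   as attribute `ica`.
#' @export
ica_relevance <- function(concepts, epochs, relevance, labeler = NULL,
                          maxit = 200) {
  pool <- cluster_pool(concepts)
  ids <- pool$sample_ids
  d <- epochs$data[ids, , , drop = FALSE]
  Xc <- matrix(aperm(d, c(2, 3, 1)), nrow = dim(d)[2])
  Rr <- unclass(relevance)[ids, , , drop = FALSE]
  Rc <- matrix(aperm(Rr, c(2, 3, 1)), nrow = dim(Rr)[2])
  ica <- fit_ica(Xc, maxit = maxit)
  rel <- project_relevance(ica, Rc)
  labs <- label_components(ica, labeler)
  out <- cbind(labs, relevance = as.numeric(rel))
  out <- out[order(-out$relevance), ]
  rownames(out) <- NULL
  attr(out, "ica") <- ica
  out
}
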