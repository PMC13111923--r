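#' Matrix of concept representations
#'
#' Stacks the mean activation maps of a list of concepts (optionally
#' restricted to one class) into a matrix, one row per concept.
#'
#' @param concepts list of `concept` objects.
#' @param class_y optional class filter.
#' @return list with `X` (matrix `[n_concepts, map_len]`), `model_ids`,
#'   `filters`, `classes`, `idx` (positions in the input list).
#' @export
concept_matrix <- function(concepts, class_y = NULL) {
  idx <- seq_along(concepts)
  if (!is.null(class_y))
    idx <- idx[vapply(concepts, function(cp) cp$class_y, 0L) == class_y]
  if (length(idx) == 0) stop("no concepts of the requested class")
  X <- do.call(rbind, lapply(concepts[idx], function(cp) cp$mean_map))
  list(X = X,
       model_ids = vapply(concepts[idx], function(cp) cp$model_id, ""),
       filters = vapply(concepts[idx], function(cp) cp$filter, 0L),
       classes = vapply(concepts[idx], function(cp) cp$class_y, 0L),
       idx = idx)
}

#' Embed concept representations in two dimensions
#'
#' Cosine-metric UMAP of the concepts' mean activation maps (cosine makes
#' the embedding invariant to the overall activation scale of a model).
#' Deterministic under a fixed seed (single-threaded optimization).
#'
#' @param concepts list of `concept` objects, or a numeric matrix of
#'   representations (rows = concepts).
#' @param class_y class to embed (lists only; embedding is per class).
#' @param n_neighbors,min_dist UMAP parameters (defaults 15 / 0.1);
#'   `n_neighbors` is capped at n_concepts - 1.
#' @param seed RNG seed for the embedding.
#' @return matrix `[n_concepts, 2]` of coordinates.
#' @export
embed_concepts <- function(concepts, class_y = NULL, n_neighbors = 15,
                           min_dist = 0.1, seed = 42L) {
  X <- if (is.matrix(concepts)) concepts
       else concept_matrix(concepts, class_y)$X
  if (nrow(X) < 3) stop("need at least 3 concepts to embed")
  nn <- min(n_neighbors, nrow(X) - 1L)
  set.seed(seed)
  uwot::umap(X, n_neighbors = nn, min_dist = min_dist,
             metric = "cosine", n_threads = 1, n_sgd_threads = 1,
             batch = TRUE)
}

# plain DBSCAN on a small point set (O(n^2) distances)
dbscan_labels <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  dm <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  core <- vapply(nb, length, 0L) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == -1L])
      }
    }
  }
  labels
}

#' Density-based clustering of the 2-D embedding
#'
#' DBSCAN on the embedding coordinates with the standard parameters
#' (eps 0.4, min_samples 15). For small concept sets (< 100 concepts,
#' i.e. far fewer than the 16-models-by-16-filters regime the default
#' density threshold presumes), `min_samples` is scaled down
#' proportionally, floored at 5.
#'
#' @param coords matrix `[n, 2]` of embedding coordinates.
#' @param eps DBSCAN radius.
#' @param min_samples density threshold; `NULL` = auto-scale as above.
#' @return integer cluster labels (`-1` = noise), attribute
#'   `min_samples` records the threshold used.
#' @export
cluster_embedding <- function(coords, eps = 0.4, min_samples = NULL) {
  stopifnot(is.matrix(coords), all(is.finite(coords)))
  n <- nrow(coords)
  if (is.null(min_samples))
    min_samples <- if (n >= 100) 15L else max(5L, ceiling(15 * n / 256))
  labels <- dbscan_labels(coords, eps, min_samples)
  structure(labels, min_samples = min_samples)
}

#' Per-model cluster composition
#'
#' Counts, for every model, how many of its filters fall into each
#' cluster, and reports each cluster's model coverage (fraction of models
#' contributing at least one filter). Noise-labelled concepts are
#' excluded.
#'
#' @param labels cluster labels from [cluster_embedding()].
#' @param model_ids model id per concept (same order as `labels`).
#' @return list with `composition` (matrix models x clusters of filter
#'   counts) and `coverage` (named vector per cluster).
#' @export
cluster_composition <- function(labels, model_ids) {
  stopifnot(length(labels) == length(model_ids))
  keep <- labels != -1L
  models <- sort(unique(model_ids))
  clusters <- sort(unique(labels[keep]))
  comp <- matrix(0L, length(models), length(clusters))
  dimnames(comp) <- list(models,
                         if (length(clusters))
                           paste0("cluster_", clusters) else NULL)
  for (i in which(keep))
    comp[model_ids[i], paste0("cluster_", labels[i])] <-
      comp[model_ids[i], paste0("cluster_", labels[i])] + 1L
  coverage <- colMeans(comp > 0)
  list(composition = comp, coverage = coverage)
}
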