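# Cross-model consistency of learned filter concepts: optimal cosine
# matching of filters followed by Pearson correlation of the concatenated
# mean activation maps, aggregated over model pairs and LOO repetitions.

#' Match the filters of two models
#'
#' Finds the filter bijection from model A to model B that maximizes the
#' total cosine similarity of their mean activation maps (optimal linear
#' assignment, removing the arbitrariness of filter order).
#'
#' @param A,B matrices `[n_filters, map_len]` of mean activation maps.
#' @return integer permutation `p` such that B's filter `p[i]` matches
#'   A's filter `i`.
#' @export
match_filters <- function(A, B) {
  stopifnot(is.matrix(A), is.matrix(B), nrow(A) == nrow(B),
            ncol(A) == ncol(B))
  nA <- sqrt(rowSums(A^2)); nB <- sqrt(rowSums(B^2))
  S <- tcrossprod(A, B) / outer(pmax(nA, 1e-300), pmax(nB, 1e-300))
  as.integer(clue::solve_LSAP(S + 1, maximum = TRUE))
}

#' Correlation between two matched models
#'
#' Reorders B's maps by the filter matching, flattens both models'
#' maps into 1-D vectors and returns their Pearson correlation.
#'
#' @param A,B matrices `[n_filters, map_len]`.
#' @param perm permutation from [match_filters()].
#' @return scalar correlation, `NA` (with a warning) if a flattened
#'   vector has zero variance.
#' @export
pair_correlation <- function(A, B, perm = match_filters(A, B)) {
  a <- as.vector(t(A))
  b <- as.vector(t(B[perm, , drop = FALSE]))
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance activation maps; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

# mean activation maps per (model, class): [n_filters, map_len].
# Filters with an empty concept fall back to the mean map over all
# class samples, so matching always sees the full filter bank.
model_concept_maps <- function(model, epochs, layer_id = "pointwise_conv",
                               classes = c(0L, 1L),
                               composite = crp_composite(),
                               mass_fraction = 0.2, cap = 10L) {
  model <- attach_vil(canonicalize(model))
  nf <- switch(layer_id, temporal_conv = model$dims$F1,
               spatial_conv = model$dims$M, sep_conv = model$dims$M,
               pointwise_conv = model$dims$F2)
  out <- list()
  for (cl in classes) {
    sel <- which(epochs$labels == cl)
    sub <- subset_epochs(epochs, sel)
    am_all <- forward_activations(model, sub, layer_id)
    maps <- matrix(0, nf, dim(am_all)[3])
    for (f in seq_len(nf)) {
      cond <- crp_condition(layer_id, f, cl)
      R <- crp(model, sub, cond, composite)
      ksel <- select_top_k(attr(R, "total"), mass_fraction, cap)
      rows <- if (length(ksel)) ksel else seq_len(dim(am_all)[1])
      maps[f, ] <- colMeans(matrix(am_all[rows, f, , drop = FALSE],
                                   nrow = length(rows)))
    }
    out[[paste0("class", cl)]] <- maps
  }
  out
}

#' Consistency of learned concepts across LOO models
#'
#' For every repetition of a LOO cross-validation and every unordered
#' model pair, matches filters per class and computes the flattened-map
#' correlation; pairs are averaged within a repetition, then summarized
#' per condition (mean and confidence interval over repetitions). The
#' report is emitted per class.
#'
#' @param runs_by_condition named list (conditions, e.g. `unique`,
#'   `same`); each element is a list of repetitions; each repetition a
#'   list of models' concept maps as produced by `model_concept_maps`
#'   (named per-class matrices).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return data.frame with one row per (condition, class): `mean`,
#'   `ci_half_width`, `n_reps`, plus attribute `per_rep` (list of
#'   per-repetition means).
#' @export
consistency_report <- function(runs_by_condition, conf_level = 0.95) {
  rows <- list(); per_rep_store <- list()
  for (cond in names(runs_by_condition)) {
    reps <- runs_by_condition[[cond]]
    classes <- names(reps[[1]][[1]])
    for (cl in classes) {
      rep_means <- numeric(0)
      for (rp in reps) {
        if (length(rp) < 2) {
          warning("repetition with a single model skipped")
          next
        }
        cors <- c()
        for (i in seq_len(length(rp) - 1)) for (j in (i + 1):length(rp)) {
          A <- rp[[i]][[cl]]; B <- rp[[j]][[cl]]
          cors <- c(cors, pair_correlation(A, B))
        }
        rep_means <- c(rep_means, mean(cors, na.rm = TRUE))
      }
      m <- mean(rep_means)
      hw <- if (length(rep_means) > 1)
        qt(1 - (1 - conf_level) / 2, length(rep_means) - 1) *
          sd(rep_means) / sqrt(length(rep_means)) else 0
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, class = cl, mean = m,
                   ci_half_width = hw, n_reps = length(rep_means))
      per_rep_store[[paste(cond, cl, sep = ".")]] <- rep_means
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_rep") <- per_rep_store
  attr(out, "conf_level") <- conf_level
  out
}
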