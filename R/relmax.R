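#' Per-sample relevance scores for a filter condition
#'
#' Scores every test sample of the conditioned class by the signed sum of
#' its filter-conditioned CRP heatmap. Samples of the other class are not
#' scored (their entry is `NA`): concept representatives are always drawn
#' from the condition's own class.
#'
#' @param model eegnet
#' @param epochs held-out test [epoch_set()].
#' @param condition a [crp_condition()].
#' @param composite a [crp_composite()].
#' @return numeric vector of length `n_epochs(epochs)`; `NA` for
#'   non-matching class.
#' @export
score_samples <- function(model, epochs, condition,
                          composite = crp_composite()) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(condition, "crp_condition"))
  sel <- which(epochs$labels == condition$class_y)
  if (length(sel) == 0)
    stop("no samples of class ", condition$class_y, " to score")
  R <- crp(model, subset_epochs(epochs, sel), condition, composite)
  scores <- rep(NA_real_, n_epochs(epochs))
  scores[sel] <- attr(R, "total")
  scores
}

#' Top-k sample selection by relevance mass
#'
#' Sorts positive scores in descending order and returns the smallest
#' prefix whose cumulative mass reaches `mass_fraction` of the total
#' positive mass, clipped to at most `cap` samples. Ties are broken by
#' sample index. With no positive score the selection is empty (an empty
#' concept, excluded downstream).
#'
#' @param scores per-sample scores (`NA` allowed, never selected).
#' @param mass_fraction fraction of the total positive relevance mass the
#'   selection must reach (default 0.2).
#' @param cap hard upper bound on k (default 10).
#' @return integer vector of selected sample indices (possibly empty),
#'   in descending score order.
#' @export
select_top_k <- function(scores, mass_fraction = 0.2, cap = 10L) {
  stopifnot(mass_fraction > 0, mass_fraction <= 1, cap >= 1)
  idx <- which(!is.na(scores) & scores > 0)
  if (length(idx) == 0) return(integer(0))
  ord <- idx[order(-scores[idx], idx)]
  cum <- cumsum(scores[ord])
  total <- cum[length(cum)]
  k <- which(cum >= mass_fraction * total)[1]
  k <- min(k, cap, length(ord))
  ord[seq_len(k)]
}

#' Build one filter concept
#'
#' A concept is one (model, layer, filter, class) unit: the selected
#' representative samples, their relevance scores, the mean activation map
#' of the conditioned filter over those samples (the unit representation
#' used for cross-model comparison), and the mean frequency-domain
#' relevance.
#'
#' @param model eegnet
#' @param epochs test [epoch_set()].
#' @param condition singleton-filter [crp_condition()].
#' @param composite a [crp_composite()].
#' @param mass_fraction,cap selection rule parameters
#'   (see [select_top_k()]).
#' @param model_id identifier recorded on the concept.
#' @param sample_offset added to the stored sample ids (to express them in
#'   a cohort-global index space).
#' @param freq_rel optional precomputed `freq_relevance` for all of
#'   `epochs` under this condition (avoids recomputation).
#' @param scores optional precomputed [score_samples()] result.
#' @return object of class `concept`, or `NULL` for an empty concept.
#' @export
build_concept <- function(model, epochs, condition,
                          composite = crp_composite(),
                          mass_fraction = 0.2, cap = 10L,
                          model_id = "model", sample_offset = 0L,
                          freq_rel = NULL, scores = NULL) {
  stopifnot(length(condition$filters) == 1L)
  if (is.null(freq_rel))
    freq_rel <- relevance_in_frequency(model, epochs,
                                       condition = condition,
                                       composite = composite,
                                       sfreq = epochs$sfreq)
  if (is.null(scores)) {
    scores <- rep(NA_real_, n_epochs(epochs))
    sel0 <- which(epochs$labels == condition$class_y)
    scores[sel0] <- attr(freq_rel, "time_total")[sel0]
  }
  sel <- select_top_k(scores, mass_fraction, cap)
  if (length(sel) == 0) return(NULL)
  am <- forward_activations(model, subset_epochs(epochs, sel),
                            condition$layer_id)
  mean_map <- colMeans(matrix(am[, condition$filters, , drop = FALSE],
                              nrow = length(sel)))
  mf <- apply(unclass(freq_rel)[sel, , , drop = FALSE], c(2, 3), mean)
  structure(list(model_id = model_id, layer_id = condition$layer_id,
                 filter = condition$filters, class_y = condition$class_y,
                 sample_ids = sel + sample_offset,
                 scores = scores[sel], k = length(sel),
                 mean_map = mean_map, mean_freq_rel = mf,
                 freqs = attr(freq_rel, "freqs")),
            class = "concept")
}

#' All filter concepts of one trained model
#'
#' Iterates CRP + relevance maximization over every filter of a layer and
#' both classes on the model's held-out test data, returning the
#' non-empty concepts.
#'
#' @param model eegnet
#' @param epochs held-out test [epoch_set()].
#' @param layer_id conditioning layer (default the last, 16-filter,
#'   pointwise convolution).
#' @param classes classes to condition on.
#' @param composite,mass_fraction,cap see [build_concept()].
#' @param model_id,sample_offset bookkeeping passed through.
#' @return list of `concept` objects.
#' @export
concepts_for_model <- function(model, epochs,
                               layer_id = "pointwise_conv",
                               classes = c(0L, 1L),
                               composite = crp_composite(),
                               mass_fraction = 0.2, cap = 10L,
                               model_id = "model", sample_offset = 0L) {
  model <- canonicalize(model)
  model <- attach_vil(model)
  nf <- switch(layer_id, temporal_conv = model$dims$F1,
               spatial_conv = model$dims$M, sep_conv = model$dims$M,
               pointwise_conv = model$dims$F2)
  out <- list()
  for (cl in classes) {
    sel <- which(epochs$labels == cl)
    if (length(sel) == 0) next
    sub <- subset_epochs(epochs, sel)
    for (f in seq_len(nf)) {
      cond <- crp_condition(layer_id, f, cl)
      fr <- relevance_in_frequency(model, sub, condition = cond,
                                   composite = composite,
                                   sfreq = epochs$sfreq)
      scores <- attr(fr, "time_total")
      cpt <- build_concept(model, sub, cond, composite, mass_fraction,
                           cap, model_id = model_id,
                           sample_offset = 0L, freq_rel = fr,
                           scores = scores)
      if (is.null(cpt)) next
      # express sample ids in the caller's index space
      cpt$sample_ids <- sel[cpt$sample_ids] + sample_offset
      out[[length(out) + 1L]] <- cpt
    }
  }
  out
}
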