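#' Full-pipeline configuration
#'
#' One configuration object driving the whole analysis: synthetic cohort
#' (or a path to a stored epoch container), preprocessing, LOO training,
#' relevance/selection parameters, clustering, bands and regions. All
#' randomness is derived from the explicit seeds it carries.
#'
#' @param cohort a [cohort_config()], or a path to an HDF5 epoch
#'   container readable by [read_epochs_h5()].
#' @param train list: `epochs`, `batch_size`, `lr`, `seed_mode`,
#'   `n_reps`, `base_seed`, optional `hyper`.
#' @param relevance list: `mass_fraction`, `cap`, `layer_id`, plus
#'   [crp_composite()] arguments.
#' @param clustering list: `eps`, `min_samples` (NULL = auto),
#'   `n_neighbors`, `min_dist`, `seed`.
#' @param bands a [band_scheme()] (or names drawn from it).
#' @param preproc list: `car` (logical), `batch_size`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            preproc = list(car = TRUE, batch_size = 128L),
                            train = list(epochs = 500L, batch_size = 128L,
                                         lr = 1e-3, seed_mode = "unique",
                                         n_reps = 1L, base_seed = 1L),
                            relevance = list(mass_fraction = 0.2,
                                             cap = 10L,
                                             layer_id = "pointwise_conv"),
                            clustering = list(eps = 0.4,
                                              min_samples = NULL,
                                              n_neighbors = 15,
                                              min_dist = 0.1,
                                              seed = 42L),
                            bands = band_scheme()) {
  band_names <- c("delta", "theta", "alpha", "beta", "gamma")
  if (!inherits(bands, "band_scheme")) {
    if (is.character(bands)) {
      unknown <- setdiff(bands, band_names)
      if (length(unknown))
        stop("unknown band name(s): ", paste(unknown, collapse = ", "))
      sel <- band_scheme()[bands]
      bands <- structure(sel, class = "band_scheme")
    } else stop("bands must be a band_scheme or band names")
  }
  if (!is.null(relevance$mass_fraction) &&
      (relevance$mass_fraction <= 0 || relevance$mass_fraction > 1))
    stop("mass_fraction must be in (0, 1]")
  structure(list(cohort = cohort, preproc = preproc, train = train,
                 relevance = relevance, clustering = clustering,
                 bands = bands),
            class = "pipeline_config")
}

#' Run the full concept-analysis pipeline
#'
#' Orchestrates generate/load -> preprocess -> subject-independent LOO
#' training -> per-filter CRP concepts (relevance maximization) ->
#' per-class UMAP+DBSCAN clustering -> cluster composition -> functional
#' grouping and band-topography views -> ICA relevance, and persists
#' every stage's tabular outputs (CSV/JSON) under `out_dir` together with
#' a hash of the configuration. Reruns with the same configuration
#' reproduce the tabular outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- digest::digest(config)
  writeLines(cfg_hash, file.path(out_dir, "config_hash.txt"))

  stage <- function(name, expr) {
    message(sprintf("[pipeline] %s", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohort <- stage("data", {
    if (inherits(config$cohort, "cohort_config"))
      generate_cohort(config$cohort)
    else read_epochs_h5(config$cohort)
  })

  prep <- stage("preprocess", {
    x <- cohort
    if (isTRUE(config$preproc$car)) x <- common_average_reference(x)
    batch_standardize(x, config$preproc$batch_size)
  })

  runs <- stage("train", do.call(train_loo, c(
    list(cohort = prep),
    config$train[intersect(names(config$train),
                           c("seed_mode", "n_reps", "epochs", "batch_size",
                             "lr", "base_seed", "hyper"))])))
  acc <- data.frame(subject = vapply(runs, `[[`, "", "subject"),
                    rep = vapply(runs, `[[`, 0L, "rep"),
                    seed = vapply(runs, `[[`, 0L, "seed"),
                    accuracy = vapply(runs, `[[`, 0, "accuracy"))
  write.csv(acc, file.path(out_dir, "accuracy.csv"), row.names = FALSE)

  rel <- config$relevance
  composite <- crp_composite()
  concepts <- stage("explain", {
    out <- list()
    for (rn in runs[vapply(runs, `[[`, 0L, "rep") == 1L]) {
      te_idx <- which(prep$subjects == rn$subject)
      te <- subset_epochs(prep, te_idx)
      cps <- concepts_for_model(rn$model, te,
                                layer_id = rel$layer_id,
                                composite = composite,
                                mass_fraction = rel$mass_fraction,
                                cap = rel$cap,
                                model_id = paste0("model_", rn$subject))
      for (cp in cps) {
        cp$sample_ids <- te_idx[cp$sample_ids]
        out[[length(out) + 1L]] <- cp
      }
    }
    out
  })
  ctab <- data.frame(
    model = vapply(concepts, `[[`, "", "model_id"),
    filter = vapply(concepts, `[[`, 0L, "filter"),
    class = vapply(concepts, `[[`, 0L, "class_y"),
    k = vapply(concepts, `[[`, 0L, "k"),
    sample_ids = vapply(concepts, function(cp)
      paste(cp$sample_ids, collapse = ";"), ""))

  clus <- stage("cluster", {
    out <- list()
    for (cl in c(0L, 1L)) {
      cm <- concept_matrix(concepts, cl)
      coords <- embed_concepts(cm$X,
                               n_neighbors = config$clustering$n_neighbors,
                               min_dist = config$clustering$min_dist,
                               seed = config$clustering$seed)
      labels <- cluster_embedding(coords, config$clustering$eps,
                                  config$clustering$min_samples)
      comp <- cluster_composition(labels, cm$model_ids)
      out[[paste0("class", cl)]] <-
        list(idx = cm$idx, coords = coords, labels = labels,
             composition = comp)
    }
    out
  })
  ctab$cluster <- NA_integer_
  ctab$umap_x <- NA_real_; ctab$umap_y <- NA_real_
  for (cl in names(clus)) {
    ctab$cluster[clus[[cl]]$idx] <- clus[[cl]]$labels
    ctab$umap_x[clus[[cl]]$idx] <- clus[[cl]]$coords[, 1]
    ctab$umap_y[clus[[cl]]$idx] <- clus[[cl]]$coords[, 2]
  }
  write.csv(ctab, file.path(out_dir, "concepts.csv"), row.names = FALSE)
  for (cl in names(clus)) {
    comp <- clus[[cl]]$composition$composition
    write.csv(cbind(data.frame(model = rownames(comp)),
                    as.data.frame(comp)),
              file.path(out_dir, paste0("composition_", cl, ".csv")),
              row.names = FALSE)
  }

  views <- stage("views", {
    regions <- default_regions(prep$channels)
    out <- list()
    for (cl in c(0L, 1L)) {
      key <- paste0("class", cl)
      labs <- clus[[key]]$labels
      for (cid in sort(unique(labs[labs != -1L]))) {
        sub_c <- concepts[clus[[key]]$idx][labs == cid]
        fg <- functional_grouping(sub_c, regions, config$bands,
                                  channels = prep$channels)
        bt <- band_topo(sub_c, prep, config$bands)
        nm <- sprintf("class%d_cluster%d", cl, cid)
        write.csv(as.data.frame(fg),
                  file.path(out_dir, paste0("grouping_", nm, ".csv")))
        out[[nm]] <- list(grouping = fg, topo = bt)
      }
    }
    out
  })

  ica_out <- stage("ica", {
    truth <- tryCatch(ground_truth(cohort), error = function(e) NULL)
    labeler <- if (!is.null(truth)) ground_truth_labeler(truth)
    out <- list()
    for (cl in c(0L, 1L)) {
      key <- paste0("class", cl)
      labs <- clus[[key]]$labels
      kept <- sort(unique(labs[labs != -1L]))
      if (!length(kept)) next
      cid <- kept[1]
      sub_c <- concepts[clus[[key]]$idx][labs == cid]
      ids <- sort(unique(unlist(lapply(sub_c, `[[`, "sample_ids"))))
      mdl <- attach_vil(runs[[1]]$model)
      R <- lrp(mdl, subset_epochs(prep, ids), class_y = cl)
      Rfull <- array(0, dim(prep$data)); Rfull[ids, , ] <- unclass(R)
      tab <- ica_relevance(sub_c, prep, Rfull, labeler = labeler)
      write.csv(tab, file.path(out_dir,
                               sprintf("ica_class%d_cluster%d.csv",
                                       cl, cid)), row.names = FALSE)
      out[[key]] <- tab
    }
    out
  })

  res <- list(config_hash = cfg_hash, accuracy = acc,
              concepts = concepts, concept_table = ctab,
              clusters = clus, views = views, ica = ica_out)
  summary <- list(config_hash = cfg_hash,
                  mean_accuracy = mean(acc$accuracy),
                  n_concepts = length(concepts),
                  n_clusters = lapply(clus, function(z)
                    length(unique(z$labels[z$labels != -1L]))))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Render a human-readable pipeline report
#'
#' Assembles the persisted stage outputs of [run_pipeline()] into one
#' markdown document (accuracies, concept bookkeeping, cluster model
#' coverage, per-cluster functional grouping, ICA tables). Missing stage
#' outputs are marked absent rather than failing.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return path of the written `report.md`, invisibly.
#' @export
export_report <- function(out_dir) {
  lines <- c("# Concept analysis report", "")
  hash_f <- file.path(out_dir, "config_hash.txt")
  if (file.exists(hash_f))
    lines <- c(lines, paste("Configuration hash:", readLines(hash_f)), "")
  sec <- function(title, path, render) {
    if (!file.exists(path)) return(c(paste0("## ", title), "", "_absent_", ""))
    c(paste0("## ", title), "", render(path), "")
  }
  render_csv <- function(path) {
    df <- tryCatch(read.csv(path, check.names = FALSE),
                   error = function(e) NULL)
    if (is.null(df) || !nrow(df)) return("_empty_")
    c(paste(colnames(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(r, collapse = " | ")))
  }
  lines <- c(lines, sec("Leave-one-out accuracy",
                        file.path(out_dir, "accuracy.csv"), render_csv))
  lines <- c(lines, sec("Concepts",
                        file.path(out_dir, "concepts.csv"), render_csv))
  for (f in list.files(out_dir, pattern = "^composition_.*csv$"))
    lines <- c(lines, sec(paste("Cluster composition:", f),
                          file.path(out_dir, f), render_csv))
  for (f in list.files(out_dir, pattern = "^grouping_.*csv$"))
    lines <- c(lines, sec(paste("Functional grouping:", f),
                          file.path(out_dir, f), render_csv))
  for (f in list.files(out_dir, pattern = "^ica_.*csv$"))
    lines <- c(lines, sec(paste("ICA relevance:", f),
                          file.path(out_dir, f), render_csv))
  out <- file.path(out_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
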