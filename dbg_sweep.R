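library(crpeeg)
z <- readRDS("clu4.rds")   # 6 subjects, 16/class, 120 epochs, 10/13 Hz bursts
concepts <- z$concepts
for (nn in c(10, 15, 25, 40, 60)) for (md in c(0.1)) {
  cat("== n_neighbors", nn, "min_dist", md, "\n")
  for (cl in 0:1) {
    cm <- concept_matrix(concepts, cl)
    co <- embed_concepts(cm$X, n_neighbors = nn, min_dist = md, seed = 42)
    lb <- cluster_embedding(co, eps = 0.4)
    if (all(lb == -1)) { cat(" class", cl, ": no clusters\n"); next }
    cp <- cluster_composition(lb, cm$model_ids)
    cat(" class", cl, ": k", ncol(cp$composition), " cov", round(cp$coverage,2),
        " sizes", colSums(cp$composition), " noise", sum(lb==-1), "\n")
  }
}
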