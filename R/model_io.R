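#' Save an eegnet model to HDF5
#'
#' Layout: group `/params` with one dataset per weight array (`Wt`,
#' `bn1_gamma`, ..., `Wd`, `bd`, `b1..b3`), group `/dims` with the
#' architecture geometry, and scalars `/dropout`, `/canonical`.
#'
#' @param model eegnet
#' @param path output file (overwritten).
#' @return `path`, invisibly.
#' @export
save_eegnet_h5 <- function(model, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "params")
  p <- model$params
  flat <- list(Wt = p$Wt, Ws = p$Ws, Wsep = p$Wsep, Wpw = p$Wpw,
               Wd = p$Wd, bd = p$bd, b1 = p$b1, b2 = p$b2, b3 = p$b3)
  for (bn in c("bn1", "bn2", "bn3"))
    for (f in c("gamma", "beta", "mean", "var"))
      flat[[paste(bn, f, sep = "_")]] <- p[[bn]][[f]]
  for (nm in names(flat)) rhdf5::h5write(flat[[nm]], path,
                                         paste0("params/", nm))
  rhdf5::h5write(unlist(model$dims), path, "dims")
  rhdf5::h5write(names(model$dims), path, "dim_names")
  rhdf5::h5write(model$dropout, path, "dropout")
  rhdf5::h5write(as.integer(model$canonical), path, "canonical")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load an eegnet model from HDF5
#'
#' @param path file written by [save_eegnet_h5()].
#' @return eegnet
#' @export
load_eegnet_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  dims <- as.list(as.integer(rhdf5::h5read(path, "dims")))
  names(dims) <- as.vector(rhdf5::h5read(path, "dim_names"))
  rd <- function(nm) {
    v <- rhdf5::h5read(path, paste0("params/", nm))
    if (is.array(v) || is.matrix(v)) v else as.numeric(v)
  }
  p <- list(Wt = rd("Wt"), Ws = rd("Ws"), Wsep = rd("Wsep"),
            Wpw = rd("Wpw"), Wd = rd("Wd"), bd = as.numeric(rd("bd")),
            b1 = as.numeric(rd("b1")), b2 = as.numeric(rd("b2")),
            b3 = as.numeric(rd("b3")))
  for (bn in c("bn1", "bn2", "bn3"))
    p[[bn]] <- list(gamma = as.numeric(rd(paste0(bn, "_gamma"))),
                    beta = as.numeric(rd(paste0(bn, "_beta"))),
                    mean = as.numeric(rd(paste0(bn, "_mean"))),
                    var = as.numeric(rd(paste0(bn, "_var"))))
  structure(list(dims = dims, params = p,
                 dropout = as.numeric(rhdf5::h5read(path, "dropout")),
                 canonical = as.logical(
                   as.integer(rhdf5::h5read(path, "canonical"))),
                 bn_eps = 1e-3),
            class = "eegnet")
}
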