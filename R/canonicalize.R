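#' Fold batch normalization into the adjacent convolutions
#'
#' Rewrites the network into an equivalent batch-norm-free ("canonical")
#' form: each inference-mode batch-norm (running statistics) is folded
#' into the convolution it follows, producing scaled weights plus a
#' per-filter bias. Relevance propagation rules are defined on the
#' canonical form. The operation is idempotent and preserves the forward
#' pass up to floating-point error.
#'
#' @param model eegnet
#' @return canonical eegnet (`model$canonical == TRUE`).
#' @export
canonicalize <- function(model) {
  stopifnot(inherits(model, "eegnet"))
  if (model$canonical) return(model)
  p <- model$params
  eps <- model$bn_eps
  d <- model$dims
  s1 <- p$bn1$gamma / sqrt(p$bn1$var + eps)
  p$Wt <- sweep(p$Wt, 2, s1, "*")
  p$b1 <- p$bn1$beta - p$bn1$mean * s1
  s2 <- p$bn2$gamma / sqrt(p$bn2$var + eps)
  for (f1 in seq_len(d$F1)) for (dd in seq_len(d$D)) {
    m <- (f1 - 1L) * d$D + dd
    p$Ws[, dd, f1] <- p$Ws[, dd, f1] * s2[m]
  }
  p$b2 <- p$bn2$beta - p$bn2$mean * s2
  s3 <- p$bn3$gamma / sqrt(p$bn3$var + eps)
  p$Wpw <- sweep(p$Wpw, 2, s3, "*")
  p$b3 <- p$bn3$beta - p$bn3$mean * s3
  idbn <- function(k) list(gamma = rep(1, k), beta = rep(0, k),
                           mean = rep(0, k), var = rep(1, k))
  p$bn1 <- idbn(d$F1); p$bn2 <- idbn(d$M); p$bn3 <- idbn(d$F2)
  model$params <- p
  model$canonical <- TRUE
  model
}
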