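#' Relevance-propagation composite
#'
#' Assigns a propagation rule to each layer kind. The default is the
#' epsilon/alpha2-beta1 composite: the alpha-beta rule (alpha = 2,
#' beta = 1, weighing positive evidence twice as much as negative) on all
#' convolutional layers, the epsilon-stabilized rule on the dense head and
#' the average-pooling layers. ELU and dropout are relevance-transparent;
#' bias relevance is absorbed (kept in the denominators, not propagated).
#'
#' @param conv,dense,pool rule per layer kind: `"alphabeta"`, `"epsilon"`
#'   or `"lrp0"`.
#' @param alpha,beta alpha-beta rule coefficients; must satisfy
#'   `alpha - beta = 1`.
#' @param epsilon stabilizer of the epsilon rule, relative to the mean
#'   absolute denominator of the layer; must be > 0.
#' @return object of class `crp_composite`.
#' @export
crp_composite <- function(conv = "alphabeta", dense = "epsilon",
                          pool = "epsilon", alpha = 2, beta = 1,
                          epsilon = 1e-6) {
  rules <- c("alphabeta", "epsilon", "lrp0")
  stopifnot(conv %in% rules, dense %in% rules, pool %in% rules)
  if (abs(alpha - beta - 1) > 1e-12) stop("alpha - beta must equal 1")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(conv = conv, dense = dense, pool = pool, alpha = alpha,
                 beta = beta, epsilon = epsilon),
            class = "crp_composite")
}

#' CRP conditioning set
#'
#' Restricts the backward relevance flow at a convolutional layer to a
#' subset of its filters (the concept conditioning set), together with the
#' output class the explanation is computed for.
#'
#' @param layer_id convolutional layer id (see [eegnet_layers()]).
#' @param filters non-empty integer vector of filter indices (1-based).
#' @param class_y conditioned class label (0-based).
#' @return object of class `crp_condition`.
#' @export
crp_condition <- function(layer_id, filters, class_y) {
  conv_layers <- c("temporal_conv", "spatial_conv", "sep_conv",
                   "pointwise_conv")
  if (!layer_id %in% conv_layers)
    stop("condition layer must be convolutional")
  filters <- as.integer(filters)
  if (length(filters) == 0) stop("empty filter conditioning set")
  if (anyDuplicated(filters)) stop("duplicated filter indices")
  structure(list(layer_id = layer_id, filters = filters,
                 class_y = as.integer(class_y)),
            class = "crp_condition")
}

# 0/0-safe division (used by alpha-beta and lrp0 denominators)
sdiv <- function(num, den) {
  out <- num / den
  out[den == 0] <- 0
  out
}

# epsilon-stabilized division; eps is relative to the denominator scale
ediv <- function(num, den, eps) {
  s <- eps * mean(abs(den))
  if (s == 0) return(sdiv(num, den))
  num / (den + s * (2 * (den >= 0) - 1))
}

pos <- function(x) pmax(x, 0)
neg <- function(x) pmin(x, 0)

# alpha-beta redistribution factors per output unit. Units whose
# contributions are single-signed fall back to the plain proportional
# split (the missing part carries no mass to counter-weigh), which keeps
# the rule exactly conserving on bias-free layers.
ab_factors <- function(R, zp, zn, alpha, beta) {
  bp <- sdiv(R, zp); bn <- sdiv(R, zn)
  Up <- alpha * bp; Un <- beta * bn
  op <- (zn == 0) & (zp != 0)
  on <- (zp == 0) & (zn != 0)
  if (any(op)) Up[op] <- bp[op]
  if (any(on)) Un[on] <- -bn[on]
  list(Up = Up, Un = Un)
}

#' Single-layer relevance redistribution (dense-like layer)
#'
#' Redistributes upper-layer relevance through one linear map
#' `z = a %*% W (+ b)` with the requested rule. Exposed as a building
#' block for toy analyses; the network-level drivers are [lrp()] and
#' [crp()].
#'
#' @param rule `"lrp0"`, `"epsilon"` or `"alphabeta"`.
#' @param a inputs, vector `[J]` or matrix `[n, J]`.
#' @param W weights `[J, K]`.
#' @param R upper relevance, vector `[K]` or matrix `[n, K]`.
#' @param b optional bias `[K]` (its relevance share is absorbed).
#' @param alpha,beta,epsilon rule parameters.
#' @return relevance of the inputs, same shape as `a`.
#' @export
propagate_layer <- function(rule, a, W, R, b = NULL, alpha = 2, beta = 1,
                            epsilon = 1e-6) {
  vec <- is.null(dim(a))
  if (vec) { a <- matrix(a, 1); R <- matrix(R, 1) }
  if (is.null(b)) b <- numeric(ncol(W))
  if (rule %in% c("lrp0", "epsilon")) {
    z <- a %*% W + matrix(b, nrow(a), ncol(W), byrow = TRUE)
    ratio <- if (rule == "lrp0") sdiv(R, z) else ediv(R, z, epsilon)
    out <- a * (ratio %*% t(W))
  } else if (rule == "alphabeta") {
    if (abs(alpha - beta - 1) > 1e-12) stop("alpha - beta must equal 1")
    ap <- pos(a); an <- neg(a)
    Wp <- pos(W); Wn <- neg(W)
    zp <- ap %*% Wp + an %*% Wn +
      matrix(pos(b), nrow(a), ncol(W), byrow = TRUE)
    zn <- ap %*% Wn + an %*% Wp +
      matrix(neg(b), nrow(a), ncol(W), byrow = TRUE)
    fac <- ab_factors(R, zp, zn, alpha, beta)
    Up <- fac$Up; Un <- fac$Un
    out <- ap * (Up %*% t(Wp)) + an * (Up %*% t(Wn)) -
      ap * (Un %*% t(Wn)) - an * (Un %*% t(Wp))
  } else stop("unknown rule: ", rule)
  if (vec) out <- drop(out)
  out
}

# relevance redistribution through a time-convolution bank.
# a: flat [T, M]; W: [K, F]; bias per f (optional); R: flat [T, M, F].
# Returns flat [T, M].
ab_conv_cols <- function(a, W, R, bias, padL, alpha, beta,
                         Tn, M, rule = "alphabeta", eps = 1e-6) {
  FF <- ncol(W)
  L <- Tn * M
  add_bias <- function(z, b) {
    for (f in seq_len(FF)) if (b[f] != 0) {
      rng <- ((f - 1) * L + 1):(f * L)
      z[rng] <- z[rng] + b[f]
    }
    z
  }
  if (rule != "alphabeta") {
    z <- cpp_conv_fwd(a, Tn, M, W, padL)
    if (!is.null(bias)) z <- add_bias(z, bias)
    ratio <- if (rule == "lrp0") sdiv(R, z) else ediv(R, z, eps)
    return(a * cpp_conv_gradin(ratio, Tn, M, W, padL))
  }
  ap <- pos(a); an <- neg(a)
  Wp <- pos(W); Wn <- neg(W)
  zp <- cpp_conv_fwd(ap, Tn, M, Wp, padL) +
    cpp_conv_fwd(an, Tn, M, Wn, padL)
  zn <- cpp_conv_fwd(ap, Tn, M, Wn, padL) +
    cpp_conv_fwd(an, Tn, M, Wp, padL)
  if (!is.null(bias)) {
    zp <- add_bias(zp, pos(bias))
    zn <- add_bias(zn, neg(bias))
  }
  fac <- ab_factors(R, zp, zn, alpha, beta)
  Up <- fac$Up; Un <- fac$Un
  ap * (cpp_conv_gradin(Up, Tn, M, Wp, padL) -
          cpp_conv_gradin(Un, Tn, M, Wn, padL)) +
    an * (cpp_conv_gradin(Up, Tn, M, Wn, padL) -
            cpp_conv_gradin(Un, Tn, M, Wp, padL))
}

# epsilon-rule through average pooling (factor p along dim 1)
eps_pool <- function(E, P, R, p, eps) {
  ratio <- ediv(R, P, eps)
  out <- E * pool_bwd(ratio, p, dim(E)[1])
  out
}

# backward relevance through the canonical network
crp_backward <- function(model, cache, Rlogit, composite, condition) {
  d <- model$dims; p <- model$params
  n <- cache$n
  al <- composite$alpha; be <- composite$beta; eps <- composite$epsilon
  cond_layer <- if (is.null(condition)) "" else condition$layer_id
  mask_filters <- function(R, dim_idx, nf) {
    keep <- condition$filters
    if (any(keep < 1 | keep > nf))
      stop("condition filter index out of range")
    for (f in setdiff(seq_len(nf), keep)) {
      if (dim_idx == 2) R[, f, ] <- 0 else R[, , , f] <- 0
    }
    R
  }

  # dense head
  Rflat <- t(propagate_layer(composite$dense, t(cache$flat), p$Wd,
                             t(Rlogit), b = p$bd, alpha = al, beta = be,
                             epsilon = eps))        # [n_flat, n]
  R <- array(Rflat, c(d$t2, d$F2, n))

  # pool2 (dropout transparent at inference)
  R <- eps_pool(cache$E2, cache$P2, R, d$pool2, eps)
  # elu2 transparent -> relevance at pointwise conv output
  if (cond_layer == "pointwise_conv") R <- mask_filters(R, 2, d$F2)

  # pointwise conv (alpha-beta)
  Rm <- aperm(R, c(2, 1, 3)); dim(Rm) <- c(d$F2, d$t1 * n)
  aS <- cache$Sm                                    # [M, t1*n]
  Rs <- t(propagate_layer(composite$conv, t(aS), p$Wpw, t(Rm),
                          b = p$b3, alpha = al, beta = be,
                          epsilon = eps))
  R <- aperm(array(Rs, c(d$M, d$t1, n)), c(2, 1, 3))  # [t1, M, n]
  if (cond_layer == "sep_conv") R <- mask_filters(R, 2, d$M)

  # separable depthwise conv (alpha-beta), per map
  Rd1 <- array(0, dim(R))
  for (m in seq_len(d$M)) {
    Rd1[, m, ] <- ab_conv_cols(cache$D1[, m, , drop = TRUE],
                               p$Wsep[, m, drop = FALSE],
                               R[, m, , drop = TRUE],
                               bias = NULL, d$padL_s, al, be,
                               Tn = d$t1, M = n,
                               rule = composite$conv, eps = eps)
  }
  # dropout transparent; pool1
  R <- eps_pool(cache$E1, cache$P1, Rd1, d$pool1, eps)
  # elu1 transparent -> relevance at spatial conv output
  if (cond_layer == "spatial_conv") R <- mask_filters(R, 2, d$M)

  # spatial depthwise conv
  dims4 <- c(d$Tn, d$C, n, d$F1)
  A <- cache$A1bn
  if (composite$conv != "alphabeta") {
    z <- cache$Z2          # canonical: spatial output incl. folded bias
    ratio <- if (composite$conv == "lrp0") sdiv(R, z) else ediv(R, z, eps)
    R4 <- A * cpp_spatial_gradin(ratio, p$Ws, dims4)
  } else {
    Ap <- pos(A); An <- neg(A)
    Wsp <- pos(p$Ws); Wsn <- neg(p$Ws)
    zp <- cpp_spatial_fwd(Ap, Wsp, dims4) + cpp_spatial_fwd(An, Wsn, dims4)
    zn <- cpp_spatial_fwd(Ap, Wsn, dims4) + cpp_spatial_fwd(An, Wsp, dims4)
    dim(zp) <- c(d$Tn, d$M, n); dim(zn) <- c(d$Tn, d$M, n)
    for (m in seq_len(d$M)) {
      if (p$b2[m] > 0) zp[, m, ] <- zp[, m, ] + p$b2[m]
      if (p$b2[m] < 0) zn[, m, ] <- zn[, m, ] + p$b2[m]
    }
    fac <- ab_factors(R, zp, zn, al, be)
    Up <- fac$Up; Un <- fac$Un
    R4 <- Ap * (cpp_spatial_gradin(Up, Wsp, dims4) -
                  cpp_spatial_gradin(Un, Wsn, dims4)) +
      An * (cpp_spatial_gradin(Up, Wsn, dims4) -
              cpp_spatial_gradin(Un, Wsp, dims4))
  }
  if (cond_layer == "temporal_conv") {
    dim(R4) <- dims4
    R4 <- mask_filters(R4, 4, d$F1)
  }

  # temporal conv bank
  Rx <- ab_conv_cols(cache$X0m, p$Wt, R4, bias = p$b1, d$padL_t, al, be,
                     Tn = d$Tn, M = d$C * n,
                     rule = composite$conv, eps = eps)
  dim(Rx) <- c(d$Tn, d$C, n)
  aperm(Rx, c(3, 2, 1))                             # [n, C, T]
}

#' Layer-wise relevance propagation heatmap
#'
#' Propagates the class logit backward through the (canonicalized)
#' network with the composite's rules, yielding an input-shaped
#' time-domain relevance heatmap per sample.
#'
#' @param model eegnet (canonicalized internally if needed).
#' @param x array `[n, C, T]` or [epoch_set()].
#' @param class_y class whose logit seeds the propagation (0-based).
#' @param composite a [crp_composite()].
#' @param condition optional [crp_condition()] restricting flow to a
#'   filter subset (see [crp()]).
#' @return `relevance_tensor`: array `[n, C, T]` with attributes `domain`
#'   (`"time"`), `total` (per-sample relevance sums) and `logit`
#'   (per-sample seed logits).
#' @export
lrp <- function(model, x, class_y, composite = crp_composite(),
                condition = NULL) {
  if (inherits(x, "epoch_set")) x <- x$data
  model <- canonicalize(model)
  fw <- eegnet_forward(model, x, training = FALSE, return_cache = TRUE)
  if (!all(is.finite(fw$logits))) stop("non-finite activations")
  n <- dim(x)[1]
  Rlogit <- matrix(0, model$dims$n_classes, n)
  Rlogit[class_y + 1L, ] <- fw$cache$logitm[class_y + 1L, ]
  R <- crp_backward(model, fw$cache, Rlogit, composite, condition)
  structure(R, class = "relevance_tensor", domain = "time",
            total = apply(R, 1, sum),
            logit = fw$logits[, class_y + 1L], class_y = class_y)
}

#' Concept relevance propagation (filter-conditioned LRP)
#'
#' Identical to [lrp()] except that, at the conditioning layer, relevance
#' outside the chosen filter set is set to zero before further
#' propagation, isolating the concept encoded by those filters. Summing
#' the heatmaps of singleton conditions over all filters of a layer
#' recovers the unconditioned LRP heatmap.
#'
#' @param model eegnet
#' @param x array `[n, C, T]` or [epoch_set()].
#' @param condition a [crp_condition()].
#' @param composite a [crp_composite()].
#' @return `relevance_tensor` as in [lrp()].
#' @export
crp <- function(model, x, condition, composite = crp_composite()) {
  stopifnot(inherits(condition, "crp_condition"))
  lrp(model, x, class_y = condition$class_y, composite = composite,
      condition = condition)
}
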