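test_that("single-layer redistribution reproduces hand-computed values", {
  # y = 2*x1 + 3*x2 at x = (1,1): R_out = 5 splits into (2, 3)
  W <- matrix(c(2, 3), 2, 1)
  expect_equal(propagate_layer("lrp0", c(1, 1), W, R = 5), c(2, 3))
  # all contributions positive: alpha2-beta1 equals the plain split
  expect_equal(propagate_layer("alphabeta", c(1, 1), W, R = 5,
                               alpha = 2, beta = 1), c(2, 3))
  # uniform average pool over 4 equal inputs shares R_out symmetrically
  Wp <- matrix(1 / 4, 4, 1)
  expect_equal(propagate_layer("epsilon", rep(2, 4), Wp, R = 1),
               rep(0.25, 4), tolerance = 1e-5)
})

test_that("alpha-beta conserves exactly on bias-free mixed-sign layers", {
  set.seed(8)
  a <- matrix(rnorm(50), 5, 10)
  W <- matrix(rnorm(80), 10, 8)
  R <- matrix(rnorm(40), 5, 8)
  Ra <- propagate_layer("alphabeta", a, W, R, alpha = 2, beta = 1)
  expect_equal(rowSums(Ra), rowSums(R), tolerance = 1e-10)
  # epsilon-rule converges to conservation as epsilon -> 0
  Re1 <- propagate_layer("epsilon", a, W, R, epsilon = 1e-10)
  expect_equal(rowSums(Re1), rowSums(R), tolerance = 1e-6)
})

test_that("LRP-0 equals gradient-x-input on a bias-free ReLU toy net", {
  set.seed(9)
  W1 <- matrix(rnorm(12), 4, 3)
  W2 <- matrix(rnorm(3), 3, 1)
  x <- rnorm(4)
  h <- pmax(x %*% W1, 0)
  y <- drop(h %*% W2)
  # independent oracle: numerical gradient of the network output
  f <- function(v) drop(pmax(v %*% W1, 0) %*% W2)
  gnum <- vapply(1:4, function(i) {
    e <- rep(0, 4); e[i] <- 1e-6
    (f(x + e) - f(x - e)) / 2e-6
  }, 0)
  # LRP-0 chain: relevance through the two linear maps (ReLU transparent,
  # with relevance restricted to active units by construction)
  Rh <- propagate_layer("lrp0", drop(h), W2, R = y)
  Rx <- propagate_layer("lrp0", x, W1, R = Rh)
  expect_equal(Rx, gnum * x, tolerance = 1e-6)
})

test_that("network relevance conserves the seed logit on a bias-free model", {
  m <- build_eegnet(8, 96, seed = 7)       # bias-free when canonicalized
  x <- rand_epochs(n = 6, seed = 14)
  R <- lrp(m, x, class_y = 1)
  ratio <- attr(R, "total") / attr(R, "logit")
  expect_true(all(ratio > 0.99 & ratio < 1.01))
})

test_that("singleton filter conditions partition the unconditioned heatmap", {
  m <- build_eegnet(8, 96, seed = 8)
  x <- rand_epochs(n = 3, seed = 15)
  R <- lrp(m, x, class_y = 0)
  Rsum <- array(0, dim(R))
  for (f in 1:16)
    Rsum <- Rsum + unclass(crp(m, x, crp_condition("pointwise_conv", f, 0L)))
  expect_lt(max(abs(Rsum - unclass(R))) / max(abs(unclass(R))), 1e-6)
})

test_that("conditioning on all filters equals unconditioned propagation", {
  m <- build_eegnet(8, 96, seed = 9)
  x <- rand_epochs(n = 2, seed = 16)
  R <- lrp(m, x, class_y = 1)
  Rall <- crp(m, x, crp_condition("pointwise_conv", 1:16, 1L))
  expect_equal(unclass(Rall), unclass(R), tolerance = 1e-12)
})

test_that("CRP is additive over disjoint filter sets", {
  m <- build_eegnet(8, 96, seed = 10)
  x <- rand_epochs(n = 2, seed = 17)
  r1 <- as.numeric(crp(m, x, crp_condition("pointwise_conv", 1:5, 0L)))
  r2 <- as.numeric(crp(m, x, crp_condition("pointwise_conv", 6:16, 0L)))
  r12 <- as.numeric(crp(m, x, crp_condition("pointwise_conv", 1:16, 0L)))
  expect_equal(r1 + r2, r12, tolerance = 1e-10)
})

test_that("invalid conditions and composites are rejected", {
  expect_error(crp_condition("pointwise_conv", integer(0), 0), "empty")
  expect_error(crp_condition("dense", 1, 0), "convolutional")
  expect_error(crp_composite(alpha = 2, beta = 0.5), "alpha - beta")
  expect_error(crp_composite(epsilon = 0), "epsilon")
  m <- build_eegnet(8, 96, seed = 11)
  x <- rand_epochs(n = 1, seed = 18)
  expect_error(crp(m, x, crp_condition("pointwise_conv", 20, 0L)),
               "out of range")
})

test_that("a zero seed logit produces an all-zero heatmap", {
  m <- build_eegnet(8, 96, seed = 12)
  m$params$Wd[, 1] <- 0; m$params$bd[] <- 0
  x <- rand_epochs(n = 2, seed = 19)
  R <- lrp(m, x, class_y = 0)
  expect_equal(max(abs(unclass(R))), 0)
})
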