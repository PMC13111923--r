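test_that("the DFT inspection layer leaves predictions unchanged", {
  m <- build_eegnet(8, 96, seed = 20)
  x <- rand_epochs(n = 3, seed = 21)
  mv <- attach_vil(m)
  p0 <- eegnet_predict(m, x)$logits
  p1 <- predict_with_vil(mv, x)$logits
  expect_lt(max(abs(p0 - p1)), 1e-5)
  # round trip of the raw signal is exact to numerical precision
  xr <- crpeeg:::vil_reconstruct(mv, x)
  expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-6)
  # one-sided grid: floor(T/2)+1 bins at sfreq/T spacing
  expect_equal(mv$vil$n_bins, 96L %/% 2L + 1L)
})

test_that("total relevance is conserved between time and frequency domains", {
  m <- build_eegnet(8, 96, seed = 22)
  x <- rand_epochs(n = 5, seed = 23)
  fr <- relevance_in_frequency(m, x, class_y = 1, sfreq = 32)
  tt <- attr(fr, "time_total")
  expect_lt(max(abs(attr(fr, "total") - tt) / pmax(abs(tt), 1e-12)), 1e-5)
  expect_equal(dim(fr), c(5L, 8L, 49L))
  expect_equal(attr(fr, "freqs")[2], 32 / 96)
})

test_that("zero time-domain relevance maps to zero frequency relevance", {
  m <- build_eegnet(8, 96, seed = 24)
  m$params$Wd[, 2] <- 0; m$params$bd[] <- 0
  x <- rand_epochs(n = 2, seed = 25)
  fr <- relevance_in_frequency(m, x, class_y = 1, sfreq = 32)
  expect_equal(max(abs(unclass(fr))), 0)
})

test_that("band aggregation routes bins into the canonical bands", {
  bands <- band_scheme()
  nb <- 193
  freqs <- (0:(nb - 1)) / 3
  fr <- structure(matrix(0, 4, nb), freqs = freqs)
  fr[2, which.min(abs(freqs - 10))] <- 3        # exactly one alpha bin
  out <- band_aggregate(fr, bands, positive_only = TRUE)
  expect_equal(unname(out[2, "alpha"]), 3)
  expect_equal(unname(sum(out) - out[2, "alpha"]), 0)
  # all-negative input with positive_only gives zeros
  frn <- structure(matrix(-1, 4, nb), freqs = freqs)
  expect_true(all(band_aggregate(frn, bands) == 0))
  # uniform relevance: band mass proportional to bin count (signed mode)
  fru <- structure(matrix(1, 1, nb), freqs = freqs)
  outu <- band_aggregate(fru, bands, positive_only = FALSE)
  counts <- vapply(bands, function(b)
    sum(freqs >= b[1] & freqs < b[2]), 0)
  expect_equal(as.numeric(outu), as.numeric(counts))
  # bins at/above 60 Hz fall outside every band and are reported
  expect_equal(attr(outu, "out_of_band"), sum(freqs >= 60))
})

test_that("a matched-filter model concentrates relevance on the tone's bin", {
  # hand-built model: temporal filter 1 = 10 Hz quadrature pair on an
  # 8-channel net; the spatial filter picks channel 3; positive head
  Tn <- 384L; C <- 8L
  m <- build_eegnet(C, Tn, seed = 26)
  f0 <- 31 / 3                                    # exact DFT bin 31
  tt <- (0:63) / 128
  m$params$Wt[] <- 0
  m$params$Wt[, 1] <- sin(2 * pi * f0 * tt)
  m$params$Wt[, 2] <- cos(2 * pi * f0 * tt)
  m$params$Ws[] <- 0
  m$params$Ws[3, 1, 1] <- 1; m$params$Ws[3, 1, 2] <- 1
  m$params$Wsep[] <- 0; m$params$Wsep[8, ] <- 1   # pass-through tap
  m$params$Wpw[] <- abs(m$params$Wpw)
  m$params$Wd[] <- abs(m$params$Wd)
  x <- array(0, c(1, C, Tn))
  x[1, 3, ] <- sin(2 * pi * f0 * (1:Tn) / 128 + 0.4)
  fr <- relevance_in_frequency(m, x, class_y = 0, sfreq = 128)
  v <- abs(fr[1, 3, ])
  bin <- which.max(v)
  freqs <- attr(fr, "freqs")
  expect_lt(abs(freqs[bin] - f0), 0.34)
  win <- max(1, bin - 1):min(length(v), bin + 1)
  expect_gte(sum(v[win]) / sum(abs(fr)), 0.95)
})
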