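test_that("mains tone is suppressed and the passband preserved", {
  pc <- preproc_config()
  t <- seq(0, 20, by = 1 / 512)[-1]
  raw <- continuous_eeg(rbind(sin(2 * pi * 50 * t),
                              sin(2 * pi * 10 * t)), 512)
  out <- filter_and_resample(raw, pc)
  expect_equal(out$sfreq, 128)
  mid <- 300:2200                      # away from filter edge effects
  expect_lt(sd(out$data[1, mid]) / sd(raw$data[1, ]), 0.1)
  expect_lt(abs(max(abs(out$data[2, mid])) - 1), 0.05)
})

test_that("a 360 s trial yields 120 non-overlapping 3 s windows", {
  pc <- preproc_config()
  x <- matrix(rnorm(2 * 360 * 128), 2)
  w <- window_epochs(continuous_eeg(x, 128), pc)
  expect_equal(n_epochs(w), 120)
  expect_equal(n_times(w), 384)
  # left-aligned half-open windows: first window = first 384 samples
  expect_equal(w$data[1, , ], x[, 1:384])
})

test_that("band edge above the post-resampling Nyquist is rejected", {
  expect_error(preproc_config(band = c(1, 70), resample_hz = 128),
               "Nyquist")
  expect_error(preproc_config(band = c(1, 60), resample_hz = 100),
               "Nyquist")
})

test_that("common average reference zeroes the channel sum and is idempotent", {
  co <- generate_cohort(lateralized_config(n_subjects = 1,
                                           n_epochs_per_class = 3))
  car <- common_average_reference(co)
  sums <- apply(car$data, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-10)
  car2 <- common_average_reference(car)
  expect_equal(car2$data, car$data, tolerance = 1e-12)
  # constant offset on all channels is removed entirely
  cst <- co; cst$data[] <- 5
  expect_true(all(common_average_reference(cst)$data == 0))
})

test_that("CAR of a one-hot spatial pattern follows the (1 - 1/C) algebra", {
  C <- 8
  d <- array(0, c(1, C, 4)); d[1, 3, ] <- 1
  es <- epoch_set(d, 0L, "S01", paste0("ch", 1:C), 128)
  car <- common_average_reference(es)
  expect_equal(car$data[1, 3, ], rep(1 - 1 / C, 4))
  expect_equal(car$data[1, 1, ], rep(-1 / C, 4))
})

test_that("batch standardization yields mean 0 / sd 1 per channel per batch", {
  co <- generate_cohort(lateralized_config(n_subjects = 2,
                                           n_epochs_per_class = 10))
  bs <- batch_standardize(co, batch_size = 16)
  n <- n_epochs(co)
  starts <- seq(1, n, by = 16)
  for (s in starts[c(1, length(starts))]) {
    idx <- s:min(s + 15, n)
    for (c in c(1, n_channels(co))) {
      v <- as.vector(bs$data[idx, c, ])
      expect_lt(abs(mean(v)), 1e-6)
      expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
    }
  }
  # the trailing partial batch is standardized on its own statistics
  expect_false(n %% 16 == 0 && length(starts) == 1)
})

test_that("standardization is invariant to per-channel affine scaling", {
  co <- generate_cohort(lateralized_config(n_subjects = 1,
                                           n_epochs_per_class = 8))
  sc <- co
  for (c in seq_len(n_channels(co)))
    sc$data[, c, ] <- sc$data[, c, ] * (c + 1) + 3 * c
  expect_equal(batch_standardize(sc, 8)$data,
               batch_standardize(co, 8)$data, tolerance = 1e-8)
})

test_that("unit-variance, zero-mean batches pass through unchanged", {
  set.seed(3)
  d <- array(rnorm(8 * 2 * 64), c(8, 2, 64))
  for (c in 1:2) {
    v <- d[, c, ]
    d[, c, ] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }
  es <- epoch_set(d, rep(0:1, 4), rep("S01", 8), c("a", "b"), 128)
  expect_equal(batch_standardize(es, 8)$data, d, tolerance = 1e-6)
})
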