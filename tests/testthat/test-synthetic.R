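test_that("noise-free tone cohort concentrates power on the planted channel/band", {
  co <- generate_cohort(tone_config())
  i0 <- which(co$labels == 0)
  ps <- crpeeg:::mean_periodogram(subset_epochs(co, i0))
  f <- (0:(n_times(co) %/% 2)) * co$sfreq / n_times(co)
  c3 <- which(co$channels == "C3")
  expect_equal(max(ps[-c3, ]), 0)
  peak <- f[which.max(ps[c3, ])]
  expect_gte(peak, 8); expect_lt(peak, 12)
  # class-1 epochs carry no signal at all in this config
  expect_equal(max(abs(co$data[co$labels == 1, , ])), 0)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- lateralized_config(n_subjects = 2, n_epochs_per_class = 3)
  expect_identical(generate_cohort(cfg)$data, generate_cohort(cfg)$data)
})

test_that("pink-noise background has the configured spectral slope", {
  cfg <- cohort_config(n_subjects = 1, n_epochs_per_class = 30,
                       signal_spec = list(),
                       noise_spec = list(exponent = 1, amplitude = 5),
                       artifact_spec = list(),
                       subject_variability = list(amp_jitter = 0,
                                                  freq_jitter = 0),
                       seed = 5)
  co <- generate_cohort(cfg)
  ps <- colMeans(crpeeg:::mean_periodogram(co))
  f <- (0:(n_times(co) %/% 2)) * co$sfreq / n_times(co)
  sel <- f >= 2 & f <= 40
  slope <- unname(coef(lm(log(ps[sel]) ~ log(f[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("all-zero amplitudes produce an exactly zero cohort", {
  cfg <- cohort_config(
    n_subjects = 1, n_epochs_per_class = 2,
    signal_spec = list(list(class = 0, center = 10, bandwidth = 0,
                            channels = "C3", amplitude = 0)),
    noise_spec = list(exponent = 1, amplitude = 0),
    artifact_spec = list(list(kind = "blink", channels = "Fp1",
                              rate = 1, amplitude = 0)),
    subject_variability = list(amp_jitter = 0, freq_jitter = 0),
    seed = 7)
  expect_true(all(generate_cohort(cfg)$data == 0))
})

test_that("ground truth lists every planted source with its loading", {
  # loud, frequent blinks so the source dominates its loading channel
  cfg <- lateralized_config(n_subjects = 2, n_epochs_per_class = 5)
  cfg$artifact_spec[[1]]$amplitude <- 100
  cfg$artifact_spec[[1]]$rate <- 0.8
  co <- generate_cohort(cfg)
  gt <- ground_truth(co)
  # source count = planted signals + artifacts
  expect_length(gt$sources,
                length(cfg$signal_spec) + length(cfg$artifact_spec))
  bl <- gt$sources[[which(vapply(gt$sources, `[[`, "", "kind") == "blink")]]
  expect_setequal(names(which(bl$loading > 0)), c("Fp1", "Fp2"))
  # loud blink time course is visible on its loading channel
  fp1 <- which(co$channels == "Fp1")
  expect_gt(cor(as.vector(bl$time_course), as.vector(co$data[, fp1, ])),
            0.5)
})

test_that("sources plus noise-free residual reconstruct the data", {
  cfg <- cohort_config(
    n_subjects = 1, n_epochs_per_class = 4,
    signal_spec = list(list(class = 0, center = 12, bandwidth = 1,
                            channels = c("C3", "FC1"), amplitude = 3)),
    noise_spec = list(exponent = 1, amplitude = 0),
    artifact_spec = list(list(kind = "blink", channels = c("Fp1", "Fp2"),
                              rate = 0.5, amplitude = 20)),
    subject_variability = list(amp_jitter = 0, freq_jitter = 0),
    seed = 9)
  co <- generate_cohort(cfg)
  gt <- ground_truth(co)
  rec <- array(0, dim(co$data))
  for (s in gt$sources)
    for (c in which(s$loading != 0))
      rec[, c, ] <- rec[, c, ] + s$loading[c] * s$time_course
  expect_equal(rec, co$data, tolerance = 1e-12)
})

test_that("planted class band-power difference has the planted sign per subject", {
  cfg <- lateralized_config(n_subjects = 4, n_epochs_per_class = 8)
  co <- generate_cohort(cfg)
  f <- (0:(n_times(co) %/% 2)) * co$sfreq / n_times(co)
  alpha <- f >= 8 & f < 12
  t7 <- which(co$channels == "T7")
  for (su in unique(co$subjects)) {
    p0 <- crpeeg:::mean_periodogram(
      subset_epochs(co, co$subjects == su & co$labels == 0))
    p1 <- crpeeg:::mean_periodogram(
      subset_epochs(co, co$subjects == su & co$labels == 1))
    expect_gt(sum(p0[t7, alpha]), sum(p1[t7, alpha]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(montage = c("C3", "C3")), "unique")
  expect_error(cohort_config(signal_spec = list(
    list(class = 0, center = 10, bandwidth = 1, channels = "NOPE",
         amplitude = 1))), "not in montage")
  expect_error(cohort_config(noise_spec = list(exponent = 1,
                                               amplitude = -1)), ">= 0")
  expect_error(cohort_config(sfreq = 100, epoch_len = 1.505), "integer")
})

test_that("epoch container round-trips through HDF5", {
  co <- generate_cohort(tone_config(n_epochs_per_class = 2))
  path <- tempfile(fileext = ".h5")
  write_epochs_h5(co, path)
  back <- read_epochs_h5(path)
  expect_equal(back$data, co$data, tolerance = 1e-12)
  expect_identical(back$labels, co$labels)
  expect_identical(back$channels, co$channels)
  expect_equal(back$sfreq, co$sfreq)
  unlink(path)
})
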