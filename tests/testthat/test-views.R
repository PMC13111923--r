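# concepts referencing a tiny cohort, with controllable frequency relevance
view_fixture <- function(rel_fun, seed = 50, n_epochs_per_class = 6) {
  co <- generate_cohort(lateralized_config(n_subjects = 1,
                                           n_epochs_per_class =
                                             n_epochs_per_class,
                                           seed = seed))
  nb <- n_times(co) %/% 2 + 1
  C <- n_channels(co)
  freqs <- (0:(nb - 1)) * co$sfreq / n_times(co)
  cps <- lapply(1:3, function(i) {
    structure(list(model_id = "mA", layer_id = "pointwise_conv",
                   filter = i, class_y = 0L,
                   sample_ids = which(co$labels == 0)[1:4],
                   scores = rep(1, 4), k = 4L, mean_map = rnorm(24),
                   mean_freq_rel = rel_fun(C, nb, freqs),
                   freqs = freqs), class = "concept")
  })
  list(cohort = co, concepts = cps, freqs = freqs, C = C, nb = nb)
}

test_that("relevance percentages are normalized to total positive relevance", {
  fx <- view_fixture(function(C, nb, f) matrix(abs(rnorm(C * nb)), C, nb))
  out <- psd_relevance_curves(fx$concepts, fx$cohort, fmax = 64)
  expect_equal(sum(out$relevance_pct) + out$remainder_pct, 100,
               tolerance = 1e-9)
  expect_equal(length(out$psd), sum(fx$freqs <= 64))
})

test_that("a pure-tone cluster peaks at the tone's PSD bin", {
  fx <- view_fixture(function(C, nb, f) matrix(1, C, nb), seed = 51)
  # the planted class-0 signal is 10 Hz on left temporal channels
  out <- psd_relevance_curves(fx$concepts, fx$cohort, fmax = 45)
  t7 <- which(fx$cohort$channels == "T7")
  psd_t7 <- crpeeg:::mean_periodogram(fx$cohort,
                                      fx$concepts[[1]]$sample_ids)[t7, ]
  pk <- fx$freqs[which.max(psd_t7)]
  expect_gte(pk, 8); expect_lt(pk, 12)
})

test_that("band topography scales power per band but never the relevance", {
  fx <- view_fixture(function(C, nb, f) {
    m <- matrix(0, C, nb); m[2, which.min(abs(f - 10))] <- 4; m
  }, seed = 52)
  bt <- band_topo(fx$concepts, fx$cohort)
  # per band, scaled power has cross-channel mean 1
  for (b in colnames(bt$power))
    if (any(bt$power[, b] > 0))
      expect_equal(mean(bt$power[, b]), 1, tolerance = 1e-9)
  # relevance passes through unscaled: planted 4 in the alpha band
  expect_equal(bt$relevance[2, "alpha"], 4)
  expect_equal(sum(bt$relevance) - bt$relevance[2, "alpha"], 0)
  expect_equal(rownames(bt$positions), fx$cohort$channels)
})

test_that("all-negative relevance produces zero positive-only views", {
  fx <- view_fixture(function(C, nb, f) matrix(-1, C, nb), seed = 53)
  bt <- band_topo(fx$concepts, fx$cohort)
  expect_true(all(bt$relevance == 0))
  regions <- default_regions(fx$cohort$channels)
  fg <- functional_grouping(fx$concepts, regions,
                            channels = fx$cohort$channels)
  expect_true(all(fg == 0))
  # absolute-value variant sees the magnitude instead
  fga <- functional_grouping(fx$concepts, regions,
                             channels = fx$cohort$channels, use_abs = TRUE)
  expect_true(all(fga > 0))
})

test_that("region relevance is dominated by the loaded region", {
  fx <- view_fixture(function(C, nb, f) {
    m <- matrix(0, C, nb)
    m[c(7, 9, 11), f >= 8 & f < 12] <- 2     # FC5, T7, CP5 (left temporal)
    m
  }, seed = 54)
  regions <- default_regions(fx$cohort$channels)
  fg <- functional_grouping(fx$concepts, regions,
                            channels = fx$cohort$channels)
  expect_gt(fg["temporal_left", "alpha"], fg["temporal_right", "alpha"])
  expect_true(all(fg["temporal_left", "alpha"] >= fg[, "alpha"]))
})

test_that("views are invariant to concept order within a cluster", {
  fx <- view_fixture(function(C, nb, f) matrix(runif(C * nb), C, nb),
                     seed = 55)
  a <- psd_relevance_curves(fx$concepts, fx$cohort)
  b <- psd_relevance_curves(rev(fx$concepts), fx$cohort)
  expect_equal(a, b, tolerance = 1e-12)
  regions <- default_regions(fx$cohort$channels)
  expect_equal(functional_grouping(fx$concepts, regions,
                                   channels = fx$cohort$channels),
               functional_grouping(rev(fx$concepts), regions,
                                   channels = fx$cohort$channels),
               tolerance = 1e-12)
})

test_that("unknown channels and empty regions are rejected", {
  expect_error(channel_positions(c("C3", "XX")), "XX")
  expect_error(crpeeg:::validate_regions(list(left = character(0)), c("C3")),
               "empty|not in montage")
  expect_error(crpeeg:::validate_regions(list(a = "C3", b = "C3"), c("C3", "C4")),
               "disjoint")
})
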