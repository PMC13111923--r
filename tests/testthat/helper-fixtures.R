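# Shared fixtures. Expensive fixtures (LOO-trained cohorts) are built
# lazily once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

montage16 <- function() montage_16()

# lateralized 10 Hz cohort with artifacts, for module-level tests
lateralized_config <- function(n_subjects = 6, n_epochs_per_class = 10,
                               amplitude = 6, seed = 11) {
  cohort_lateralized_alpha(n_subjects = n_subjects,
                           n_epochs_per_class = n_epochs_per_class,
                           amplitude = amplitude, freq_jitter = 1,
                           seed = seed, artifacts = TRUE)
}

# noise-free single-tone config for exact spectral checks
tone_config <- function(channel = "C3", center = 10, bandwidth = 0,
                        n_epochs_per_class = 3, seed = 4) {
  cohort_config(
    n_subjects = 1, n_epochs_per_class = n_epochs_per_class,
    signal_spec = list(list(class = 0, center = center,
                            bandwidth = bandwidth, channels = channel,
                            amplitude = 1, envelope = "constant")),
    noise_spec = list(exponent = 1, amplitude = 0),
    artifact_spec = list(),
    subject_variability = list(amp_jitter = 0, freq_jitter = 0),
    seed = seed)
}

# the scaled-down recovery experiment shared by the acceptance checks:
# 6 subjects, 16 channels, LOO-CV with 200 training epochs
recovery_fixture <- function() {
  memo("recovery", {
    cfg <- cohort_recovery()
    cohort <- generate_cohort(cfg)
    prep <- batch_standardize(common_average_reference(cohort), 128)
    runs <- train_loo(prep, seed_mode = "unique", n_reps = 1,
                      epochs = 200, batch_size = 128, base_seed = 101)
    list(config = cfg, cohort = cohort, prep = prep, runs = runs)
  })
}

# per-model filter concepts on the recovery fixture (used by the
# clustering checks)
recovery_concepts <- function() {
  memo("recovery_concepts", {
    fx <- recovery_fixture()
    concepts <- list()
    for (rn in fx$runs) {
      te_idx <- which(fx$prep$subjects == rn$subject)
      te <- subset_epochs(fx$prep, te_idx)
      cps <- concepts_for_model(rn$model, te,
                                model_id = paste0("m_", rn$subject))
      for (cp in cps) {
        cp$sample_ids <- te_idx[cp$sample_ids]
        concepts[[length(concepts) + 1L]] <- cp
      }
    }
    concepts
  })
}

# small random inputs for engine-level tests
rand_epochs <- function(n = 4, C = 8, Tn = 96, seed = 1) {
  set.seed(seed)
  array(rnorm(n * C * Tn), c(n, C, Tn))
}
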