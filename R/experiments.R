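# Frozen study conditions for the package's validation experiments.
# Tests and the acceptance script both build their cohorts from these
# constructors, so the experiments are reproducible from the package
# alone.

#' Validation cohort configurations
#'
#' Constructors for the synthetic study conditions used by the package's
#' validation experiments (see the methods vignette for the rationale
#' behind each choice):
#'
#' * `montage_16()`: a 16-channel 10-20 montage covering frontal,
#'   temporal and occipital left/right groups.
#' * `cohort_lateralized_alpha()`: binary cohort with a 10 Hz tone on
#'   the left temporal group for class 0 and its right mirror for
#'   class 1, on 1/f background noise.
#' * `cohort_recovery()`: the scaled-down recovery experiment — 6
#'   subjects, clearly separable lateralized alpha regime, no artifact
#'   sources.
#' * `cohort_two_concept()`: each class an equal mixture of two
#'   alternative signatures in distinct band-by-hemisphere cells
#'   (sustained 10 Hz temporal vs. burst 13 Hz frontal; both below the Nyquist rate of the pooled activation maps), for the
#'   concept-clustering experiment.
#' * `cohort_blink()`: loud frontal blink source on top of a weak
#'   lateralized signal, for the ICA relevance experiment.
#'
#' @param n_subjects,n_epochs_per_class cohort size.
#' @param amplitude planted tone amplitude, microvolt.
#' @param freq_jitter per-subject centre-frequency jitter, Hz.
#' @param seed cohort RNG seed.
#' @param artifacts include the default blink + mains sources.
#' @return a [cohort_config()] (or a character vector for
#'   `montage_16()`).
#' @name validation_cohorts
NULL

#' @rdname validation_cohorts
#' @export
montage_16 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "FC5", "FC6",
    "T7", "T8", "CP5", "CP6", "PO3", "PO4", "O1", "O2")
}

#' @rdname validation_cohorts
#' @export
cohort_lateralized_alpha <- function(n_subjects = 6,
                                     n_epochs_per_class = 10,
                                     amplitude = 14, freq_jitter = 0.5,
                                     noise_amplitude = 10,
                                     seed = 11, artifacts = FALSE) {
  mont <- montage_16()
  art <- if (artifacts)
    list(list(kind = "blink", channels = c("Fp1", "Fp2"), rate = 0.3,
              amplitude = 40),
         list(kind = "line_noise", channels = mont, freq = 50,
              amplitude = 2))
  else list()
  cohort_config(
    n_subjects = n_subjects, n_epochs_per_class = n_epochs_per_class,
    montage = mont,
    signal_spec = list(
      list(class = 0, center = 10, bandwidth = 2,
           channels = c("T7", "FC5", "CP5"), amplitude = amplitude,
           envelope = "constant"),
      list(class = 1, center = 10, bandwidth = 2,
           channels = c("T8", "FC6", "CP6"), amplitude = amplitude,
           envelope = "constant")),
    noise_spec = list(exponent = 1, amplitude = noise_amplitude),
    artifact_spec = art,
    subject_variability = list(amp_jitter = 0.2,
                               freq_jitter = freq_jitter),
    seed = seed)
}

#' @rdname validation_cohorts
#' @export
cohort_recovery <- function(seed = 11) {
  cohort_lateralized_alpha(n_subjects = 6, n_epochs_per_class = 8,
                           amplitude = 24, freq_jitter = 0.5,
                           noise_amplitude = 3,
                           seed = seed, artifacts = FALSE)
}

#' @rdname validation_cohorts
#' @export
cohort_two_concept <- function(seed = 13, n_subjects = 6,
                               n_epochs_per_class = 12) {
  mont <- montage_16()
  cohort_config(
    n_subjects = n_subjects, n_epochs_per_class = n_epochs_per_class,
    montage = mont,
    signal_spec = list(
      list(class = 0, center = 10, bandwidth = 0, phase = 0,
           channels = c("T7", "FC5", "CP5"), amplitude = 20,
           envelope = "gauss_burst", burst_center = 0.75, prob = 0.5),
      list(class = 0, center = 13, bandwidth = 0, phase = 0,
           channels = c("F4", "F8", "FC6"), amplitude = 20,
           envelope = "gauss_burst", burst_center = 2.25, prob = 0.5),
      list(class = 1, center = 10, bandwidth = 0, phase = 0,
           channels = c("T8", "FC6", "CP6"), amplitude = 20,
           envelope = "gauss_burst", burst_center = 0.75, prob = 0.5),
      list(class = 1, center = 13, bandwidth = 0, phase = 0,
           channels = c("F3", "F7", "FC5"), amplitude = 20,
           envelope = "gauss_burst", burst_center = 2.25, prob = 0.5)),
    noise_spec = list(exponent = 1, amplitude = 4),
    artifact_spec = list(),
    subject_variability = list(amp_jitter = 0.2, freq_jitter = 0),
    seed = seed)
}

#' @rdname validation_cohorts
#' @export
cohort_blink <- function(seed = 17) {
  mont <- montage_16()
  cohort_config(
    n_subjects = 2, n_epochs_per_class = 15, montage = mont,
    signal_spec = list(
      list(class = 0, center = 10, bandwidth = 1,
           channels = c("T7", "FC5", "CP5"), amplitude = 8),
      list(class = 1, center = 10, bandwidth = 1,
           channels = c("T8", "FC6", "CP6"), amplitude = 8)),
    noise_spec = list(exponent = 1, amplitude = 10),
    artifact_spec = list(
      list(kind = "blink", channels = c("Fp1", "Fp2"), rate = 1,
           amplitude = 80)),
    subject_variability = list(amp_jitter = 0.1, freq_jitter = 0.5),
    seed = seed)
}

#' Cohort of literally duplicated subjects
#'
#' Replicates one generated subject's epochs under several subject ids,
#' so that every LOO fold trains on identical data: in the same-seed
#' regime all fold models are then bit-identical, the reference point of
#' the stochastic-variance analysis.
#'
#' @param n_subjects number of duplicates.
#' @param n_epochs_per_class epochs per class in the template subject.
#' @param seed template cohort seed.
#' @return [epoch_set()]
#' @export
duplicated_cohort <- function(n_subjects = 3, n_epochs_per_class = 12,
                              seed = 19) {
  cfg <- cohort_lateralized_alpha(n_subjects = 1,
                                  n_epochs_per_class = n_epochs_per_class,
                                  seed = seed)
  one <- generate_cohort(cfg)
  n1 <- n_epochs(one)
  data <- array(0, c(n1 * n_subjects, n_channels(one), n_times(one)))
  labels <- integer(0); subjects <- character(0)
  for (s in seq_len(n_subjects)) {
    data[((s - 1) * n1 + 1):(s * n1), , ] <- one$data
    labels <- c(labels, one$labels)
    subjects <- c(subjects, rep(sprintf("D%02d", s), n1))
  }
  epoch_set(data, labels, subjects, one$channels, one$sfreq)
}

#' Stochastic-variance consistency experiment
#'
#' Repeats a scaled-down LOO-CV on a duplicated-subject cohort under the
#' unique-seed and same-seed regimes and collects each model's per-class
#' mean activation maps, ready for [consistency_report()].
#'
#' @param n_reps repetitions per condition.
#' @param base_seed seed from which cohort and fold seeds derive.
#' @param train_epochs training epochs per fold.
#' @return named list (`unique`, `same`) of repetition lists.
#' @export
run_consistency_experiment <- function(n_reps = 5, base_seed = 23,
                                       train_epochs = 40) {
  co <- duplicated_cohort(n_epochs_per_class = 8, seed = base_seed)
  prep <- batch_standardize(common_average_reference(co), 128)
  out <- list()
  for (cond in c("unique", "same")) {
    reps <- list()
    for (r in seq_len(n_reps)) {
      runs <- train_loo(prep, seed_mode = cond, n_reps = 1,
                        epochs = train_epochs, batch_size = 128,
                        base_seed = base_seed + 100 * r)
      reps[[r]] <- lapply(runs, function(rn) {
        te <- subset_epochs(prep, prep$subjects == rn$subject)
        model_concept_maps(rn$model, te)
      })
    }
    out[[cond]] <- reps
  }
  out
}
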