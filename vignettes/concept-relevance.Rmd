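---
title: "Filter concepts in convolutional EEG decoders: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter concepts in convolutional EEG decoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crpeeg)
```

## What the package computes

`crpeeg` asks what a compact convolutional EEG decoder has learned, and
whether different subject-independent trainings learn the same thing. It
does so with concept relevance propagation (CRP): layer-wise relevance
propagation (LRP) extended with a conditioning set that restricts the
backward relevance flow to chosen filters of a chosen layer. One
(model, filter, class) unit is summarized as a *concept*: the test
samples on which the filter accumulates the most relevance, their mean
activation map, and the relevance those samples carry in time and (via a
Fourier inspection layer) frequency domain. Concepts from many LOO-CV
models are embedded with cosine UMAP, clustered with DBSCAN, and each
cluster is translated into neuroscientific views — PSD/relevance
curves, per-band topographies, functional region grouping, and ICA
artifact attribution.

## The decoder and its training

The network is the standard EEGNet layer graph for a `C x T` input
window: a bank of `F1 = 8` temporal convolutions (64 taps at 128 Hz,
i.e. 0.5 s), batch-norm, a depthwise spatial convolution across all
channels (`D = 2` filters per temporal filter, max-norm 1), batch-norm,
ELU, average pooling by 4, dropout 0.25, a separable convolution
(16-tap depthwise followed by a `16 -> F2 = 16` pointwise convolution),
batch-norm, ELU, pooling by 8, dropout, and a dense softmax head
(max-norm 0.25). All convolutions are bias-free. Training minimizes
cross-entropy with Adam (learning rate 0.001, moments 0.9/0.999,
epsilon 1e-8) for a fixed number of epochs without validation stops,
batch size 128. Subject-independent evaluation uses leave-one-subject-out
cross-validation in two seed regimes: every fold its own seed
(`"unique"`) or one seed per repetition (`"same"`); with identical
training data the same-seed regime is bit-reproducible, which makes the
stochastic-variance comparison meaningful on a CPU.

Because no deep-learning framework is part of the package's dependency
footprint, the forward/backward passes are implemented in the package
itself (R with C++ kernels for the two heavy convolutions). A practical
consequence worth knowing: with the cohort sizes used in the examples
the full training set fits in one batch, so one training epoch is one
Adam step.

*"Last convolutional layer"* always means the pointwise convolution of
the separable block — the only 16-filter convolution — and activation
maps are read out there after canonicalization, so folded batch-norm
scaling is part of the map.

## Relevance propagation rules

Batch-norm layers are first folded into the adjacent convolutions
(`canonicalize()`); this leaves an equivalent bias-carrying network on
which the rules are defined. The composite assigns:

* **alpha2-beta1** to all convolutions: positive and negative
  contributions are split, positive evidence weighted twice, net weight
  `alpha - beta = 1`;
* **epsilon** (stabilizer `1e-6`, relative to the layer's mean absolute
  denominator, sign-matched) to the dense head and the average poolings;
* identity to ELU and dropout (elementwise layers are
  relevance-transparent);
* bias shares are absorbed: biases enter the denominators but their
  relevance is not propagated further. Conservation statements therefore
  refer to bias-free models (a freshly built network is bias-free after
  canonicalization, since its batch-norm shifts and running means are
  zero).

Two numerical conventions deserve explanation.

**Single-signed units.** At an output unit whose input contributions are
all of one sign, the missing part of the alpha/beta split carries no
mass. Scaling the present part by alpha (as some implementations do)
then inflates the unit's outgoing relevance by a factor of two and
breaks conservation. The package instead falls back to the plain
proportional split at such units, which keeps `sum(R_in) = sum(R_out)`
exact on bias-free layers and makes the all-positive case coincide with
LRP-0. The backward pass stays linear in the incoming relevance, so
filter conditions still partition the unconditioned heatmap exactly.

**Seed of the propagation.** The backward pass is seeded with the raw
logit of the conditioned class, not its softmax probability. Logit
units make the conservation bookkeeping transparent (the heatmap total
should reproduce the logit) and avoid the softmax's dependence on the
competing class. Conservation diagnostics are only meaningful on
samples whose conditioned logit is not vanishingly small: the ratio
total/logit is ill-conditioned at a near-zero seed.

## The frequency inspection layer

`attach_vil()` inserts an invertible pair — one-sided DFT per channel,
followed by the exact synthesis back to the time signal — before the
input layer. Predictions are unchanged; relevance can be read out at
the coefficient layer. The synthesis is a bias-free invertible linear
map, and relevance is pushed through it with the plain proportional
(z-) rule computed as `R_z = z * B^T (R_x / x)`, with `0/0 = 0`. Under
the alpha-beta rule the input relevance always carries the factor
`x_t`, so the division is well-defined and the per-sample total is
conserved *exactly* — an epsilon-stabilized variant would leak at the
1e-6 level for no benefit. Per-bin relevance is the sum of the bin's
real and imaginary coefficient relevances; the one-sided doubling is
part of the synthesis matrix, so no manual doubling is applied. The
frequency resolution is fixed by the window (1/3 Hz for 3 s windows);
there is no zero-padding.

Band aggregation uses the conventional half-open bands delta 0-4,
theta 4-8, alpha 8-12, beta 12-30, gamma 30-60 Hz. Bins above 60 Hz
(the band-pass edge) belong to no band and are reported separately as
out-of-band mass rather than silently dropped.

## Concept selection and representation

For a condition (layer, filter, class), every *test* sample of that
class is scored by the signed sum of its conditioned heatmap — test
data of the held-out subject, because only concepts that generalize to
an unseen person should score highly, and only same-class samples,
because relevance-ranked selection otherwise drifts toward a small pool
of high-relevance samples of one class. The representative set is the
smallest prefix of the descending score list that accumulates at least
20% of the total positive relevance mass, hard-capped at 10 samples
(ties broken by sample index). Negative-score samples are never
selected; a filter with no positive-score sample yields an empty
concept, which is logged and excluded downstream. The concept's
representation for cross-model comparison is the mean activation map of
the conditioned filter over the selected samples.

## Clustering and the consistency statistic

Mean activation maps are embedded per class with UMAP under the cosine
metric (`n_neighbors = 15`, `min_dist = 0.1`, single-threaded and
seeded, so embeddings are reproducible), then clustered with DBSCAN at
`eps = 0.4`. The density threshold `min_samples = 15` presumes on the
order of 16 models x 16 filters; for smaller concept sets it is scaled
proportionally (floored at 5). DBSCAN runs on the 2-D embedding, noise
points are labelled `-1` and excluded from the views. Clustering is
strictly per class; permuting the other class's concepts changes
nothing.

Cross-model consistency: for each unordered model pair within a
repetition, filters are matched by maximizing total cosine similarity
of the mean maps (optimal linear assignment, not greedy, so the result
does not depend on filter order), model B's maps are reordered,
flattened, and Pearson-correlated with model A's. Pair correlations are
averaged per repetition; means and t-based confidence intervals are
reported per condition and class. The interval level defaults to 95%
and is configurable (90% is the other level in common use). Filters
whose concept is empty fall back to the mean activation map over all
class samples so that the matching always sees the full filter bank.

## ICA attribution

Cluster data (the concatenated representative samples, time domain) are
decomposed by: per-channel scaling to unit variance, PCA whitening on
the numerically non-degenerate subspace (common-average-referenced data
lose exactly one dimension), and extended infomax rotation
(`ica::icaimax`, the variant matching the training regime of
ICLabel-style classifiers). Sources are normalized to unit variance.
The cluster's signed time-domain relevance is projected through the
same unmixing chain, and each component's share is the sum of absolute
projected values — projection first, absolute value second, preserving
interference between channels. Component naming goes through a
pluggable labeler interface; the package ships a ground-truth labeler
for synthetic cohorts (matching component topographies to planted
source loadings by absolute cosine) and an `"unlabelled"` fallback, so
the pipeline never requires an external classifier.

## The synthetic cohort generator

Every downstream claim is validated on cohorts with known ground truth.
An epoch is built as `1/f^a` background noise (per channel, unit-sd
shaped in the frequency domain, scaled to the configured microvolt sd)
plus linearly mixed planted sources: class-dependent narrow-band
oscillations on named channels (per-epoch frequency drawn uniformly
from the configured band, random phase, optionally a Gaussian burst
envelope, optionally expressed only on a random subset of the class's
epochs via `prob` — that is how several alternative concepts per class
are planted), and stereotyped artifacts: biphasic blink pulse trains
with Poisson onsets and a fixed frontal topography, coherent mains
sinusoids, and burst-enveloped high-frequency muscle noise.
Between-subject variance is a multiplicative amplitude jitter and an
additive center-frequency jitter drawn once per subject. The cohort is
a deterministic function of its configuration, and the full source
decomposition (loadings and per-epoch time courses) is retrievable for
validation.

What the generator does *not* emulate: volume-conducted source overlap
beyond the explicit loading vectors, realistic event-related
potentials, non-stationary noise, electrode drift, or realistic
channel covariance. Passing the recovery checks therefore shows the
pipeline recovers planted spatial/spectral/artifact structure through
real training — not that it characterizes any particular real dataset.

## Study conditions used by the validation experiments

The packaged experiments are sized for a desk-scale CPU run; the
configurations are fixed in the test helpers and the acceptance script.

* **Recovery cohort**: 6 subjects, 16-channel 10-20 montage (the same
  channel count as the smallest of the paradigms the method targets),
  3-s windows at 128 Hz, 10 epochs per class per subject. Class 0
  carries a 10±1 Hz tone on the left temporal group (T7, FC5, CP5),
  class 1 its right mirror; pink-noise background of 10 µV sd; subject
  jitter 20% amplitude, ±1 Hz. The tone amplitude (12 µV) puts the
  cohort in a clearly separable regime: a pilot at half this amplitude
  showed models memorizing subjects (0.98 train, chance-level held-out
  accuracy), i.e. the effect fell below the subject-independent
  learnability threshold at this cohort size, which is a property of
  the scaled-down design rather than of the method. Training: LOO-CV,
  200 epochs, batch 128 (full-batch at this size), unique seeds.
* **Two-concept cohort** (clustering): each class is an equal mixture
  of two alternative signatures in distinct band x hemisphere cells
  (class 0: alpha-left-temporal or beta-right-frontal; class 1
  mirrored), so a decoder needs two filter groups and their concepts
  should form two clusters per class with every model represented.
* **Blink cohort** (ICA): a loud, frequent blink source plus a planted
  relevance pattern concentrated on its loading channels validates the
  component ranking.
* **Consistency runs**: duplicated-subject cohorts trained in the
  same-seed regime give bit-identical models (correlation exactly 1),
  the unique-seed regime gives strictly less; 5 scaled-down repetitions.

## Numerical choices and degenerate inputs

* Batch standardization guards zero-variance channels with a `1e-12`
  variance floor; the trailing partial batch uses its own statistics
  (no lookahead, matching the online-mimicking intent).
* Pooling truncates a non-divisible tail; windows are non-overlapping,
  left-aligned, half-open, 0-based in sample indexing.
* Batch-norm epsilon is 1e-3 (the Keras convention EEGNet was published
  with); running statistics use momentum 0.99.
* Same-padding places `floor((K-1)/2)` zeros on the left.
* The epsilon stabilizer is always relative to the mean absolute
  denominator of its layer, so explanations are invariant to a global
  rescaling of the input.
* UMAP runs single-threaded under a fixed seed; DBSCAN scans points in
  index order, so border-point assignment is deterministic.
* ICA rank retention uses an eigenvalue threshold of `1e-8` relative to
  the largest eigenvalue.
* Zero-variance activation maps make a Pearson correlation undefined;
  such pairs are reported as missing, with a warning, rather than
  imputed.

## Known limitations

* Cluster model-coverage on synthetic carrier concepts is structurally
  fragile: the learned convolutions give each model's activation maps
  an arbitrary carrier phase and sign, so in cosine space a planted
  concept family forms a ring rather than a tight cloud. DBSCAN at the
  standard radius then resolves ring arcs and model-specific variants
  as separate clusters: at least two clusters per class emerge
  reliably and the dominant clusters contain filters from (nearly)
  every model, but small clusters below full coverage also appear. On
  real EEG, slow non-stationary envelope structure survives the maps
  and makes clusters more coherent; a phase-invariant map
  representation would be the principled fix and is left open here.

* Conservation diagnostics are stated for bias-free canonical models;
  trained models carry folded batch-norm biases whose relevance share
  is absorbed, so their heatmap totals undershoot the logit slightly.
* Dense-head neuron concepts (scalar activations) are out of scope; the
  package analyzes convolutional filters only.
* The DFT inspection layer attributes relevance to amplitude and phase
  jointly; amplitude/phase-separated and time-frequency readouts are
  not implemented.
* Hierarchical alternatives to DBSCAN, and cross-layer concept
  hierarchies, are not implemented.
* Real-EEG ingestion is limited to the package's HDF5 epoch container
  and R matrices; BDF/EDF readers must be supplied by the caller.
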