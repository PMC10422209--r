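---
title: "Scoring dementia severity from MRI slices by supervised contrastive learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dementia severity from MRI slices by supervised contrastive learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Clinical dementia rating instruments (MMSE, CDR, FAQ and relatives) are
administered by people to people, which makes them vulnerable to rater and
patient subjectivity, and their coarse ordinal ranges stack many patients on
a handful of values. Structural MRI sees the anatomical substrate of the
disease directly: progressive cortical atrophy and ventricular enlargement.
`odssmri` implements an image-driven severity scale built on that signal.

The model has three parts.

1. **A weight-sharing residual encoder.** A 2D brain slice passes through a
   small residual convolutional network (3x3 stem, residual blocks with
   identity or 1x1-projection skips, average-pool downsampling), global
   average pooling produces a `feature_dim`-dimensional vector (default
   1024), and a projection head maps it to a `projection_dim`-dimensional
   embedding (default 128) which is L2-normalized onto the unit
   hypersphere. The "twin channel" or Siamese structure is realized as one
   parameter set applied to every input, so the two channels cannot
   disagree by construction.

2. **Supervised contrastive training.** Each step draws N images, copies
   the batch into the two channels (2N samples), and minimizes

   L_i = -(1/|P(i)|) * sum_{j in P(i)} log[ exp(z_i.z_j / tau) /
         sum_{k != i} exp(z_i.z_k / tau) ],

   where P(i) is the set of same-label anchors j != i and tau is a
   temperature (default 0.07). Same-stage images are pulled together on the
   hypersphere, different stages pushed apart. The batch loss is the sum of
   L_i over all 2N anchors; optimization uses the mean (identical gradient
   direction, step size independent of batch size).

3. **Cosine scoring against a healthy panel.** After training, five
   distinct normal-control (NC) subjects are drawn from the training split;
   one image of each is embedded as the baseline panel. A test image's
   score is the mean over the panel of `100 * cos(z_test, z_base)` — for
   unit vectors, one hundred times the dot product. Healthy brains score
   near 100; increasing atrophy moves the embedding away from the healthy
   cluster and the score falls. Averaging five baseline individuals damps
   the residual variation between healthy subjects.

## Interpretation choices in the loss and score

Two printed formulas in the literature on this construction require an
interpretation, and the package documents the one it takes:

* The positive-pair indicator: positives are the **same-label** anchors
  (`j != i`, `y_j = y_i`). A version with the inequality inverted
  contradicts the definition of supervised contrastive learning and
  collapses in the uniform-embedding closed form, so the package treats it
  as a typographical slip. The normalizer is `1/|P(i)|`, the number of
  positives of the anchor (the "L_out" variant).
* The cosine denominator is the standard product of norms. On the unit
  hypersphere every dimensionally sensible reading coincides with the dot
  product, so the choice is inert for normalized embeddings.

Negative scores are possible (antipodal embeddings give -100) and are
deliberately not clamped: a strongly negative score for a severe case is
informative, and clamping would hide pathological training.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `temperature` | 0.07 | SupCon temperature; smaller sharpens the softmax over negatives. The common SupCon default; not specified by the method's source. |
| `batch_size` | 16 | images N per step; the loss sees 2N. Larger batches give more negatives per anchor but cost memory. |
| `epochs` | 8 | passes over the training split; desk-scale CPU training of the small backbone takes ~10 s/epoch at 288 images of 64x64. |
| `learning_rate` | 1e-3 | Adam step size. |
| `feature_dim` | 1024 | pooled feature width. |
| `projection_dim` | 128 | embedding width. |
| `augmentation` | "none" | the duplicated batch is an exact copy; `"light"` flips the copy horizontally with probability 1/2. Exact copies make each anchor's duplicate a trivial positive, which is why the flip option exists; neither mode is claimed to be the original method's. |

The projection head is a **single linear layer without bias**. The head is
described in the source material as an MLP with ReLU yet with exactly one
layer; a trailing ReLU would confine embeddings to the nonnegative orthant
(half the hypersphere), so the single-layer head omits it. A two-layer
linear-ReLU-linear head (SimCLR-style) is available via
`projection_layers = 2`. The bias-free default makes the embedding
invariant to positive rescaling of the feature vector.

The backbone depth is configurable (`"small"`: stem + 2 residual stages,
for CPU-scale experiments; `"standard"`: 4 stages of 2 blocks, an
18-layer-class network) because the original description names only
"ResNet" without a depth, and the input resolution is free because pooling
is adaptive.

## The phantom generator: what it emulates, what it does not

Real cohorts for this task are access-controlled, so the package generates
**atrophy phantoms**: elliptical "brains" with a bright cortical band that
thins and a central two-lobed dark "ventricle" whose area grows
monotonically with a latent severity s in [0, 1]. Stages map to disjoint
severity intervals (NC [0, 0.15], MCI [0.35, 0.55], AD [0.75, 1.00]); each
subject draws one s uniformly from its stage interval plus a clipped
Gaussian subject effect (sd 0.05), and each of its images adds truncated
Gaussian pixel noise (sd 0.03). Subjects are split 80/20 into train/test by
subject, never by image. Defaults (40 subjects per stage, 3 images each,
64x64 pixels) keep end-to-end CPU training under two minutes.

The interval gaps make stages separable *by construction*. That is the
point — the generator provides a ground truth where the method must succeed
— but it also bounds what a green test establishes: recovery of a monotone,
separable atrophy signal under additive noise. The phantoms have no MRI
physics, no bias fields, no registration error, no overlapping severity
distributions, and no 3D structure, so phantom results say nothing about
performance on real scanner data. Where image counts per subject are
unequal in real cohorts, the generator uses a constant count; the class
ratios of a real cohort can be emulated by generating stages separately.

Chosen realism defaults (noise sd 0.03 on a [0, 1] intensity scale, subject
effect sd 0.05 against stage interval widths of 0.15-0.25) follow the usual
phantom-study convention of a few percent pixel noise and within-stage
biological variability smaller than the between-stage separation.

## Numerical choices

* **Loss stability.** The per-anchor log-sum-exp over negatives is computed
  max-shifted; the vectorized loss is tested against an explicit
  double-loop oracle at 1e-6.
* **Gradients.** Backpropagation through convolutions (im2col), pooling,
  residual sums, global average pooling, the projection head and the L2
  normalization is hand-written and verified against central finite
  differences.
* **Anchors without positives** cannot occur in duplicated batches (each
  copy is its anchor's positive); the standalone loss treats them as an
  error by default and excludes them with a warning in lenient mode, which
  the training loop uses.
* **Threshold selection** for the two- and three-class tables maximizes
  accuracy by exhaustive scan over midpoints between sorted unique scores
  (padded beyond the extremes so all-one-class solutions are reachable);
  ties break toward higher sensitivity, then the lower cut. Selection
  defaults to the evaluated set itself, with an optional separate selection
  set — published tables rarely state which convention was used, so both
  exist and neither is claimed.
* **Quantiles** use linear interpolation between order statistics (R type
  7); the quartile deviation depends on this rule, so it is fixed and
  documented. The **variation ratio** requires a mode, hence a
  discretization: normalized scores are rounded to 2 decimals first.
* **Stage coding** is NC = 0, MCI = 1, AD = 2. Pearson depends on the
  spacing; Spearman is invariant to any monotone recoding. Signed
  correlations are stored; displays also give |r| x 100 as a percentage.
* **Degenerate inputs**: constant images normalize to all zeros; constant
  scores yield zero dispersion; a zero vector after projection raises an
  error rather than returning a non-unit embedding.
* **Welch vs pooled t-test**: the default is the unequal-variance Welch
  form; the pooled Student form is one flag away (`var_equal = TRUE`)
  because sources that print "Student's t-test" rarely say which they ran.
* **Seeding.** Every stochastic component draws its seed from one global
  seed via a named-substream hash (`derive_seed`), so any stage can be
  re-run independently and the full pipeline is byte-reproducible.

## Worked example

```{r, eval = FALSE}
library(odssmri)

data <- generate_phantom_dataset(phantom_config(seed = 7))
fit <- odss_fit(data,
                encoder = encoder_config(seed = 5),
                training = train_config(epochs = 8, seed = 11),
                panel_seed = 13)
summary(fit)
plot(fit)
```

On this seeded phantom cohort the held-out evaluation reports a strongly
negative score-stage correlation and well-separated stage means; the exact
numbers are computed by the test suite and by `scripts/acceptance.R`, not
quoted here.

## Known limitations

* The phantom world is easier than clinical data; accuracy-1.0 results on
  phantoms are a correctness check, not a clinical claim.
* Training is plain R + BLAS on CPU; it is sized for 64x64 phantoms, not
  for full-resolution cohort training.
* The NIfTI reader covers the NIfTI-1 single-file subset the package
  writes and reads (five datatypes, slope/intercept scaling, both byte
  orders); it is not a general neuroimaging I/O library.
* Per-image scoring is the default; per-subject aggregation is provided
  (`per_subject = TRUE`) but reporting conventions differ across studies.
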