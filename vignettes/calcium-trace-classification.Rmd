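---
title: "Classifying single-cell calcium traces: models, simulation and explainability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying single-cell calcium traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcitrace)
```

## The problem

Ex vivo calcium imaging of tissue slices expressing a genetically encoded
indicator (GCaMP) yields one fluorescence time series per cell. In a
receptor-mutant model — here an inactivating, misfolding mutation of the
luteinizing hormone receptor (LHR), with heterozygous control (HET),
homozygous mutant (HOM), and pharmacological-chaperone-treated mutant
(HOM_TREATED) animals — each cell's trace reflects both its spontaneous
("basal") calcium dynamics and its response to bath-applied ligand (LH).
Population statistics (mean peaks, AUC) summarize group differences, but
they discard the single-cell structure. `calcitrace` treats each trace as a
high-dimensional vector (1500 frames at 2 Hz: 5 min basal, 3 min LH, washout)
and provides the full analysis chain: simulation, quantification, embedding
and clustering, supervised classification with a feature-learning network,
transfer evaluation of treated cells, and saliency-based explanation.

## The synthetic cohort generator

Real recordings are not required: `generate_cohort()` simulates labelled
cohorts with the statistical structure the analysis assumes. Each cell is

* a **basal component** — one sinusoid with per-cell random frequency
  (uniform in a group-specific band, in Hz) and phase, a Gaussian
  random-walk drift scaled to a terminal SD, and white noise; plus
* for Bernoulli-chosen **responders**, a **ligand response** — a saturating
  rise `A(1 - exp(-(t - t0)/tau_rise))` beginning `latency` seconds after
  ligand onset, a plateau through the end of application, and an
  exponential washout decay.

This is deliberately phenomenological: it is the simplest process that
reproduces heterogeneous spontaneous signatures, graded response
amplitudes, latency spread, and inactive-cell fractions. It does not model
biophysics (no IP3/store dynamics, no bursting, no photobleaching), no
spatial structure and no animal-level random effects beyond round-robin
animal ids — so passing tests demonstrate that the *analysis chain* behaves
correctly under controlled conditions, not that it will reach the same
accuracy on real recordings.

### Default (study-calibrated) conditions

`default_cohort_config()` freezes per-sex defaults calibrated once against
the printed population summaries of the motivating study:

* male cohort (278 HET / 175 HOM cells): group mean-trace peak targets
  0.40 and 0.23 dF/F0;
* female cohort (401 HET / 203 HOM / 391 HOM_TREATED): peak targets 0.28,
  0.055 and 0.32;
* treated cells are control-like but with delayed kinetics
  (latency 40 ± 24 s), so that ≈37% are inactive (< 0.1 dF/F0) during
  the first LH minute against ≈16.5% of controls.

Choices the summaries do not pin down were made once, as follows, and are
not tuned per analysis:

* **Amplitude/latency distributions.** Truncated Gaussians; amplitude means
  were calibrated numerically (five generated cohorts, n as above) so the
  peak of each group's mean trace lands on its target; responder fractions
  (0.85/0.62 male, 0.85/0.25/0.88 female) encode the qualitative
  "responsive vs nearly flat vs rescued" phenotypes.
* **Kinetic phenotypes.** Male mutant cells respond more slowly
  (rise tau 28 s vs 12 s, latency 16 s vs 8 s), the "dampened but not
  abolished" male phenotype; female mutant cells are distinguished by
  response *prevalence and size*, not kinetics — their few responders have
  control-like time constants. This matters for transfer: a treated cell is
  a robust but *delayed* responder, and the control/mutant classifier must
  not have been given "late onset" as mutant evidence, or rescue would be
  invisible to it. The corresponding real-data observation is that treated
  cells cluster with controls despite delayed kinetics.
* **Basal signatures.** Control and mutant basal oscillation bands overlap
  but differ (0.01–0.08 Hz at amplitude 0.035 vs 0.05–0.14 Hz at 0.024;
  drift 0.020 vs 0.013): enough for above-chance basal-only classification,
  weak enough that full traces stay at least as informative. The monotone
  ordering (full-trace accuracy above basal-only, as in the study's
  full-trace vs basal-only comparisons) is asserted on the male cohort,
  where the response carries a kinetic signature; on the female cohort the
  two are close. Treated cells share the control basal parameters.

## Trace quantification

`normalize_df_f0()` uses `F0 =` mean raw fluorescence over the basal
window; a percentile baseline could be substituted upstream for drifting
recordings. "Total change" within a window is the **per-frame mean** of
dF/F0, so the 600-frame basal and 360-frame LH windows are directly
comparable (the raw sum is also reported); the study never states this
operational definition, so it is a documented package decision. AUC uses
trapezoidal integration with time in seconds over half-open windows
`[start, end)`; with `shared_endpoint = TRUE` the closing frame is included
so BASAL + LH + WASH partitions the whole-trace AUC exactly. A cell is
"inactive" in a window when its *maximum* dF/F0 stays below 0.1 — a single
supra-threshold transient marks a cell active. Heatmaps order cells by
descending LH-window total change with ties broken by cell id.

## Embedding and clustering

`embed_tsne()` is an exact O(n²) t-SNE: per-point Gaussian bandwidths are
calibrated by bisection to perplexity 30, similarities symmetrized,
and a Student-t 2D embedding optimized by gradient descent for 1000 steps
(seed 42 by default). The optimizer uses the standard recipe the original
implementation and scikit-learn share — early exaggeration 12 for the first
250 steps, learning rate 200, momentum 0.5 then 0.8, adaptive per-parameter
gains — none of which the study states; they are accepted defaults and
recorded in the embedding's `params`. The KL divergence against the
unexaggerated similarities is recorded every step (`embedding_kl_trace()`),
making the descent property assertable; transient increases are allowed,
but the final value must not exceed the initial one. Exact t-SNE costs
O(n²) per step and is comfortable to a few thousand cells, which covers
single-slice cohorts. UMAP is consumed from `uwot` and skipped gracefully
when unavailable.

`cluster_kmeans()` is Lloyd's algorithm exactly as classically printed:
random selection of K data points as initial centroids, assignment by
squared Euclidean distance with ties to the lowest cluster index, centroid
means, iterate until assignments stabilize; 10 restarts by default, best
inertia kept, empty clusters re-seeded from the farthest point. Whether the
original analysis used restarts is unstated; restarts only mitigate bad
initializations and leave the fixed point set unchanged. The per-iteration
inertia trace is retained so monotone descent is testable. Silhouettes
follow `s(i) = (b(i) − a(i))/max(a(i), b(i))` with singleton clusters
scored 0 (a common convention; the source is silent). Cluster composition
tables are row-normalized group fractions; purity is the row maximum.

## Classification

`stratified_split()` holds out 20% per class (rounded), seeded.
`run_baseline_suite()` fits the eight classical baselines with the
published hyperparameters. Two printed inconsistencies are resolved as
follows: the perceptron width is exposed as a parameter with default 400
(the tables' configuration) rather than 100 (the benchmark list's), and the
logistic-regression iteration cap is irrelevant under the ridge solver used
here (`glmnet` with `lambda = 1/(C·n)`, the exact equivalent of the
published C = 1 L2 objective). Inputs are raw dF/F0 by default — no
standardization is described in the source — with an optional `standardize`
flag for the scale-sensitive models. Gaussian naive Bayes is implemented
directly so the published variance smoothing (1e-9 times the largest
feature variance) is honoured.

The **feature-learning network** is the package's own implementation
(plain matrix algebra, no deep-learning framework): 1500 → 512 (ReLU,
dropout 0.5) → 128 (the `z2` pre-activation embedding, then ReLU, dropout
0.2) → softmax, cross-entropy, Adam at learning rate 0.001, batch size 32,
early stopping on validation accuracy with patience 30. The source defines
only the 80:20 split, so a stratified 10% of the *training* portion serves
as the validation set — the test set never influences stopping. `max_epochs`
defaults to 500; early stopping dominates in practice. Class encoding is
fixed (HET, HOM, HOM_TREATED in that order) so argmax ties break
deterministically toward control. Training is exactly reproducible for a
given seed on one platform; across BLAS builds, reduction order may differ
at floating-point precision.

For **basal-only** analysis, `truncate_basal()` restricts traces to the
pre-ligand frames (600 frames, 5 min); the truncated grid carries an empty
ligand window so windowed response statistics refuse to run on it.

**Transfer evaluation**: `transfer_fraction_control()` feeds cells from the
treated group — never seen in training — through the binary control/mutant
network and reports the percentage classified as control, the rescue
statistic. `project_feature_space()` embeds every cell's 128-dimensional
`z2` features with t-SNE for the corresponding visualization.

## Saliency

Grad-CAM was designed for convolutional feature maps; a dense network
needs an adaptation, and the source does not specify one. The package
default treats the first hidden layer's activations `a_k = ReLU(z1_k)` as
the feature map, weighs each unit by its class gradient
`alpha_k = ∂y_c/∂a_k`, and redistributes `alpha_k a_k` over frames through
the unit's normalized absolute input weights
`w_hat[k,t] = |W1[t,k]| / Σ_t |W1[t,k]|`, with a final ReLU and per-cell
max-normalization. An `input_gradient` variant (ReLU of gradient × input)
is available behind a flag.

The two variants have complementary blind spots, which the package's
paired simulations make explicit: weight-based redistribution highlights
frames the network reads with *large weights* (small-amplitude basal
signatures) but stays nearly flat when the class signal is carried by
large-amplitude response frames, where discrimination needs only
ordinary-sized weights; input-weighted maps do the opposite, because the
ligand transient dominates any product with the input. The saliency
localization tests therefore exercise each regime with the variant suited
to it, and a practitioner should read the two maps together. Saliency is
computed with respect to each cell's predicted class unless a target class
is given; an untrained or zeroed model returns an all-zero map with a
warning.

## Pipeline and reproducibility

`run_full()` executes the whole chain from one `run_config()`: cohort →
metrics → embeddings → K-means over K = 2…5 (on the t-SNE plane and on raw
1500-dimensional traces) → baseline suite and feature net, full-trace and
basal-only → transfer and feature-space projection → saliency → CSV tables
(and PNG figures) plus a JSON manifest. Every stochastic stage derives its
seed deterministically from the master seed and the stage name, so a rerun
with the same configuration is byte-identical. A thin command-line wrapper
(`inst/cli/calcitrace.R`, verbs `simulate`/`metrics`/`embed`/`cluster`/
`classify`/`explain`/`run-all`) exposes the same functions to shell users.

## Numerical choices and degenerate inputs

* dF/F0 normalization rejects cells with `F0 ≤ 0` by name rather than
  producing signed nonsense.
* Empty windows, empty groups, classes with fewer than two cells, `K`
  exceeding the point count, and single-cluster silhouettes are rejected
  with explicit errors.
* PCA on rank-deficient input zero-fills the second axis with a warning;
  t-SNE reduces an infeasible perplexity to `(n−1)/3` with a warning.
* K-means ties and softmax argmax ties resolve toward the lowest index.
* Cross-entropy and softmax use log-sum-exp shifting; probabilities are
  floored at 1e-12 inside logs.

## Problem sizes used in the test-suite

The packaged tests and the acceptance script run the full study at its
native cohort sizes (453 male cells, 995 female cells) for the headline
checks, and smaller paired cohorts (around 100–240 cells, sometimes on
shortened grids) for property checks where the contrast under test does not
depend on n — sizes chosen to keep the suite comfortably interactive while
leaving the tested contrasts far from their detection limits.

## Known limitations

* The generator's group differences are encoded in a handful of
  parameters; real cohorts carry slice-, animal- and cell-type-level
  structure the simulator does not attempt, so real-data accuracies will
  differ from synthetic ones.
* Exact t-SNE is quadratic in cells; beyond a few thousand cells a
  Barnes-Hut implementation should be substituted.
* The feature net runs on CPU; at the study's scale training takes tens of
  seconds, but the implementation is not intended for datasets orders of
  magnitude larger.
* Saliency for dense networks is an adaptation with documented blind spots
  (above); image-domain saliency and ROI detection are out of scope.
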