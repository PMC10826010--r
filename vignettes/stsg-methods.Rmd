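---
title: "Generating and evaluating synthetic longitudinal health data with stsg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and evaluating synthetic longitudinal health data with stsg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data model

`stsg` treats a longitudinal cohort as two coupled components under one
variable schema: a *static* table (one row per subject — the metadata) and
a *dynamic* table (one row per subject and time step, integer time index
0..T−1). All preprocessing, generation and evaluation code operates on
this pair. The time axis is deliberately index-based: the cohorts this
package targets are resampled to uniform steps before synthesis, so
wall-clock timestamps carry no extra information and are out of scope.

Preprocessing follows the conventions of clinical longitudinal pipelines:
subjects whose dynamic component misses more than a configurable number of
samples (default 30) are excluded and the remaining gaps linearly
interpolated; alternatively each missing cell can be forward-filled with
the last valid measurement, the natural choice when absence means "no
change since the last reading" (hourly ICU charting). For both fills the
boundary case is not forced by the definition; we use nearest-valid
extension (backfill a missing prefix, hold the last value over a missing
suffix), preferring to retain subjects over discarding them. Ragged
cohorts are truncated to the length of the shortest series. Categorical
variables encode to integer codes in schema-category order (deterministic
across files, unlike order-of-appearance coding) or to one-hot indicator
columns; numeric variables min–max scale to [0, 1], chosen to match the
sigmoid output layer of the generators and to mix naturally with indicator
columns. Constant columns scale to 0 and invert back to the constant.

## The three generation strategies

*A1* assumes the series themselves are not disclosive: per-subject
summaries (max, min, mean of each dynamic variable) are appended to the
metadata, a metadata-only generator is trained on the augmented table, and
each sampled row is paired with a *real* series whose actual summaries
best match the synthesized ones. *A2* additionally synthesizes the series
with a separate model and couples synthetic metadata to the synthetic
pool. *A3* generates both components jointly in one model and needs no
coupling.

The coupling objective — "as small a distance as possible" between
synthesized and actual summaries — is formalized here as a minimum-cost
assignment: Euclidean distance in summary space, solved exactly by a
Jonker–Volgenant shortest-augmenting-path algorithm (O(n·m²), optimal),
with a greedy nearest-unused alternative for very large pools. Three
choices were genuinely open and are package decisions: distances are
computed on pool-standardized summaries by default (heart-rate and
ventilation summaries differ by orders of magnitude; standardization
weighs them comparably, and a raw-space option remains); pairing is
injective (reusing one real series for many synthetic subjects would
distort downstream marginals and inflate membership-attack exposure); and
the synthesized summary columns are dropped from the coupled output by
default because they disagree slightly with the attached series —
`keep_summaries = TRUE` retains them.

## Generative backends

No neural-network framework is assumed: both adversarial backends run on
the package's own dense-network engine (manual backpropagation, Adam with
β₁ = 0.5, β₂ = 0.9, seeded bit-reproducible training). For the
piecewise-linear critics the gradient of the WGAN gradient-penalty term
with respect to the weights has a closed form (activation masks are
locally constant, exactly as reverse-mode autodiff treats them); every
gradient path is verified against central finite differences in the test
suite.

**WGAN-GP with alignment loss.** The generator loss is
$$L_G = -\,\mathbb{E}[D(G(z))] \;+\; \lambda \sum_i \sum_{j<i}
\lVert \hat r_{ij} - r_{ij}\rVert_{L1},$$
the second term penalizing the disparity between synthetic and real
intervariable Pearson correlations so that correlation structure is
optimized directly rather than only through the critic. Defaults follow
the reference schedule for this model family: 5000 epochs, batch 64,
learning rate 0.001, five critic updates per generator update, λ = 10,
gradient-penalty coefficient 10. Two points are underdetermined and fixed
as package choices: the correlation matrices are computed *per batch*
(per-epoch matrices would stale the gradient and cost memory), and they
cover *all numeric design columns* — static numerics plus every series
time point — while one-hot indicator columns are excluded, since Pearson
coefficients are defined for numeric pairs and the mixed-type association
treatment belongs to evaluation, not to a differentiable loss.

**DGAN.** A DoppelGANger-style architecture: an MLP generates the
metadata; its output is concatenated to the noise input of a recurrent
(tanh) generator at every step, which emits S consecutive records per
iteration (batch generation, T/S iterations — e.g. S = 6 gives 8
iterations on 48-step series), capturing longer-range effects than
step-per-step emission. An auxiliary critic judges the metadata alone and
a combined critic the concatenated metadata and series; both use the
gradient penalty at coefficient 10. Categoricals are label-encoded (the
model-specific requirement), scaled codes re-quantized on sampling. When S
does not divide T the series are right-padded by repeating the last sample
and trimmed after generation, so no configuration crashes. Network sizes
(two hidden layers of 128, recurrent state 128, noise dimension 32) are
exposed in the configs; the critic update ratio is 1:1 for this backend.

**Baseline resampler.** Bootstrap resampling of real subjects plus
Gaussian jitter (scale = `jitter` × per-variable SD). Its expected
behaviour is known in closed form, which makes it the end-to-end oracle of
the evaluation suite: with `jitter = 0` and n equal to the training size
it returns the training records themselves in original order, so
correlation similarity is exactly 1, autocorrelation MAE exactly 0 and
TSTR similarity exactly 1 — the theoretical optima the pipeline tests
assert. (Returning a permutation instead would break the TSTR identity,
since tree ensembles are not invariant to training-row order.)

## Evaluation methodology

Because generative models produce different assets each time they sample,
all metrics are averaged over *pseudo-cross-validation*: n_folds (default
8) equally dimensioned synthetic datasets from one trained setup, sampled
with distinct derived seeds, reported as mean ± sample SD with Welch
two-sample t-tests between strategies (fold variances visibly differ
between strategies, so the unequal-variance test is the safer default;
two identical zero-variance fold vectors are reported as p = 1 by
convention). Retraining per fold is available behind a flag; the default
trains once and samples per fold, matching the motivation (sampling
variability) at an eighth of the cost.

*Associations.* The mixed-type association matrix uses Pearson r for
numeric pairs, Cramér's V (from the χ² statistic, zero-marginal rows and
columns dropped) for categorical pairs, and the R² of regressing the
numeric feature on categorical indicators for mixed pairs. Dynamic
variables enter through their per-subject series mean (optionally the full
summary triple). Zero-variance features yield masked cells — blank, not
silently zero — and masked cells are excluded pairwise from similarity
vectors. Similarity between real and synthetic matrices is standard cosine
similarity of the stacked lower triangles; a printed variant that
normalizes by the product of vector *sums* exists in the literature of
this metric family but is unbounded, so it is provided only behind
`variant = "printed"`. Both a per-fold similarity (aggregated mean ± SD)
and a pooled similarity computed from the element-wise mean of the fold
matrices are reported; the pooled form is the primary summary, the
per-fold values feed the significance tests.

*Records.* Classifier- and distance-based metrics need one numeric vector
per subject. The representation — numeric statics, one-hot categoricals,
per-variable summary triple, then 8 evenly spaced series samples per
variable — caps the dimension independently of T while keeping both
distributional and temporal information. Whether such metrics should see
flattened subjects or individual time stamps is not standardized; subjects
are the unit of privacy and of sampling here, so flattened subjects were
chosen.

*DLA.* Five classifiers (random forest: 100 trees, Gini; kNN: 10
neighbours; decision tree: Gini; linear SVM: C = 100; MLP: hidden layers
64 + 32, relu, adam, batch 200, learning rate 0.001, 100 epochs) are
trained to separate real (0) from synthetic (1) records on a stratified
70/30 split; mean AUROC near 0.5 means indistinguishable. The MLP runs on
the package's own engine because no installed R package provides a
two-hidden-layer relu/adam MLP; the SVM's libsvm backend exposes no
iteration cap, so its 300-epoch limit is nominal. One artifact worth
knowing: when real and synthetic tables contain *identical* records
(the degenerate copy case), row-level splitting leaks duplicates across
the train/test boundary with opposite labels and the AUROC inverts below
0.5; the calibration property (AUROC ≈ 0.5) is therefore asserted on
disjoint same-distribution splits, where it holds.

*PRD.* The pooled records are z-scored and k-means clustered (20 clusters,
seeded); per-cluster histograms p (real) and q (synthetic) are swept over
λ = tan θ for 1001 angles in (0, π/2) — a symmetric grid, so the pair set
is closed under λ ↔ 1/λ — giving α(λ) = Σ min(λp, q),
β(λ) = Σ min(p, q/λ). The curve is summarized by the maximum
F<sub>γ</sub> with γ = 8, weighing recall (coverage) above precision
(quality); a histogram-mode entry point bypasses clustering and is tested
against an independent closed-form sweep to 10⁻¹².

*Autocorrelation.* Per dynamic variable, subject-level sample ACFs at lags
1..min(40, T−1) are averaged per side and compared by MAE. For A1 the
value is 0 by construction (the series are real) and serves as the
baseline for the other strategies. Constant series contribute no ACF; an
all-constant variable is masked with a warning.

*TSTR/TRTR.* The regression task predicts the per-subject mean of a
chosen dynamic variable from all other flattened features (the target's
own columns are excluded). The five regressor twins mirror the DLA
configurations; utility is the cosine similarity of the TRTR and TSTR
per-regressor MAE vectors — across regressors, not folds, since the fold
dimension is already consumed by the pseudo-cross-validation envelope.

*MIA.* The adversary holds a fraction (10–50 %) of the generator's
training subjects and the published synthetic data. Attack precision needs
a false-positive population, so the candidate set pairs the known members
with an equally sized sample of held-out non-members; a candidate is
disclosed when any synthetic record lies within cosine distance 0.2 after
per-column min–max normalization on the union (without it, large-unit
columns dominate the angle). A single match suffices, and precision is
defined as 0 when nothing is flagged so that zero-disclosure curves plot
continuously. This member/non-member construction is the package's own:
reported attack precisions are comparable within this framework, not
across publications.

Inside `pseudo_cross_validate()` the cohort is split once per run into a
generator-training part and a holdout (default 35 %) that serves as the
TSTR test set and the MIA non-member population; the holdout fraction must
cover the largest adversary fraction, i.e. h ≥ 0.5·(1−h) for the standard
grid.

## What the fixtures emulate — and what they do not

The *exercise* family mimics graded treadmill tests: five
cardiorespiratory series (HR, VO₂, VCO₂, RR, VE) follow a
warmup–ramp–saturation–recovery effort profile whose resting and
saturation levels are linear in age, sex and weight, scaled by a single
`metadata_effect` knob (0 decouples metadata from series; the default 1
yields an age–HR-mean correlation near 0.55; 5 pushes it above 0.9).
VCO₂ and VE are built from VO₂ and RR, so dynamic–dynamic correlations
are nonzero by construction. The *ICU* family mimics hourly charting: a
persistent three-state latent severity path drives step-like series
(FiO₂ and vasopressor dose exactly piecewise constant — the natural
forward-fill stress test) with binary and five-class categorical
metadata. Both are transparent generative ground truths: their parameters
are recoverable from the output, which is what the parameter-linked tests
assert. They do **not** attempt physiological realism, realistic marginal
distributions, irregular sampling, informative missingness, or
measurement-device artifacts — so passing tests demonstrate that the
machinery is correct under known structure, not that any particular real
cohort would synthesize well. A single-very-long-series family was
considered and omitted: the exercise family at large T covers the same
code paths.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant variables mask their
association cells and scale to zero; empty clusters use the min-with-zero
semantics of the PRD formulas; assignment ties break toward the
lowest-index column; `sample()`-based draws all flow through one seeded
RNG-preserving wrapper, so library calls never perturb a caller's RNG
state. Scaling inversion is exact to 10⁻⁹; PRD histogram mode to 10⁻¹²;
the Hungarian solver is tested to equal exhaustive search on instances up
to n = 7.

The test and acceptance workloads are sized for a single CPU: smoke
adversarial runs use 200 epochs on 50-subject, 48-step cohorts (about ten
seconds per seed per backend); the end-to-end oracle uses 200 subjects;
DLA calibration uses 2000 records; the acceptance script's strategy
comparison uses 120 subjects and 4 folds. These sizes are the package's
validation conditions, chosen so the full suite runs in minutes while
every statistical assertion retains comfortable Monte-Carlo margins.

## Known limitations

Autocorrelation is the only series-specific resemblance metric; trend,
seasonality and variability descriptors are natural extensions. The MIA
is one fixed attack (cosine threshold 0.2) rather than a family of
attacks, and its absolute precision depends on the candidate-set
construction. The adversarial backends are faithful but compact
implementations — single-machine, dense layers, vanilla RNN — intended
for method comparison at cohort scale, not for maximum sample fidelity on
very wide datasets. Finally, synthetic data that passes every metric here
has still not undergone clinical validation; conclusions drawn from it
should be reviewed by domain experts before real-world use.
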