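---
title: "mnflow: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mnflow: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mnflow` automates scoring of the in vitro cytokinesis-block micronucleus
(CBMN) assay from imaging-flow-cytometry single-cell images: gating of
in-focus single cells, nine-class convolutional classification
(mono/bi/tri/tetranucleate, each with or without micronuclei, plus
other/unscorable), confusion-matrix cross-validation, binucleated-cell
micronucleus (MN) frequency statistics against vehicle control, and
covariate benchmark-dose (BMD) potency estimation. A seeded synthetic image
generator stands in for cytometer data so the whole chain is testable
without any instrument or download.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic world does and does not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The synthetic imaging world

## What the generator emulates

Each cell is rendered into a 64 x 64 pixel, two-channel, 16-bit image
(channel 1 nuclear fluorescence, channel 2 brightfield) at a nominal
0.33 um/px (a 40x imaging-flow-cytometer calibration). Nuclei and
micronuclei are soft-edged discs in the fluorescence channel; the
brightfield channel holds a textured cell disc with a darker rim on a
mid-grey background. A laboratory profile applies the nuisance variation
that differs between cytometers and stains: fluorescence gain, background
level, Gaussian focus blur, a linear illumination tilt, and additive
sensor noise. Defaults (`lab_profile()`): gain 1.0, background 5% of
range, blur sigma 0.8 px, tilt 4%, noise sd 1.5% of range; these render an
in-focus, well-stained population and are all free parameters.

Morphology defaults, chosen once for a TK6-like population and exposed in
`cell_spec()` / `random_cell_spec()`:

* cell diameter uniform 54-60 px, i.e. a disc area of 236-308 um^2 —
  inside the 200-500 um^2 single-cell gate by construction;
* nucleus diameters a per-class fraction of the cell diameter (0.42,
  0.34, 0.30, 0.27 for 1-4 nuclei) with +-8% jitter;
* micronucleus diameters 0.15-0.26 of the mean parent-nucleus diameter.
  The CBMN scoring rule admits 1/16-1/3, and the validator enforces that
  full range, but at this resolution a 1/16-ratio MN is ~1.2 px across and
  is unresolvable by any scorer; the default sampling range keeps rendered
  MN detectable while staying inside the admissible band.

Nuclei are placed on a jittered ring around the cell centre with a >= 2.5
px clear gap between nucleus boundaries. Plain rejection sampling was
tried first and abandoned: once the first nucleus lands near the centre no
second position can satisfy the separation, the constraint then has to be
relaxed, and the resulting touching nuclei merge into one blob — breaking
the generator's own label contract (the round-trip invariant below).
Micronuclei are rejection-placed clearly inside the cell, >= 3.5 px away
from every nucleus boundary, so blur cannot bridge them to a parent
nucleus above the detection threshold.

The ninth class renders five unscorable kinds: debris (small speckle),
doublets (two touching cell discs), out-of-focus cells (blur sigma
3.2-4.5 px), mitotic figures (a cluster of small bright fragments) and
dead cells (shrunken granular discs). Mitotic cells intentionally pass the
gates — they are in-focus single cells that the classifier, not the gate,
must reject.

## What a green test does not establish

The generator produces stereotyped geometry: real images have out-of-plane
nuclei, partial occlusion (a 2-D projection of a 3-D cell), stain
heterogeneity within nuclei, camera-motion degradation, and genuinely
ambiguous events that experienced scorers disagree on. A classifier that
reaches 85-100% per-class accuracy here has demonstrated that the
training/inference machinery works end to end — not that it would reach
the published accuracies on cytometer data. The accuracy criteria in
`tests/testthat/test-acceptance.R` are deliberately internal to the
synthetic world.

## Round-trip label fidelity

The generator's central invariant is that its labels are honest: an
independent blob oracle (mid-intensity threshold, 8-connectivity, CBMN
size rule) recovers the rendered phenotype for >= 99% of non-unscorable
cells at the default profile, and every rendered MN measures back inside
the 1/16-1/3 ratio band. The oracle lives in the test helpers, not in the
package, so it cannot drift with the implementation.

## Dose-response simulation

The true binucleated-cell MN frequency follows a Hill-shaped induction
curve `f(x) = f0 (1 + (F - 1) x^d / (b^d + x^d))` — the same family the
BMD module fits, so the estimation problem is well specified. Defaults:
background `f0 = 0.01` (a typical TK6 vehicle-control MN frequency),
plateau fold-change `F = 8`, half-maximal concentration `b = 1` ug/mL
(inside the 0.8-1.6 ug/mL exposure design), log-steepness `d = 2`, and
median-preserving lognormal replicate noise with natural-log sd 0.15.
Per-replicate scoring then draws a multinomial phenotype mix (55%
binucleate at baseline) so the observed frequency carries binomial
counting noise on top of the replicate noise, exactly as a scored sample
does. The generator returns the closed-form ground-truth BMD alongside.

# Gating

The gate set is: brightfield area 200-500 um^2, aspect ratio 0.75-1.0,
gradient RMS 55-80, all boundaries inclusive (region gates include their
boundary, and one convention had to be fixed for exact testability). The
proprietary cytometer feature definitions are not public, so surrogates
are declared, not claimed identical:

* area: object-mask pixel count x pixel size^2; the mask thresholds the
  smoothed absolute deviation from the border background level;
* aspect ratio: minor/major axis of the mask's second-moment ellipse;
* gradient RMS: RMS of the Sobel gradient magnitude over the mask,
  linearly calibrated (constant 344.0, frozen) so the default in-focus
  synthetic population median sits at 67.5 — the centre of the published
  55-80 in-focus window. Only the gate behaviour matters downstream.

# The classifier

## Architecture

Input 64 x 64 x 2. A 3 x 3 stem convolution (32 channels), then three
scales of two dual-path subunits each: every subunit runs a 1 x 1 and a
3 x 3 convolution in parallel (each followed by batch normalisation and
ReLU) and concatenates them to the scale width (32, 64, 128). 2 x 2 max
pools sit between scales, and a pool directly after the stem
(`stem_pool = TRUE`) brings the scales to 32/16/8 px. The head is global
average pooling, a fully connected layer and softmax. All widths, depths
and the stem pool are configurable (`network_config()`); the defaults are
a declared surrogate where the original architecture diagram leaves filter
counts unstated. The stem pool is a pragmatic choice: the original
network family downsamples early, and at full 64-px resolution the first
scale alone triples single-CPU training time for no measurable accuracy
gain in this synthetic world.

The implementation is self-contained single-precision RcppArmadillo
(im2col + GEMM convolutions, batch-norm with saved inverse-sigma
backward, argmax-routed max-pool gradients, ADAM with L2 on
convolution/FC weights only). No deep-learning runtime is required.

## Training schedule

Defaults follow the published recipe: 30 epochs, batch size 88,
cross-entropy under ADAM, initial learning rate 5e-3 dropped by 0.9 every
5 epochs (`lr_at_epoch()` is the exact closed form), L2 1e-4, epsilon
1e-8, reshuffling every epoch, and augmentation by random x/y reflection,
rotation, translation and 90-110% scaling. Rotation (+-15 deg) and
translation (+-4 px) ranges are unstated upstream; the defaults keep cell
content inside the frame so augmentation never changes the blob-oracle
label, and both are configurable.

Two interpretation choices worth recording:

* "zero-center" input handling: per-batch, per-channel mean subtraction
  of the 0-1-scaled input at training time, in addition to the in-network
  batch-norm layers; inference subtracts the stored training-set channel
  means.
* batch-norm inference statistics are finalised after training by a full
  train-mode pass over the training set (pooling chunk moments by the law
  of total variance). A momentum-0.1 moving average starting from 0/1
  initialisation retains a visible bias after short trainings — the
  10-epoch acceptance run lost ~25 accuracy points to it before the
  finalisation pass was introduced.

Determinism: every stochastic step (weight init, shuffling, augmentation
draws) flows from explicit seeds through R's RNG; two runs with equal
seeds produce bit-identical weights in the single-threaded test
configuration.

Class weighting (optional) defaults to inverse class frequency normalised
to mean 1; `merge_polynucleated()` collapses the four tri/tetra classes to
one `polynucleated` label for the reduced six-class variant.

# Significance framework

Binucleated-cell MN frequency is `N(BN+MN) / (N(BN) + N(BN+MN))` — the
total-binucleate denominator of standard CBMN practice. A zero frequency
is replaced by the half-minimum pseudo-count `0.5 / n_binucleated` before
the log10 transform; a sample with no binucleates at all returns an
explicit `NA`, never a silent zero.

The decision framework: log10-transform; Shapiro-Wilk on pooled
within-group-centred residuals (per-group n = 3 is too small for
per-group testing) and Bartlett across groups; if both p > 0.05, a
one-sided (increase) single-step Dunnett test against the vehicle control
at alpha 0.05, otherwise a one-sided many-to-one Dunn rank test with
Sidak family correction (the correction is unstated upstream; Sidak is the
conventional choice for the many-to-one family). Both branches are
invariant to rescaling all frequencies by a constant.

The Dunnett adjusted p-value is computed by the package's own quadrature
of the equicorrelated multivariate-t orthant probability — conditioning on
the control mean (40-node Gauss-Hermite) and the pooled standard deviation
(64-node Gauss-Legendre on the chi density) — because no multivariate-t
package is guaranteed in the runtime. The quadrature reproduces classical
one-sided critical values (e.g. 2.42 at k = 3, df = 8, alpha = 0.05) to
three decimals and an independent reference implementation to ~1e-4.

# Benchmark-dose analysis

## Model families and covariate ladder

Continuous-data families in their standard four-parameter forms:
exponential `y = a (c - (c - 1) exp(-(x/b)^d))` and Hill
`y = a (1 + (c - 1) x^d / (b^d + x^d))`, with lognormal error (normal on
log responses) and the within-group variance profiled out analytically.
The benchmark response is a 50% increase over the *fitted* background
(`y(BMD) = a (1 + ces)`), which has closed-form inversions for both
families; the BMD therefore depends only on (b, c, d) — two covariate
levels that share potency share the BMD even when their backgrounds
differ.

Internally the potency parameter is replaced by the BMD itself
(`b = BMD / gain(c, d)`), with `c` parameterised as
`1 + ces + exp(theta)` so the benchmark is always reachable during
optimisation. This makes the profile-likelihood interval a coordinate
profile and removes a whole class of constraint failures.

With a covariate, fitting walks a nested acceptance ladder from the fully
shared model: within-group variance, then background `a`, then potency
`b` become level-specific only if the likelihood-ratio test improves the
fit at p < 0.05; maximum response `c` and log-steepness `d` stay shared
throughout. If level-specific `b` is rejected the covariate is "rejected
for potency" and one BMD is reported for all levels. The ladder order is
configurable; the default mirrors the end state reported for this assay
(covariate-dependent `a` and `var`, shared `c`, `d`, and ultimately a
shared potency).

Optimisation: BFGS on log-parameters from five deterministic data-driven
starts (d in {0.5, 1, 2, 4}, potency from the design quantiles), with a
Nelder-Mead polish; ladder steps warm-start from the nested accepted
model plus two cold starts. All restarts are deterministic, so fits are
reproducible without seeds.

## Profile-likelihood intervals and their calibration

The two-sided 90% interval is read off the profile deviance. The default
cutoff is the F-calibrated form `N log(1 + qF(0.90; 1, N - p)/(N - p))`
(exact for Gaussian regression with profiled variance) rather than the
asymptotic chi-square(1) value 2.706: at the replicate counts of a typical
dose-response design (N = 12) the chi-square cutoff under-covers
noticeably (~0.81 vs ~0.89 measured in the acceptance simulation), and the
F form is the standard small-sample correction. `cutoff_method = "chisq"`
restores the asymptotic behaviour. Bound search steps the log-BMD in 0.25
increments (max 60) and polishes by `uniroot`; a profile that never
crosses the cutoff reports an infinite (or zero) bound with an
`unbounded` flag.

One identifiability caveat, found empirically and worth knowing when
designing experiments: with only four distinct concentrations the
four-parameter mean function is *saturated* — several (a, b, c, d)
configurations interpolate the group means exactly, `c` can diverge along
a likelihood ridge, and profile intervals lose calibration (coverage
~0.70 in simulation regardless of cutoff). The coverage acceptance
criterion therefore simulates a 6-concentration design; fits to
4-concentration data remain useful for the covariate likelihood-ratio
ladder (which compares nested structures on the same design) but their
intervals should be read with caution.

# Pipeline and reproducibility

`run_pipeline()` chains simulate, ingest/gate, train, score, evaluate,
dose-response and bmd under a single JSON config (JSON rather than YAML
because the guaranteed runtime has no YAML parser). Per-module seeds are
derived from one master seed by FNV-1a hashing of `(seed, module)`; every
stage artifact is recorded with a content hash and the producing config
hash, and rerunning an identical config and seed reproduces byte-identical
CSV/JSON outputs. The interchange format is a two-page 16-bit multipage
TIFF per cell (uncompressed, little-endian — written and read by the
package's own minimal baseline-TIFF codec, since no TIFF library is
guaranteed at runtime) plus a CSV manifest carrying labels, provenance and
gating features.

# Known limitations

* The renderer is statistical scenery, not microscopy simulation: no
  point-spread asymmetry, no chromatin texture, no overlapping/occluded
  nuclei, no apoptosis-vs-necrosis distinction, no nuclear buds or
  bridges.
* Gating feature surrogates are calibrated to reproduce gate behaviour,
  not the proprietary feature values.
* The CNN is CPU-bound and single-threaded by design; it is sized for
  tens of thousands of images, not millions.
* BMD intervals on saturated (4-concentration) designs are not
  calibrated; see above.
* The Dunn branch with n = 3 replicates is conservative: rank tests at
  this sample size have little power, which is the accepted cost of the
  non-parametric fallback.
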