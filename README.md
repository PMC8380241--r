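# mnflow

Automated scoring of the in vitro cytokinesis-block micronucleus (CBMN)
assay from imaging flow cytometry single-cell images.

The CBMN assay is a standard genotoxicity test: cells exposed to a test
compound are blocked from completing cytokinesis, so cells that divided
appear **binucleated**, and chromosomal damage shows up as small satellite
**micronuclei** (MN) next to the main nuclei. The DNA-damage readout is the
binucleated-cell MN frequency

> f = N(BN+MN) / (N(BN) + N(BN+MN))

scored over thousands of cells per sample. Manual scoring is slow and
subjective; imaging flow cytometry captures brightfield + nuclear
fluorescence images of every cell in flow, and a convolutional classifier
can score them automatically.

`mnflow` implements that pipeline end to end, for toxicologists and
image-analysis researchers who want a self-contained, testable reference
implementation:

* **synthetic data** — a seeded generator for labelled 64×64 two-channel
  16-bit cell images (mono/bi/tri/tetranucleate ± MN, plus
  debris/doublet/out-of-focus/mitotic/dead "other" events), with
  laboratory-profile nuisance variation and full dose–response experiment
  simulation;
* **ingest** — multipage-TIFF + CSV-manifest interchange, per-channel
  min/max illumination normalisation, centre crop/zero-pad to 64×64, and
  single-cell gating (brightfield area 200–500 µm², aspect ratio
  0.75–1.0, gradient-RMS focus score 55–80, boundaries inclusive);
* **classifier** — a nine-class Inception-style dual-path CNN
  (conv/batch-norm/ReLU subunits, max pooling, global average pooling,
  softmax) written directly in RcppArmadillo: ADAM, cross-entropy,
  batch 88, learning rate 5e-3 dropping ×0.9 every 5 epochs, L2 1e-4,
  reflection/rotation/translation/90–110 % scale augmentation — no
  deep-learning runtime needed, CPU only, fully seeded;
* **evaluation** — human-vs-network confusion matrices with per-class
  precision / FDR / sensitivity / FNR and overall accuracy, stratified
  60/40 train/test splits;
* **statistics** — the dose–response significance framework (log10
  transform, Shapiro–Wilk + Bartlett pretests routing to a one-sided
  Dunnett test or a non-parametric Dunn fallback, α = 0.05/0.01/0.001
  stars) with the Dunnett multivariate-t probability computed by built-in
  quadrature;
* **benchmark dose** — covariate BMD analysis with the EFSA continuous
  families, exponential `y = a(c − (c−1)e^−(x/b)^d)` and Hill
  `y = a(1 + (c−1)x^d/(b^d + x^d))`, lognormal error, a
  var → a → b likelihood-ratio acceptance ladder for covariate-specific
  parameters (c, d always shared), closed-form BMD at CES 50 % and
  profile-likelihood 90 % confidence intervals;
* **pipeline/CLI** — `run_pipeline()` and an `inst/cli/mnflow.R` launcher
  chaining simulate → gate → train → score → evaluate → dose-response →
  bmd under one JSON config with deterministic per-module seed fan-out
  and content-hashed artifacts.

## Worked example

Simulate a carbendazim-style experiment (three concentrations plus
vehicle control, triplicate, 2,000 events scored per replicate), test for
significant MN induction, and estimate the benchmark dose:

```r
library(mnflow)

drspec <- dose_response_spec(concentrations = c(0, 0.8, 1.2, 1.6),
                             replicates = 3, n_scored_per_sample = 2000,
                             background_mn_freq = 0.01,
                             potency_param = 1.0, max_fold_induction = 8,
                             seed = 42)
dr <- simulate_experiment(drspec)
round(tapply(dr$response, dr$concentration, mean), 4)
#>      0    0.8    1.2    1.6
#> 0.0117 0.0371 0.0569 0.0720

significance_pipeline(dr)
#> Branch: Dunnett (Shapiro-Wilk p = 0.063, Bartlett p = 0.853)
#>   concentration statistic   p_adjusted significance
#> 1           0.8  4.929898 1.487426e-03           **
#> 2           1.2  6.731996 1.943532e-04          ***
#> 3           1.6  7.758659 7.191394e-05          ***

fit <- fit_covariate_model(dr[, c("concentration", "response")],
                           bmd_config("hill"))
ci <- bmd_confidence_interval(fit)
sprintf("BMD %.3f [%.3f, %.3f] ug/mL", ci$bmd, ci$bmdl, ci$bmdu)
#> "BMD 0.365 [0.012, 0.776] ug/mL"
attr(dr, "true_bmd")     # generator's ground truth
#> 0.2773501
```

The mean frequencies rise from the 1 % background toward the plateau, all
three concentrations are significantly elevated over control via the
Dunnett branch, and the profile-likelihood interval for the
50 %-increase benchmark concentration covers the generator's true value.
(The interval is wide: a four-concentration design barely constrains a
four-parameter curve — see the methods vignette.)

Rendering and gating a single cell:

```r
sp  <- cell_spec("binucleate_mn", n_micronuclei = 1, mn_diameter_ratios = 0.22)
img <- render_cell(sp, lab_profile(), seed = 7)     # 64 x 64 x 2, 16-bit
compute_gating_features(img)
#> area 314.1 um^2, aspect ratio 0.995, gradient RMS 67.7   (passes all gates)
```

Training and evaluating a classifier (the acceptance-scale run):

```r
pop  <- rep(PHENOTYPE_CLASSES, each = 500)           # 4,500 cells
# ... render, split 60/40, then:
m  <- train_network(build_network(network_config(seed = 13)),
                    recs[train], labels[train],
                    train_config(epochs = 10, seed = 17))
pr <- predict(m, recs[test])
overall_metrics(confusion_matrix(labels[test], pr$label))
```

On the default synthetic world this reaches ≥ 85 % overall accuracy with
the four core CBMN classes (mono/bi ± MN) each ≥ 80 % — the exact run is
`tests/testthat/test-acceptance.R` ("acceptance 4").

## Full pipeline

```sh
Rscript inst/cli/mnflow.R run --out myrun --seed 11
# or stage by stage:
Rscript inst/cli/mnflow.R simulate --out myrun --seed 11
Rscript inst/cli/mnflow.R ingest   --out myrun --seed 11
...
```

Artifacts (`manifest.csv`, `gated.csv`, `scores.csv`, `freq.csv`,
`stats.csv`, `bmd.json`, `run_report.json`) land in `--out`; rerunning
with the same config and seed reproduces them byte-identically.

## Documentation

`vignettes/mnflow-methods.Rmd` describes the models and assumptions, every
tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, the numerical choices (profile
cutoff calibration, optimiser restarts, degenerate-input conventions) and
known limitations.
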