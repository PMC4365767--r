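---
title: "Methods: models, parameters and design choices in cpacor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cpacor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Epigenome-wide association studies (EWAS) on Infinium 450K-style bead
arrays relate per-CpG methylation fractions (beta values) to a phenotype
across hundreds or thousands of samples. Two features of these data break
naive per-marker testing. First, the assay chemistry — two probe designs,
two colour channels, bisulfite conversion, chip-by-chip processing —
introduces technical variation that is correlated with processing batches
and inflates association test statistics. Second, methylation in whole
blood is dominated by white-cell composition, so markers covary globally
through each sample's cell mixture; correlated markers distort the null
distribution of test statistics in both directions (deflation for most
phenotype draws, severe inflation for some).

`cpacor` implements a complete pipeline addressing both problems:
quality control with a stringent, calibrated detection threshold;
stratified quantile normalisation of signal intensities; *control probe
adjustment* — principal components of the array's control-probe
intensities used as regression covariates to absorb batch structure;
reference-based estimation of white-cell proportions; a final residual
PCA; and per-marker association with permutation-based inflation
diagnostics. A synthetic-array generator with a full ground-truth record
makes every stage testable without real array data.

# Pipeline model

For sample $i$ and marker $j$, the methylated and unmethylated
intensities $M_{ji}, U_{ji}$ give the beta value

$$\beta_{ji} = \frac{M_{ji}}{M_{ji} + U_{ji} + a}, \qquad a = 100,$$

the bead-array convention; the positive offset keeps $\beta < 1$ and
stabilises low-intensity probes. The stages are:

1. **Background correction.** Per sample and colour channel, the 5th
   percentile of the negative-control intensities is subtracted, flooring
   at 1. The quantile is a parameter (`probs`); negative controls measure
   optical background by design.
2. **Detection P values.** The background distribution per sample and
   channel is summarised by the median and normal-consistent MAD of the
   negative controls. Type I probes are tested against
   $N(2\mu_c, 2\sigma_c)$ of their single channel; Type II probes against
   $N(\mu_G+\mu_R, \sigma_G+\sigma_R)$ — spreads added rather than
   combined in quadrature, following the convention of the detection test
   in the tooling this field uses. The P value is the upper-tail
   complement $1 - \Phi(z)$ computed in double precision. Reported values
   are floored at machine epsilon ($2.22\times10^{-16}$) so that log-scale
   diagnostics never hit zero; *masking* uses the raw complement, in
   which a clearly detected probe underflows to exactly 0. That is what
   makes the stringent threshold meaningful: masking at $10^{-16}$ (the
   inclusive rule `p >= threshold` sets entries to missing) keeps exactly
   the entries whose detection P underflowed, i.e. probes overwhelmingly
   above background. The lenient conventional threshold (0.05) leaves
   substantial background-only calls — visible on the Y chromosome in
   females, where true signal is absent.
3. **QC filtering.** Sample and marker call rates are the fractions of
   non-missing entries after masking; samples with call rate strictly
   below 0.98 are excluded, as are samples whose recorded sex contradicts
   their Y-chromosome call rate (females above 0.5, males below 0.5; the
   0.5/0.5 cut points are midpoint defaults and configurable). A
   two-pass mode (initial lenient mask for top-level QC, then the final
   threshold with call rates recomputed) is available; the default is a
   single pass at the final threshold.
4. **Stratified quantile normalisation.** Intensities are split into six
   categories — Type-I M red, Type-I U red, Type-I M green, Type-I U
   green, Type-II green (M signals), Type-II red (U signals) — and each
   category is quantile-normalised across samples (scheme `QN-I6`, the
   default; `QN-I4`, `QN-I2`, beta-scale `QN-B3` and `none` exist for
   comparison). Normalisation delegates to
   `limma::normalizeQuantiles(ties = TRUE)`: missing entries stay
   missing, non-missing values are placed by interpolated fractional
   ranks, and ties receive the mean of their span. Autosomes and sex
   chromosomes are normalised in separate runs (their beta distributions
   differ), which the pipeline's stream mechanism enforces.
5. **Control probe adjustment.** One feature per (non-negative control
   probe, channel); features are centred and scaled (correlation-scale
   PCA is the default because control categories span different
   intensity magnitudes; covariance-scale is a flag) and decomposed by
   SVD with a deterministic sign convention (largest-magnitude loading
   positive). The first $k=30$ sample-score vectors enter all downstream
   regressions as covariates.
6. **Cell composition.** Houseman-style constrained projection: for each
   sample, $\min_w \lVert y - B_0 w\rVert^2$ subject to $w \ge 0$, where
   $B_0$ is the cell-type reference at the reference markers present on
   the array and missing markers are dropped per sample. No sum-to-one
   constraint is imposed because the measured total white-cell count
   enters the model as its own covariate. The solver is Lawson–Hanson
   NNLS (`pracma::lsqnonneg`), deterministic to well below the 1e-8
   tolerance the estimates are reported at.
7. **Residual PCA.** Betas are regressed (OLS, per marker, on each
   marker's non-missing samples) on age, sex, cell estimates, total
   count and the 30 control PCs; a PCA over samples of the residuals of
   complete markers supplies 5 further covariates capturing global
   covariation unexplained by measured factors.
8. **Association.** Per marker, logistic (or linear) regression of the
   phenotype on the beta value plus the full adjustment set, with a Wald
   test on the beta coefficient. Non-converged or separated fits are
   flagged and reported with missing P rather than aborting, because
   permutation analyses at scale occasionally separate.

## Permutation machinery

Permutation of the phenotype across samples (jointly for all markers, so
inter-marker correlation is preserved) yields the null distribution of
per-marker statistics. Refitting the full model per marker per
permutation is wasteful; the pipeline uses the two-stage shortcut:
betas are residualised once on the covariates, and each permuted
phenotype is regressed (logistic) on the per-marker residual alone. On a
desk-scale cohort (n = 500, 2,000 markers) the squared correlation
between the two routes' $-\log_{10} P$ vectors exceeds 0.999 (the
acceptance script recomputes it); the residual discrepancy is the
finite-sample difference between adjusting covariates inside versus
outside the logistic fit, and it shrinks as the sample grows.

The per-permutation genomic inflation factor is
$\lambda = \mathrm{median}\{Q_{\chi^2_1}(1-p_j)\} / 0.4549364$, and the
permutation summary reports the median and 2.5/97.5 percentiles of
$\lambda$ together with the per-rank envelope of ordered $-\log_{10} P$
values (the QQ prediction interval). The epigenome-wide significance
threshold is Bonferroni at $\alpha = 0.05$ over the number of
effectively independent tests, rounded down to a power of ten — with
470,000 tests, $10^{-7}$.

Destroying inter-marker correlation (each marker's values independently
permuted across samples, missingness travelling with the values) is the
reference condition under which the permutation null is expected to be
exactly calibrated.

The univariate logistic fits behind the permutation engine are a
vectorised Newton/IRLS implementation with the exact per-marker 2×2
information matrix; it matches `stats::glm` coefficients to ~1e-13 on
test fixtures (the suite asserts this) and fits 2,000 markers × 500
samples in well under a second, which is what makes 200-permutation
analyses interactive.

# The synthetic-array generator

`cohort_design()` fixes the study conditions; the generator is not a
tuning dial. Defaults describe a desk-scale population study: 500
samples, 2,000 markers, chips of 12 samples (the 450K BeadChip layout),
six cell types, chip batch effects of log-scale SD 0.3 per colour
channel, logit-scale marker noise 0.3.

Per sample, cell proportions follow a Dirichlet with a
granulocyte-dominated concentration (mean fractions roughly 56/14/9/6/9/5%
for granulocytes, CD4+ T, CD8+ T, B, monocytes and NK cells — the
ballpark of adult peripheral blood). Constitutive markers are bimodal in
beta (modes near 0.08 and 0.92), matching the array's marginal
distribution. A quarter of markers are cell-type dependent and shaped
like real cell-specific CpGs: one lineage (drawn in proportion to its
abundance, so myeloid-divergent CpGs dominate) diverges from a common
base by a beta-scale contrast of 0.3–0.9; at these markers cell
composition is the dominant biological variance component, as it is in
whole-blood methylation, which is what makes the cell-composition and
residual-PC adjustments consequential. The 500 reference markers carry
strongly discriminative profiles (between-cell-type range ≥ 0.3). True
betas are logistic-transformed sums of the cell-mixture logit, age/sex/
spike effects, a shared within-cluster component (markers come in
clusters of 2–8 within 1 kb, clusters ≥ 10 kb apart — the source of
local correlation), and independent logit noise of SD 0.15, putting the
per-CpG residual SD near 0.05 on the beta scale at mid-range markers
(conservative relative to real arrays, where it is nearer 0.02–0.04).

The technical layer maps true betas to intensities: per-probe total
intensity is log-normal; M and U route to colour channels by probe
chemistry; each chip has per-channel log-gains (a processing-run
component shared by the chips generated in one call plus a chip-local
component, each of SD `batch_sd` — duplicate batches are deliberately
separate runs); markers respond to the gain with their own sensitivity
(uniform 0.5–1.5), so batch effects perturb within-sample ranks — a pure
scalar gain would be a rank-preserving transform that quantile
normalisation removes entirely, which contradicts how real batch effects
survive QN. A second batch component acts at the probe level: each
(marker, chip) pair receives an independent logit-scale shift of SD
`probe_batch_sd` (default 0.1), standing in for probe-lot and spatial
hybridisation variability. The scalar gains are what quantile
normalisation largely removes; the probe-level component is what
control-probe adjustment removes beyond it — without such a component
CPA would have nothing left to do after QN. Control probes carry the
same gains with probe-specific sensitivities plus a control-by-chip
fingerprint (SD 0.15), reflecting that the monitored chemistry steps
vary semi-independently across chips; this is precisely what makes
control-probe PCA informative about the whole chip-level batch space.
Negative controls and Y probes in females draw from the background
distribution. A per-measurement logit-scale technical noise (SD 0.1)
makes duplicates concordant but not identical. Every run returns a
ground-truth record: cell proportions, chip gains and assignments,
spiked markers, per-marker effects, true betas.

What the generator does **not** emulate: probe sequences and
cross-hybridisation mechanics, SNP-induced artefacts, realistic
chromosomal marker density, dye-swap chemistry detail, or spatial
position-on-chip effects. Passing tests therefore demonstrate that the
pipeline removes the *kinds* of structure it targets (multiplicative
channel/batch bias expressed in control probes, cell-mixture
covariation, local clustering), not that it handles every artefact of a
physical array.

# Numerical choices and degenerate inputs

- Detection floor at machine epsilon; masking on the raw complement
  (see above). A zero negative-control MAD is fatal with advice, not a
  silent degenerate test.
- Quartiles by linear interpolation (R type 7) in the outlier-rate
  fences; stated because the rate depends on the convention.
- QN tie handling: tied values receive the mean of their rank span,
  keeping the transform deterministic; QN is exactly idempotent on
  complete matrices and idempotent up to interpolation error under
  missingness.
- PCA sign convention: the largest-magnitude loading of each component
  is made positive, so scores are reproducible across runs and BLAS
  builds.
- Ranking ties in the spike benchmark break by descending absolute
  coefficient, then marker id — deterministic by construction.
- Rank-deficient designs are fatal and name the collinear columns;
  covariates that are constant within a stream (e.g. sex in a
  single-sex sex-chromosome run) are dropped with a message.
- Separated or non-converged logistic fits are flagged
  (`converged = FALSE`, missing P).

# Desk-scale validation and its honest limits

The acceptance computations (see `scripts/acceptance.R`) run at n = 500
samples and 2,000 markers with 200 permutations — sizes chosen so the
whole suite completes in minutes on one CPU while leaving the Monte
Carlo error of each reported quantity well below its tolerance; the
paper-scale analyses they stand in for used thousands of samples and
~470,000 markers.

Two desk-scale effects are worth stating plainly, because they are
properties of the statistics at this n, not defects of the
implementation:

- Univariate logistic Wald tests with bounded, strongly bimodal
  predictors (beta values) show a small finite-sample displacement of
  the median squared statistic at n = 500 (of order 1–3%, direction
  depending on the realised marker distribution); the same computation
  with Gaussian predictors is exact to Monte Carlo error, and the
  effect shrinks as n grows. The permutation-null medians we report are
  therefore expected to sit within about ±0.01–0.02 of 1, not exactly
  at it.
- The duplicate-comparison regression (replicate status on beta plus 30
  control PCs, 72 observations) has a median-based $\lambda$ whose
  realisation-to-realisation SD is ~0.15, driven by inter-marker
  correlation and the small number of chips; the acceptance script
  therefore reports the mean over eight independently simulated
  replication experiments of 5,000 markers each — a more precise
  estimate of the same quantity. Near-exact collinearity between
  replicate status and the chip space (six chips, thirty PCs) makes the
  adjusted regression mildly conservative in some realisations.

# Known limitations

- IDAT parsing is out of scope; data enter as tab-separated text.
- The cell-type reference is user-supplied or synthetic; the package
  does not ship any empirical reference panel.
- Single-marker tests only; no region-level or mixed-model association.
- The permutation engine assumes a binary phenotype (logistic family);
  quantitative phenotypes are supported in the direct per-marker
  regression only.
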