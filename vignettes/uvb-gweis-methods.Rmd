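---
title: "Methods: gene-environment interaction GWAS of vitamin D status with a cumulative weighted UVB exposure"
author: "uvbGweis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-environment interaction GWAS of vitamin D status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvbGweis)
```

# The scientific problem

Circulating 25-hydroxyvitamin D (25OHD, nmol/L) is shaped by both genetics
and sun exposure. Because ambient vitamin-D-effective UVB varies roughly
fifty-fold over the year at UK latitudes, a genome-wide analysis that
ignores the environment leaves a large variance component unmodelled and
can miss loci whose effect depends on UVB. This package implements the
full analysis chain for a genome-wide gene-environment interaction study
(GWEIS) of 25OHD in which the environmental exposure is an
*individualized cumulative weighted ambient UVB dose* (CW-D-UVB) rather
than the crude "season of blood draw":

1. **Exposure** (`osgbToLatLon`, `latLonToCell`, `dailySeries`,
   `cumulativeWeightedDose`, `buildExposureTable`): residential
   coordinates and sampling dates are turned into a per-participant dose.
2. **QC** (`hweExactTest`, `kingKinship`, `variantQc`, `sampleQc`,
   `applyQc`): genotype filters for missingness, allele frequency,
   Hardy-Weinberg, imputation quality, heterozygosity and relatedness.
3. **GWEIS** (`preparePhenotype`, `fitVariant`, `runGweis`,
   `runStratified`): per-variant marginal, main and interaction effects
   with model-based and robust covariance and three Wald tests.
4. **Post-GWAS** (`clumpLeads`, `stepwiseConditionalSelection`,
   `varianceExplained`, `signConcordanceTest`, `buildRiskScores`,
   `evaluateRiskScores`): independent-variant selection, replication
   statistics and genetic risk scores.
5. **Heritability** (`computeLdScores`, `ldscH2`, `ldscRg`,
   `stratifiedH2`): LD score regression, genetic correlation and
   exposure-stratified SNP-heritability.
6. **Synthetic data** (`simConfig`, `simulateGenotypes`,
   `simulateUvbGrid`, `simulateCohort`, `makeFixtureBundle`): generators
   with full ground truth so that every stage is testable without any
   external data.

# The exposure model

The exposure of a participant sampled on day $t$ living in grid cell $c$
is

$$\mathrm{CWDUVB} = \sum_{x=1}^{135} D_c(t - x)\; e^{-(\ln 2 / 35)\,x},$$

where $D_c$ is the daily vitamin-D-effective UVB dose (kJ/m$^2$) of the
cell and $x$ is the lag in days. Lag $x = 1$ is the day *before* blood
draw; the sampling day itself is excluded, since that day's UVB cannot
yet be reflected in the assay. The half-life of 35 days reflects the
turnover of the vitamin-D-UVB effect in the body; the 135-day window
(about four half-lives) is where contributions become negligible. Both
are tunable through `weightingParams()` but are deliberately frozen as
defaults.

Residences given as British National Grid eastings/northings are
converted by the inverse transverse Mercator on the Airy 1830 ellipsoid
with the standard OSGB constants. **Datum choice:** by default no
OSGB36-to-WGS84 datum shift is applied before grid lookup. The shift
moves UK points by roughly 100 m, while a quarter-degree cell is about
28 km tall, so the cell assignment is essentially never affected; an
optional seven-parameter Helmert transformation (`datum = "WGS84"`) is
provided for users whose dose grids are WGS84-referenced.

**Missing daily doses** are handled with a declared policy: interior
gaps are linearly interpolated between the nearest observed neighbours,
gaps at the window edges carry the nearest observed value, and a window
with more than 10% missing days is rejected with a per-participant
error. Real satellite dose products have sporadic gaps; interpolation on
the smooth seasonal scale of UVB introduces far less error than
dropping days, and the 10% guard keeps badly covered windows out.

**Grid convention:** cells are half-open and anchored at the lower-left
corner, so a point exactly on an interior boundary belongs to the
higher-index cell; the cell's single stored value is used directly (no
bilinear interpolation), matching products that publish per-cell
averages.

# The association engine

The phenotype is prepared by clamping raw 25OHD at the assay lower limit
of detection (10 nmol/L), taking the natural log (the distribution is
right-skewed), and z-scoring against the analysis sample. Two
least-squares models are fitted per variant, with covariates age, sex,
vitamin D supplement use, fish oil use, ten principal components, and
the exposure itself:

$$\text{marginal:}\quad y \sim \beta_{\text{marginal}} G + \mathbf{C},
\qquad
\text{interaction:}\quad y \sim \beta_G G + \beta_{G\times E}\,(G \cdot E)
 + \mathbf{C}.$$

Three tests are reported per variant: the 1-df Wald test of
$\beta_{\text{marginal}}$, the 1-df Wald test of $\beta_{G\times E}$,
and the 2-df joint Wald test of $(\beta_G, \beta_{G\times E})$ with
their full covariance. The joint test is the more powerful choice when
the true architecture (main vs interaction) is unknown.

**Covariance choice.** Interaction tests are vulnerable to
heteroskedasticity induced by scale misspecification, so the interaction
and joint tests default to a sandwich covariance; the marginal test uses
the model-based SE. Both covariances are always stored in the output,
and `se_type = "model"` switches the tests. The sandwich flavour is
**HC2** by default rather than HC0: the exposure is right-skewed (UVB
doses are roughly lognormal), so the G x E column contains
high-leverage rows, and the uncorrected HC0 meat is biased downward
exactly at those rows — in null calibration runs at n = 2 000 the HC0
joint test rejects at about 5.6% instead of 5%, while the
leverage-corrected HC2 weights restore the nominal level. `hc_type`
switches between HC2, HC0 and the more conservative HC3.

**Numerical route.** The scan residualizes the phenotype, the dosage and
the interaction column on the covariates once (Frisch-Waugh-Lovell) and
solves a per-variant 2x2 system; the coefficients, the model-based
covariance block and the HC0 block computed this way are algebraically
identical to the full-design quantities, which the test suite verifies
against a naive normal-equations oracle and against
`sandwich::vcovHC`. Missing dosages are mean-imputed per variant, which
keeps the sample constant across variants; constant or
covariate-collinear dosages are skipped with a recorded reason, never
fatal. P-values use the chi-square reference (Wald); at the sample sizes
of interest the difference from the t reference is negligible.

Stratified scans (`runStratified`, by BMI category with the standard
18.5/25/30 kg/m$^2$ cutoffs, exposure quintile, or a >= 3 h/day outdoors
subset) re-standardize the phenotype within stratum, so each stratum is
an independent, internally standardized analysis. BMI is deliberately
*not* a covariate of the main model — 25OHD and BMI are plausibly
bidirectionally related and conditioning on a collider could bias the
genetic effects — stratification is used instead.

# Independent variants, risk scores, replication

`clumpLeads` implements greedy LD clumping: significant variants sorted
by ascending p (ties broken by chromosome then position, so the result
is deterministic), the best remaining variant becomes a lead, and
everything with $r^2 \ge 0.1$ to it is removed.
`stepwiseConditionalSelection` implements conditional stepwise selection
in the COJO spirit, but as *exact* conditional fits on individual-level
data: the summary-statistic + external-LD version approximates exactly
this computation, and with synthetic cohorts the individual-level data
are available. Forward steps add the candidate with the smallest
conditional p while it stays below 5e-8, a backward pass drops selected
variants whose joint p rises above the threshold, and candidates with
$r^2 > 0.9$ to a selected variant within a 10 Mb window are never added
(collinearity guard).

The variance explained by independent variants on the standardized trait
uses $2\beta^2 f(1-f)$ per variant. Replication is summarized by the
two-sided exact binomial sign-concordance test at $p_0 = 0.5$ (pairs
with an exactly zero effect are excluded from both counts — a sign is
not defined for them) plus the Pearson correlation of the paired
effects. Genetic risk scores are
$\sum_j d_{ij}\beta_{\text{marginal},j}$ (marginal) and
$\sum_j d_{ij}(\beta_{G,j} + E_i\,\beta_{G\times E,j})$
(interaction-aware, using each participant's *own* exposure), evaluated
against raw 25OHD in an age- and sex-adjusted model with a
top-vs-bottom-decile contrast.

# Heritability by LD score regression

Under a polygenic model, $E[\chi^2_j] = 1 + N h^2 \ell_j / M$ plus an
intercept excess for confounding, where $\ell_j$ is the LD score of
variant $j$. LD scores are computed **in-sample** from the genotype
panel (`computeLdScores`) with the bias adjustment
$\tilde r^2 = r^2 - (1 - r^2)/(n - 2)$, over a window of 200 flanking
variants per side; synthetic genomes carry no genetic map, so the window
is defined in variant count, and in-sample scores match the simulated LD
exactly — there is nothing to download. `ldscH2` fits the weighted
regression with a free intercept (heteroskedasticity weights
$1/\max(\ell_j, 1)$, one re-weighting pass using the implied expected
chi-square), converts the slope via $M/N$, and jackknifes over 20
contiguous variant blocks (a desk-scale stand-in for the conventional
200 blocks; with 2 000 variants, 20 blocks of 100 give a stable
jackknife). `ldscRg` regresses the z-score product of two traits on the
same scores for the genetic covariance and normalizes by the geometric
mean of the univariate estimates. `stratifiedH2` chains the stratified
marginal scan into per-stratum estimates with stratum-specific N.

The package's heritability values on synthetic data are parameter-
recovery checks; observed-cohort h2 figures depend on the underlying
biobank and are not reproduction targets here.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Genotypes**: each haplotype is a latent standard-normal AR(1) series
  within LD blocks (independent across blocks), thresholded at the
  allele-frequency quantile; dosage is the sum of two independent
  haplotypes, so HWE holds by construction. The latent-Gaussian copula
  is the simplest construction with tunable $r^2$ that preserves HWE.
  `ld_rho` may be a vector recycled across blocks, giving heterogeneous
  LD and hence the spread of LD scores that LD score regression needs
  for identification. Allele frequencies are drawn uniformly from
  [0.005, 0.5]: low-frequency (MAF < 0.05) variants stay in the
  spectrum, while desk-scale cohorts (n of a few thousand) rarely
  produce monomorphic columns. Each block consumes its own seed stream,
  so enlarging the panel never perturbs earlier draws.
* **UVB grid**: a seasonal exponential-of-cosine peaking at the June
  solstice, calibrated so the noise-free June and December monthly mean
  doses at latitude 51.5 equal the London climatology (5.56 and 0.11
  kJ/m$^2$ — the ~50-fold annual range), a linear latitude dimming
  factor, and multiplicative lognormal day-to-day cloud noise with mean
  one.
* **Phenotype**: a standardized latent trait built from main genetic,
  exposure ($\gamma E_{std}$, default variance share 0.124 — the share
  ambient UVB explains of 25OHD variance in UK cohorts), interaction,
  covariate and noise components, mapped to raw 25OHD by
  $\exp(\mu + \sigma z)$ with $\mu = \log 48$, $\sigma = 0.35$ (a
  realistic right-skewed distribution) and clamped at the 10 nmol/L
  assay LOD. The exposure is standardized inside the generative model so
  variance-share parameters are interpretable; the raw kJ/m$^2$ value is
  what flows through the pipeline interface. Under
  `architecture = "interaction"` the generative model is *exactly* the
  estimation model of the scan, making parameter recovery well posed;
  under `"amplification"` every main effect is scaled by
  $1 + \kappa E_{std}$, i.e. $\beta_{G\times E} = \kappa\,\beta_G$,
  the architecture that produces a heritability gradient across exposure
  strata.

What the generator does **not** emulate: realistic human LD maps and
recombination hotspots, population structure (the ten PCs in the
simulated cohorts are pure noise covariates), imputation error,
genotype-environment correlation, and assortment. Passing tests
demonstrate the statistical machinery is correct under the stated
generative assumptions, not that any particular real-cohort estimate
will be reproduced.

# Numerical choices and degenerate inputs

* Meridional-arc inversion iterates to below 1 nm in the meridional arc
  (the practical double-precision floor at these magnitudes), far below
  the 1e-6 degree round-trip tolerance asserted in tests.
* Hard calls for HWE/KING round dosages to the nearest integer; dosages
  in (0.1, 0.9) or (1.1, 1.9) are too uncertain to call and are treated
  as missing for hard-call statistics (an imputation-uncertainty guard).
* MAF is computed from mean dosage / 2 on retained samples.
* Kinship pruning is greedy from the most related pair down, dropping
  the member with higher missingness (ties: the later sample), which is
  deterministic and matches common practice; full graph vertex-cover
  optimization is not attempted.
* Filter order is declared, not inferred: samples before variants, and
  within variants info -> missingness -> MAF -> HWE, with the reason
  recorded at the first failing filter. QC is idempotent.
* Quintile labels use stable ranks, so heavily tied exposures still give
  near-equal strata and labels are invariant under monotone transforms.
* The HWE exact test is the standard (not mid-p) formulation;
  probability ties are compared with a 1e-12 relative tolerance so that
  enumeration-equal configurations are counted identically in floating
  point.
* LDSC equivariance in the chi-square scale is exact under fixed
  weights; the adaptive second-step reweighting makes it hold to a small
  numerical tolerance only.

# Problem sizes used by the test-suite and acceptance script

Simulation-based checks run at desk scale, chosen as the smallest sizes
at which the statistical properties under test are clearly resolved:
type-I error over 2 000 null variants at n = 2 000; power ordering over
200 single-variant replicates at n = 1 000; LD score regression recovery
at n = 5 000, m = 2 000 (10 replicates in the test suite, 5 in the
acceptance script); the exposure-stratified gradient at n = 5 000 with
quintile strata of 1 000. The HWE implementation-vs-enumeration sweep
covers every genotype triple up to n = 50 in the test suite.

# Known limitations

* The pipeline analyses autosomal biallelic dosages; X-chromosome dosage
  coding, sex checks and ancestry assignment are out of scope.
* Relatedness is handled by pruning, not by mixed models; family-based
  designs need the latter.
* The stepwise selection requires individual-level genotypes; a
  summary-statistic-only mode with external LD is not provided.
* In-sample LD scores are the right choice for synthetic panels but
  carry the usual caveats when the association sample is small or
  structured.
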