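---
title: "Gene-environment interaction scanning: models, screens, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-environment interaction scanning: models, screens, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxescreen)
```

## The problem

Case-control consortia routinely ask whether a binary exposure — here,
diabetes status in relation to colorectal cancer risk — has an effect that
is modified by common genetic variants, and whether aggregates of rare
variants interact with the exposure. `gxescreen` implements the full
analysis surface such a study needs: per-variant interaction and joint
tests, a two-step screening procedure that spends the multiple-testing
budget where the data suggest interactions are likely, stratified
odds-ratio displays for interpreting hits, random-effects meta-analysis of
the exposure main effect across studies, genomic-control diagnostics,
variant QC, and a rare-variant set test. Because consortium-scale
individual-level data cannot ship with a package, a synthetic multi-study
generator with fully known ground truth drives every test.

## Single-variant models

All single-variant inference is built on a logistic disease model. With
disease $D$, exposure $E$, dosage $G \in [0,2]$ counting the alternate
allele, and adjustment covariates $\mathbf{Z}$ (age at baseline, sex,
study/genotyping platform as one factor, three principal components;
optionally BMI as "covariate set 2"):

$$\operatorname{logit} P(D = 1) = \beta_0 + \beta_G G + \beta_E E +
\beta_{G\times E}\, G E + \boldsymbol\gamma' \mathbf{Z}.$$

* **1-d.f. interaction test** — Wald test of $\beta_{G\times E}$.
  Wald is the genome-scan convention (one fit per variant); a
  likelihood-ratio version is available (`method = "lrt"`) and the two
  agree within a few percent of the statistic at the sample sizes where
  either is trusted.
* **Marginal genotype-disease test** — Wald test of $G$ in
  $\operatorname{logit} P(D) \sim G + \mathbf{Z}$.
* **Genotype-exposure association** — Wald test of $G$ in
  $\operatorname{logit} P(E) \sim G + \mathbf{Z}$, fitted on cases and
  controls pooled.
* **2-d.f. joint test** — likelihood ratio of the full model against
  $\operatorname{logit} P(D) \sim E + \mathbf{Z}$, testing
  $(\beta_G, \beta_{G\times E})$ simultaneously. The LRT is used here
  (rather than Wald) because the joint test is run once per variant anyway
  and the LRT behaves better when one component is near the boundary of
  detectability.
* **3-d.f. joint test** — the sum of the three 1-d.f. chi-squares
  (marginal, genotype-exposure, interaction) referred to $\chi^2_3$. The
  three components are asymptotically independent under the global null
  (the exposure model and the disease models involve different outcomes),
  and the calibration suite verifies the resulting p-values are uniform
  under the full null. Summation of independent 1-d.f. components is the
  canonical construction for this test; no other published formula was
  available to reproduce.

Dosages are modelled as continuous covariates, as is standard for imputed
genotypes. Monomorphic variants, collinear product terms and separated
fits are *flagged per row*, never raised, so a scan always completes.

The fitter itself is a dependency-free iteratively reweighted least
squares routine (`fit_logistic`) with convergence declared when the
largest score component drops below $10^{-8}$ or the relative
log-likelihood change falls below $10^{-10}$ (cap: 100 iterations).
Rank-deficient designs raise an error naming the collinear columns.
Separation is detected by a diverging linear predictor (|logit| > 20 —
fitted probabilities indistinguishable from 0/1 at double precision well
before that point); such fits are returned flagged non-converged. The test
suite pins the fitter against closed forms, `glm`, and a dense grid search
of the likelihood on a 12-subject dataset.

## Two-step screening

Testing millions of interactions at $5\times10^{-8}$ wastes power. The
two-step screen ranks variants in step 1 by a statistic *independent of
the interaction test under the null* — by default the EDGE statistic, the
sum of the marginal genotype-disease and genotype-exposure chi-squares on
2 d.f. (the pure marginal or pure exposure-association filters are
options, since both component screens are legitimate) — then tests the
interaction p-value in step 2 against bin-specific thresholds.

Bins follow the weighted hypothesis testing scheme: bin $k$ holds the next
$B \cdot 2^{k-1}$ variants by step-1 rank and receives budget
$\alpha/2^k$, so its per-test threshold is $(\alpha/2^k)/(B\,2^{k-1})$.
The spent budget is $\alpha(1/2 + 1/4 + \dots) < \alpha$ at any depth,
which the code asserts for every schedule it builds. A truncated final bin
keeps its full-size denominator (conservative). Ties in step-1 p-values
are broken by genomic position so schedules are deterministic. The
first-bin size defaults to $B = 5$; the constant is a tuning parameter of
the screen, not an estimate, and is exposed in the API.

Correlated variants should not multiply the correction. When LD
information is available (a genotype reference, or precomputed group
labels), members of a bin that fall in the same single-linkage cluster at
$r^2 \ge 0.2$ count once: each bin's denominator is reduced by the number
of LD-redundant members. With mutually independent variants this reduces
exactly to the raw-count schedule, and a Monte-Carlo suite verifies the
family-wise error rate stays at or below $\alpha$ under a correlated-variant
null. This effective-count construction is this package's own design; the
published description of the LD adjustment it emulates lives in
supplementary material that is not reproduced here, so the implementation
is documented as a faithful-in-spirit reimplementation, not a reproduction.

When several testing approaches run as parallel primary families
(1-d.f., two-step, 3-d.f.), the family-wise rate is split evenly:
`apply_fwer_split(3)` gives $0.05/3$ per family, alongside the fixed
$5\times10^{-8}$ genome-wide threshold used for a secondary joint-test
scan.

## Genomic control

`genomic_lambda` is the median observed 1-d.f. chi-square divided by
0.4549364, the $\chi^2_1$ median (fixed as a constant so results do not
depend on quantile-routine details). Because $\lambda$ scales with sample
size, `lambda_1000` rescales it to an equivalent 1000-case/1000-control
study:

$$\lambda_{1000} = 1 + (\lambda - 1)\,
\frac{1/n_{\text{cases}} + 1/n_{\text{controls}}}{2/1000},$$

an affine contraction toward 1 for any study larger than 1000/1000. QQ
data are emitted as points (expected quantiles $-\log_{10}((i-0.5)/m)$)
for any plotting layer; no rendering is included by design.

For presentation of joint-test results it is standard to remove variants
that merely tag known susceptibility loci: `prune_known_loci` drops a
variant only when it is both within ±2 Mb of an anchor *and* correlated
with it at $r^2 > 0.2$, with LD estimated from a control-genotype
reference. Both conditions are required; a variant near an anchor but
uncorrelated with it survives.

## Meta-analysis of the exposure main effect

Each study is analysed separately (`logit(D) ~ E + covariates` within
study; no study term) and combined by random-effects meta-analysis with
the Hartung-Knapp adjustment: weights $1/(se^2 + \tau^2)$, pooled variance
$\sum w(\hat\theta_s - \hat\theta)^2 / ((k-1)\sum w)$, and a $t_{k-1}$
reference for the interval and p-value. The between-study variance uses
the DerSimonian-Laird moment estimator truncated at zero — the standard
pairing beneath Hartung-Knapp; the methodology this reimplements names
only the Hartung-Knapp adjustment, so the $\tau^2$ estimator is a
documented choice here. Cochran's $Q$, its $\chi^2_{k-1}$ p-value and
$I^2 = \max(0, (Q - (k-1))/Q)$ (negative values truncated) are attached.
Studies that cannot support the model (no cases, constant exposure, an
empty exposure-by-status cell) are excluded and logged. The test suite
cross-checks every quantity against `metafor::rma(method = "DL",
test = "knha")` and verifies nominal interval coverage in a 48-study
simulation with heterogeneity near $I^2 = 0.48$.

Funnel data (`funnel_points`) are emitted as effect-versus-precision
pairs; a study is flagged as outlying when its standardized deviation
from the pooled estimate, using $\sqrt{se^2 + \tau^2}$, exceeds 3 — a
simple, documented rule intended to prompt sensitivity analysis rather
than automate exclusion.

## Rare-variant set-by-exposure tests

For a set of variants with MAF below 1% the package follows the
mixed-effects score test construction. With burden
$B_i = \sum_j G_{ij}$ (unweighted by default; Madsen-Browning-style
$1/\sqrt{\text{MAF}(1-\text{MAF})}$ weights optional — the weighting is a
documented default, not an inference from any source):

* **fixed component** — score test of the burden-by-exposure coefficient
  in `logit(D) ~ burden + E + burden:E + covariates`;
* **random component** — per-variant interaction effects are modelled as
  mean-zero random effects; with null-model residuals $r$ (the null holds
  the main effects *and* the fixed burden-by-exposure term) and $S$ the
  matrix of per-variant $G_j E$ columns, the statistic is
  $Q = \lVert S'r \rVert^2$ with null distribution
  $\sum_i \lambda_i \chi^2_1$, $\lambda_i$ the eigenvalues of $S'PS$
  ($P$ the covariance of the residuals after projecting out the null
  design);
* **combination** — Fisher's method,
  $X = -2(\ln p_{\text{fixed}} + \ln p_{\text{random}})$ on $\chi^2_4$.
  Fisher's product assumes the components are independent; the hierarchical
  method it emulates accounts for dependence, so this is a simplification —
  the calibration suite shows the combined stream is uniform under the
  null in the regimes tested.

The mixture tail is computed by a two-moment Satterthwaite match by
default, with a four-moment (Liu-Tang-Zhang) option and an exact
characteristic-function inversion (Imhof) used as the oracle. The Imhof
integrand oscillates with phase speed bounded by $(q + \sum\lambda)/2$;
integrating piecewise over sub-intervals no longer than one period makes
the quadrature reliable, and the implementation was validated against
direct Monte-Carlo simulation of the mixture. On random Gram-matrix
spectra in the moderate tail (p between roughly 0.03 and 0.6) the
Satterthwaite approximation tracks the exact inversion within a 15%
relative bound, which the suite asserts on 50 random instances; far-tail
p-values should use `method = "imhof"`.

A practical small-sample caveat: with a rare exposure (10% prevalence)
and MAF < 1%, the exposed-carrier cells of a small simulated cohort are
nearly empty and the random component's asymptotic null is unreliable.
Calibration tests therefore run at exposure prevalence 0.3 and a few
hundred cases — the point is to verify the statistic's null law where the
asymptotics apply, not to hide the sparsity issue, which at true
consortium scale (tens of thousands of subjects) does not arise.

With 25,000 sets scanned, the conventional suggestive threshold is
$0.05/25{,}000 = 2\times10^{-6}$.

## The synthetic cohort generator

`simulate_cohort` emulates a multi-study nested case-control design:

* **genotypes** — two latent-Gaussian haplotypes per subject, thresholded
  at $\Phi^{-1}(\text{MAF})$, so Hardy-Weinberg proportions hold
  marginally; an exchangeable within-block correlation (`ld_rho`,
  `ld_block_size`) on the latent scale induces LD blocks. Optional
  truncated-Gaussian jitter (clipped to $[0,2]$, default off) mimics
  imputed continuous dosages.
* **exposure** — logistic in the causal-variant dosage with slope
  `gamma_ge`; the intercept is solved numerically so the marginal
  prevalence matches `exposure_prevalence` (default 0.10, a typical
  population diabetes prevalence).
* **disease** — logistic with `beta_g`, `beta_e`, `beta_gxe` on the
  causal variant and exposure plus covariate effects; `beta_e` defaults
  to $\log 1.36$, the kind of moderate exposure main effect this design
  targets, and `beta0 = -2.2` puts the source-population risk near 10%.
* **sampling** — each study oversamples its source population in batches
  and keeps cases and controls until its quotas are met exactly
  (frequency matching; individual matching ratios are deliberately not
  modelled). Unattainable quotas fail loudly, naming the study.
* **covariates** — age $\sim N(60, 10^2)$, sex $\sim$ Bernoulli(0.5),
  three standard-normal principal components, study as a categorical
  label.

Only the designated causal variant carries genetic effects and the
genotype-exposure association; all other variants are null and
exposure-independent. That isolates exactly the structure the EDGE screen
and the 3-d.f. test exploit, and makes every downstream power and
calibration claim checkable. The generator does *not* attempt realistic
human LD maps, imputation error beyond dosage jitter, age-at-onset
structure, or exposure misclassification — so passing tests demonstrate
correctness of the statistics under the stated generative model, not
robustness to those real-data complications.

`simulate_rare_geneset` adds independent rare genotypes (MAF drawn inside
a configurable interval bounded above by 0.01) for an existing cohort.
Under the null architecture the cohort's disease status is untouched, so
set tests are null by construction; under the homogeneous
burden-by-exposure or heterogeneous (mean-zero per-variant) architectures
the status is redrawn with the corresponding interaction terms, providing
ground truth for power comparisons. Returning the redrawn cohort
alongside the dosages keeps the generator free of hidden state.

## Variant QC

`qc_filter_variants` applies, in order: call rate (default minimum 0.95;
platforms in the emulated setting used 95-98%, so the bound is
configurable up to 0.98), Hardy-Weinberg equilibrium (exact conditional
test on hard-called genotypes, controls only when status is supplied,
failing below $10^{-4}$), imputation $R^2$ (failing below 0.8), and the
common-variant MAF bound (1%). All thresholds are strict inequalities in
the failing direction, and each removed variant is attributed to the
first rule it fails so the report's reason counts sum to the number
removed. The HWE test enumerates the conditional distribution of
heterozygote counts given allele counts and sums the probabilities of
configurations no more probable than the observed one; unit tests pin it
to hand enumeration on small counts.

## Numerical and interface choices

* Coordinates are 1-based (VCF convention); the ±2 Mb pruning window is
  inclusive at both ends.
* Dosage files are VCF with a per-sample `DS` FORMAT field (the open
  equivalent of the binary dosage format used by consortium pipelines);
  records without `DS` fall back to `GT` hard calls with a warning, and
  multi-allelic records are skipped and counted. Imputation quality rides
  in the INFO `R2` key.
* Phenotypes are a header-driven TSV (`id`, `status`, exposure column,
  covariates); subjects with missing exposure are dropped and counted,
  since they cannot enter any interaction model.
* Genotype strata for display tables are formed by rounding dosages to
  the nearest integer while regression always uses the continuous dosage.
* Fixed seeds make every generator bit-reproducible; all simulation
  entry points take explicit seeds.
* Problem sizes in the test and acceptance suites (a 2,000-variant null
  scan at 1,000 subjects, 500-replicate error-rate runs at 600 subjects,
  30-replicate coefficient recovery at 30,000 subjects) were chosen as
  the smallest designs whose Monte-Carlo error is comfortably below the
  margins being asserted.

## Known limitations

* The Wald 1-d.f. test is anti-conservative in tiny strata (the usual
  small-sample behaviour); the LRT option is preferable below a few
  hundred subjects.
* The two-step LD adjustment is an effective-count construction, not a
  reproduction of any specific published supplementary procedure.
* Fisher's combination assumes independent components; dependence between
  the burden and variance-component tests is not modelled.
* The generator's LD model is exchangeable within blocks — adequate for
  testing LD-aware error control, not a human LD map.
* Site-specific analyses, survival outcomes, ordinal exposures and
  genotype imputation itself are out of scope.
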