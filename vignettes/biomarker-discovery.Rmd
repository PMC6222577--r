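---
title: "Nominating circulating biomarkers from a mouse strain panel"
author: "panelmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating circulating biomarkers from a mouse strain panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelmark)
```

## The problem and the approach

Circulating biomarkers for heart failure are usually sought directly in
human cohorts, where disease heterogeneity and uncontrolled environment
blur the signal. An alternative is to screen in a reference panel of
inbred mouse strains: every strain is genetically fixed, environment and
intervention are controlled, and both heart tissue and plasma are
accessible at the endpoint. The screening logic implemented here has
four stages:

1. **Differential expression.** Compare cardiac transcript levels
   between a treated arm (chronic β-adrenergic stimulation with
   isoproterenol, which induces heart-failure-like remodeling) and a
   control arm, across the whole panel, using an empirical-Bayes
   moderated t-statistic.
2. **Trait correlation.** Correlate strain-level endpoint expression
   with the per-strain change in left ventricular internal dimension in
   diastole (ΔLVIDd, mm), an echocardiographic surrogate of adverse
   remodeling.
3. **Overlay.** Intersect the symbol-level top lists from stages 1 and
   2. Genes that respond to the intervention *and* track the severity
   trait are biomarker candidates; established markers are flagged but
   kept.
4. **Confirmation.** Check candidates for directional concordance in a
   human failing-vs-non-failing heart differential-expression table,
   and validate a candidate's plasma levels in a case-control cohort
   with logistic regression.

A synthetic-data module generates strain-panel and cohort data with
known ground truth so every stage is testable without any external
download.

## Differential expression: the moderated t

For probe $g$ with treated/control means $\bar y_{g1}, \bar y_{g0}$ and
pooled residual variance $s_g^2$ on $d_g$ degrees of freedom, the
log2 fold change is $\hat\beta_g = \bar y_{g1} - \bar y_{g0}$ and the
moderated statistic is

$$\tilde t_g = \frac{\hat\beta_g}{\tilde s_g\,u}, \qquad
\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

with $u = \sqrt{1/n_1 + 1/n_0}$, referred to a t distribution on
$d_0 + d_g$ degrees of freedom. The prior $(d_0, s_0^2)$ is estimated
by closed-form moment matching of $\log s_g^2$ against a scaled-F
distribution: writing $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,
the excess of the sample variance of $e_g$ over
$\mathrm{mean}\,\psi'(d_g/2)$ equals $\psi'(d_0/2)$, inverted
numerically (Newton on the trigamma function). Two limits anchor the
estimator and are asserted in the tests: $d_0 = 0$ reproduces the
ordinary two-sample t-test exactly, and $d_0 \to \infty$ pools every
probe to the common variance $s_0^2$.

When the observed $\log s_g^2$ are *under*-dispersed relative to any
finite prior (the moment equation has no positive solution), the
correct limit is $d_0 = \infty$, i.e. complete pooling — not the
no-shrinkage limit — and that is what the estimator returns. This
situation arises routinely in our own simulations, which draw all
probes with a common noise SD. The no-shrinkage fallback is reserved
for genuinely degenerate inputs (fewer than three probes with positive
residual df).

Multiple testing uses the Benjamini–Hochberg step-up procedure, written
out in the package and property-tested against an independent
brute-force step-up and against `stats::p.adjust`. Top tables are
sorted by $|\mathrm{logFC}|$ descending (ties by raw p, then probe id),
matching how such tables are conventionally printed; p-based ordering
is available. The whole stage is cross-checked against
`limma::lmFit`/`eBayes` in the test suite — limma is an oracle there,
never the implementation.

## Trait correlation

Endpoint expression is summarized to strain means within the treated
arm (configurable), joined to the trait table pairwise-complete on
strain id, and correlated per probe. The two-sided p-value uses the
exact-null t transform $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df;
Spearman is Pearson on midranks with the same transform. Zero-variance
probes are reported with $r = 0$, $p = 1$ and a degenerate flag rather
than dropped.

The packaged reference table of top trait-correlated probes prints
(r, p) pairs but not the number of strains behind them. Treating $n$
as a free integer and scanning, a single value near 90 reproduces all
47 printed pairs to printed precision (root-mean-square error on
log p about 1.5%), and also the three in-text marker correlations.
The test suite asserts this consistency without claiming the exact
panel composition, which is not recoverable from the printed tables.

## Overlay and candidate records

Default top-list thresholds are $|\mathrm{logFC}| \ge 1$ with adjusted
$p < 0.05$ for the DE list and correlation $p < 10^{-3}$ for the trait
list; both reproduce the packaged tables' contents exactly and both are
overridable. Probe-to-symbol collapse keeps the probe with the extreme
statistic (symbol-mean collapse is available). Novelty is a *flag*
controlled by a user-supplied known-marker list (default: Nppb, Timp1,
Lgals3, Spp1) — flagged records are never removed, so no information is
destroyed by the novelty annotation. On the packaged tables the overlay
yields {Spp1, Cdo1, Gpnmb}, of which {Cdo1, Gpnmb} are novel under the
default marker list.

## Cross-species concordance

Mouse symbols map to human symbols by the uppercase convention, with a
two-column ortholog table overriding individual symbols whose human
ortholog carries a different name. A candidate is *concordant* when the
human gene is significant at level α (default 0.05, on whatever p
column the caller supplies) with the same fold-change sign,
*discordant* when significant with the opposite sign, *not significant*
when present but above α, and *absent* when unmapped or missing. The
fourth status exists because a three-way partition cannot classify a
gene that is present but non-significant — exactly the situation of the
natriuretic-peptide transcript in the packaged human table. Linear fold
changes can be declared as such and are log2-transformed before sign
comparison.

## Cohort statistics

The validation stage needs only standard statistics, but in forms not
all exposed by base R, so they are implemented against explicit
contracts and cross-checked against `stats::t.test`,
`stats::fisher.test`, `stats::cor.test` and `stats::glm` in the tests:

* **t-tests from summaries.** Published comparisons often give only
  mean ± SD and n. `tTestSummary` applies the pooled or Welch formula
  to summaries and is identically equal to the raw-data test when the
  summaries come from the same data (asserted to 1e-12). The pooled
  form is the default because it reproduces the published mouse plasma
  comparisons under equal-n assumptions (p ≈ 0.007 at 10/arm, which
  assumes an unprinted control n; p ≈ 0.13 at 6/arm); Welch is used for
  the human comparison, where group SDs differ visibly and either
  scale convention leaves p far below the reported 0.0001 bound.
* **Fisher exact.** Probability-mass two-sided rule (sum of
  hypergeometric probabilities ≤ the observed table's), with the
  double-one-sided rule available; exhaustively verified against full
  enumeration for all tables with margins ≤ 12.
* **Spearman.** Pearson on midranks with the t transform.
* **Logistic regression.** Newton/IRLS with a step-halving line search
  (the log-likelihood trace is non-decreasing by construction and
  asserted in tests), SEs from the inverse observed information, Wald
  95% intervals $\exp(\hat\beta \pm 1.959964\,\mathrm{se})$,
  convergence declared at max |score| < 1e-8 within 50 iterations, and
  explicit quasi-separation detection (pinned fitted probabilities with
  diverging coefficients) that flags the fit non-converged instead of
  reporting silently. On a 2×2 design the fitted OR equals the
  cross-product ratio ad/bc exactly.

`runCohortAnalysis` assembles the published report layout: baseline
comparisons, univariate fits per variable, a multivariate fit with the
standard covariate set (age, BMI, hypertension, diabetes, eGFR, LDL-C),
a biomarker+age sensitivity fit, and a Spearman correlation with proBNP
when that column exists. The biomarker enters on the raw ng/mL scale by
default (the published odds ratios are per-unit on the measurement
scale); the log scale is available and the choice is recorded in the
report.

## The synthetic-data generator

The generator's defaults are the study conditions the package emulates,
chosen once and kept:

* **Panel:** 91 strains, paired control/treated arms, 2 replicates per
  strain and arm (replicate counts are unpublished for such panels;
  2/arm is a generator default, not a claim about any real panel),
  Gaussian noise with SD 0.5 on the log2 scale, baseline probe means
  uniform on 5–12 (the range of printed average expressions). Planted
  treatment effects are 1–2 log2 units with mixed signs, the magnitude
  range of the printed top table. Optional per-strain random baseline
  shifts are off by default — no variance components are published for
  the emulated data, and the simplest structure consistent with
  log-intensity microarray conventions is a single residual term.
* **Trait:** a noisy linear function of the strain-mean treated
  expression of the trait-linked probes,
  $T_s = a + \sum_j w_j (m_{js} - E[m_{js}]) + \varepsilon_s$ with
  $\varepsilon_s \sim N(0, 0.5\,\mathrm{mm})$. Weights are solved from
  requested per-probe population correlations $r_j$ via
  $w_j = r_j \sigma_t / \sqrt{v (1 - \sum_k r_k^2)}$, where $v$ is the
  strain-mean sampling variance, so the *realized* |r| lands in the
  0.30–0.45 band of the printed correlation table. The identity
  requires $\sum r_j^2 < 1$, which the configuration validator
  enforces. Explicit weights bypass the scaling (used by the noise-free
  limit test, where a single unit-weight probe with zero trait noise
  gives r = 1 exactly).
* **Cohort:** 119 cases / 270 controls by default, mirroring the
  emulated case-control ascertainment: labels are fixed first and the
  biomarker and covariates are drawn conditionally on group. The
  biomarker is lognormal (natural-scale mean 1.20 ng/mL, SD 0.26 in
  controls; 0.74, SD 0.40 in cases — lower in cases), and covariate
  group-distributions are set so that all published effect directions
  hold (cases older, heavier, more hypertensive and diabetic, lower
  eGFR, lower LDL-C); magnitudes are realistic values for an elderly
  male population cohort, since individual-level parameters are not
  published. The recorded truth uses the Gaussian discriminant identity
  $\beta = \Delta\mu/\sigma^2$ for continuous covariates and the log
  odds ratio of prevalences for binary ones. A second, *prospective*
  mode draws covariates from a population and assigns case status
  through the logistic model itself; it exists because only under
  prospective sampling is a planted odds ratio exactly the true
  logistic parameter, which is what a Wald-coverage study must target.

One global seed drives everything; sub-generators receive
deterministically split seeds (a Lehmer multiplicative step), so a
fixed seed gives bit-identical output and panel and cohort streams stay
independent.

What the generator does **not** emulate: probe cross-hybridization,
batch and array-normalization artifacts, strain relatedness (kinship),
non-Gaussian expression noise, and covariate correlation structure
beyond group-conditional independence. Passing calibration tests on
these synthetic data therefore demonstrates correctness of the
*statistics*, not robustness to every failure mode of real microarray
or cohort data.

## Numerical choices and degenerate inputs

* Trigamma inversion by Newton iteration, tolerance 1e-8; prior
  estimation falls back to $d_0 = \infty$ (pooling) for under-dispersed
  variances and errors out only when all variances are zero.
* BH adjustment enforces monotonicity by a cumulative minimum from the
  largest rank down; outputs are capped at 1 and are elementwise ≥ the
  input.
* Correlation p-values clamp |r| to 1 before the t transform; |r| = 1
  maps to p = 0.
* Fisher's probability-mass rule compares probabilities with a 1e-7
  relative tolerance to avoid floating-point ties splitting the
  support.
* Logistic separation heuristic: any fitted probability within 1e-8 of
  0/1 together with max |β| > 15 flags separation; a singular
  information matrix does the same.
* The pipeline runner skips stages whose inputs are absent and logs the
  skip; any stage contract violation aborts with the stage named.

## Problem sizes in the checks

The packaged test-and-acceptance workload uses desk-scale sizes chosen
as the package's own verification conditions: null calibration on a
91-strain, 5000-probe panel; fold-change recovery over 100–200
simulated panels of 10–120 probes; Wald coverage over 300–500 fits at
n = 1000; candidate recovery over 40 panels of 120 probes. At these
sizes the whole suite runs in about a minute on one core.

## Known limitations

* Symbol-level cross-species mapping by name is a heuristic; genes
  whose orthologs differ by name are silently *absent* unless an
  ortholog table is supplied.
* The overlay is a set intersection, not a rank-aggregation statistic;
  no significance is attached to the intersection itself.
* The published top tables do not disambiguate raw from adjusted
  p-values; the packaged fixtures store the printed numbers as
  `p_value` and leave `p_adj` empty rather than guessing, and no
  acceptance check compares p-values from those tables.
* Case-control truth for the lognormal biomarker is recorded on the
  log scale (the scale on which the group-conditional model is
  Gaussian); raw-scale odds ratios from such data are approximations,
  which is why coverage studies use the prospective mode.
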