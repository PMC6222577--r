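# panelmark

Candidate circulating-biomarker discovery from an inbred mouse strain
panel, with human confirmation and case-control validation statistics.

## The scientific problem

Screening for heart-failure biomarkers directly in human cohorts is
confounded by disease heterogeneity and uncontrolled environment. A
systems-genetics alternative screens in a reference panel of inbred
mouse strains: treat every strain with a remodeling stimulus (chronic
isoproterenol), profile the cardiac transcriptome at the endpoint, and
nominate as candidates the genes that are both

1. **differentially expressed** between treated and control arms
   (panel-wide, empirical-Bayes moderated t), and
2. **correlated** across strains with the severity trait — the change
   in left ventricular internal dimension in diastole (ΔLVIDd, mm).

Candidates are then checked for directional **concordance** in a human
failing-vs-non-failing heart differential-expression table, and a
candidate's plasma levels are validated in a case-control cohort with
univariate and multivariate **logistic regression** (odds ratios with
Wald 95% intervals).

The statistical core, all authored in the package and cross-checked
against independent oracles in the tests:

* moderated t: t̃_g = β̂_g / (s̃_g·u) with
  s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), the prior (d₀, s₀²) estimated
  by closed-form moment matching of log s²_g to a scaled-F
  distribution; Benjamini–Hochberg step-up FDR adjustment;
* trait correlation with p from t = r·√((n−2)/(1−r²));
* pooled/Welch t-tests from raw data *or* published group summaries,
  Fisher exact (probability-mass two-sided rule), Spearman on midranks;
* Newton/IRLS logistic regression with step-halving, observed-information
  SEs, Wald CIs exp(β̂ ± 1.959964·se), and explicit separation
  detection.

A synthetic-data module simulates the whole study — paired strain-panel
expression with planted log2 fold changes, a trait built as a noisy
linear function of selected transcripts with known population
correlations, and a case-control biomarker cohort with planted effects
— so every stage is tested against known ground truth, offline.

## Worked example

The packaged reference tables (top differentially expressed probes and
top trait-correlated probes from a 91-strain isoproterenol panel, plus
a four-gene human heart-failure DE summary) drive the demonstration:

```r
library(panelmark)
runDemo()
#> Candidates (DE x trait-correlation overlay):
#>  symbol     de_probe   corr_probe logFC    cor de_direction corr_direction novel
#>    Spp1 ILMN_2690603 ILMN_2690603  1.31  0.374           up            pos FALSE
#>    Cdo1 ILMN_2975345 ILMN_2975345  1.17 -0.370           up            neg  TRUE
#>   Gpnmb ILMN_2648669 ILMN_2614655  1.61  0.363           up            pos  TRUE
#>
#> Novel candidates: Cdo1, Gpnmb
#>
#> Concordance vs human heart-failure DE:
#>  symbol human_symbol human_logFC human_p     status alpha
#>    Spp1         SPP1          NA      NA     absent  0.05
#>    Cdo1         CDO1          NA      NA     absent  0.05
#>   Gpnmb        GPNMB       0.263 2.9e-06 concordant  0.05
```

Three genes survive the overlay of the two top lists; Spp1
(osteopontin) is flagged as an established marker, leaving Cdo1 and
Gpnmb as novel candidates. Gpnmb is up-regulated by isoproterenol
(logFC 1.61), positively correlated with ventricular dilation
(r = 0.363), and concordantly up-regulated in failing human hearts
(logFC 0.263, p = 2.9e-6) — the profile of a credible candidate.

Validation-style statistics work from published group summaries alone:

```r
tTestSummary(5.96, 2.66, 10, 3.18, 1.08, 10, method = "pooled")
#> Two-sample t-test (pooled): t = 3.062, df = 18, p = 0.006712
```

And the full pipeline runs on simulated data with known truth:

```r
sim <- simulatePanel(panelSimConfig(n_strains = 91, n_probes = 200,
                                    seed = 42))
de <- runDE(sim$panel, sim$annotation)
head(de[, c("probe_id", "symbol", "logFC", "AveExpr", "t_mod", "p_adj")], 3)
#>          probe_id   symbol     logFC   AveExpr     t_mod         p_adj
#> 1 ILMN_SIM_000001 Gene0001  1.836601  8.825131  35.04959 7.910925e-267
#> 2 ILMN_SIM_000016 Gene0016 -1.835347  4.940256 -35.02564 9.159762e-267
#> 3 ILMN_SIM_000009 Gene0009  1.629153 10.725562  31.09066 2.147315e-210
```

The top probes are exactly the planted ones (`sim$truth$planted_logfc`
holds the true effects, here ±1.6–1.9 log2 units recovered within
sampling error).

A thin command-line wrapper with `simulate | de | correlate | overlay |
concord | cohort | run-all | demo` subcommands ships in
`inst/scripts/panelmark.R`; `runAll()` drives the same stages from a
YAML configuration and writes a manifest (package version, seed, config
hash, stage log) next to the outputs.

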