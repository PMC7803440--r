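# bpmr — two-sample Mendelian randomization of blood pressure on atrial fibrillation

`bpmr` is an R package for estimating the causal effect of blood
pressure (BP) on atrial fibrillation (AF) risk from GWAS summary
statistics, and for estimating the AF effect of BP lowering through
the protein targets of antihypertensive drug classes. It is aimed at
cardiovascular genetic epidemiologists who work with summary-level
data: it ingests exposure and outcome association tables, builds
approximately independent instruments, and reports causal odds ratios
per 10-mmHg BP increment with pleiotropy-robust sensitivity analyses.

## The statistical core

For variant $j$, let $\hat\gamma_j$ (SE $\sigma_{xj}$) be its effect
on BP in mmHg per allele and $\hat\Gamma_j$ (SE $\sigma_{yj}$) its
log-odds effect on AF, harmonized to the same effect allele. The
per-variant Wald ratio is
$\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$. The primary estimator is
inverse-variance weighted (IVW) regression of $\hat\Gamma_j$ on
$\hat\gamma_j$ through the origin with weights $\sigma_{yj}^{-2}$ and a
multiplicative random-effects standard error inflated by
$\max\{1, \sqrt{Q/(J-1)}\}$, where $Q$ is Cochran's heterogeneity
statistic. Sensitivity estimators: the weighted median (interpolating
the inverse-variance-weighted ordered ratios at the 50% point, SE by
parametric bootstrap) and MR-Egger regression (weighted fit *with*
intercept after orienting exposure effects positive; the intercept is
the directional-pleiotropy bias test). Effects are reported as
$\mathrm{OR} = e^{10\hat\theta}$ per 10 mmHg.

Supporting metrics: per-variant variance explained
$R^2 = \beta^2/(\beta^2 + N\,se^2)$ (the MAF factor of the full
formula cancels), instrument strength $F = R^2(N-2)/(1-R^2)$, and an
analytic approximation of the bias and type-I error induced by
exposure–outcome sample overlap,
$\mathrm{bias} = \rho \cdot \log(\mathrm{OR}_{obs})/10 \,/\, E[F]$.

Instrument construction follows the standard pipeline: genome-wide
selection ($P < 5\times10^{-8}$), greedy LD clumping ($r^2 < 0.001$
within 10 000 kb for the BP traits; $r^2 < 0.1$ for drug-target gene
regions), and allele harmonization with frequency-based orientation of
palindromic variants. Drug-class proxies come by two independent
routes: variants inside target-gene regions, and GTEx-style best
eQTLs validated by expression→SBP MR at $P < 0.05$.

A synthetic-data module simulates paired exposure/outcome summary
statistics (with LD blocks, pleiotropy, and overlap-correlated
sampling errors) at the scale of the source GWAS — exposure
N = 757,601; outcome 65,446 cases / 522,744 controls; ~4% of exposure
variance across 400 instruments with mean F near 75 — so the entire
pipeline runs and is validated without downloading anything.

## Worked example

```r
library(bpmr)

# simulate one SBP-like study with a true OR of 1.17 per 10 mmHg
pair <- generate_summary_pair(synth_config(n_snps = 400, seed = 1))
report <- run_primary_analysis(analysis_config(list(
  exposures = list(SBP = pair$exposure),
  outcome   = pair$outcome,
  ld        = pair$ld)))
report
#> Primary MR report: 1 trait(s), 0 error(s)
#>  exposure             method n_snp or_per_10 ci_or_low_10 ci_or_high_10 pvalue
#>       SBP ivw_random_effects   206     0.982        0.639          1.51  0.934
#>       SBP    weighted_median   206     0.822        0.420          1.61  0.569
#>       SBP        egger_slope   206     0.917        0.292          2.89  0.882
#>       SBP    egger_intercept   206        NA           NA            NA  0.899
```

206 of the 400 simulated variants pass genome-wide significance and
survive clumping/harmonization; each method then reports its odds
ratio per 10-mmHg SBP increase with a 95% CI. A single simulated
study at the default (unit-variance) noise scale is deliberately
noisy — the planted OR of 1.17 lies inside every interval, and the
Egger intercept p-value of 0.9 correctly finds no directional
pleiotropy. Averaged over 500 replicates (the calibration study in
`tests/testthat/test-acceptance.R`), the IVW estimate centres on the
planted effect with 95%-CI coverage of 0.958.

```r
report$strength
#>  trait n_variants total_r2 mean_f min_f max_f
#>    SBP        206   0.0369    136  30.8   980

overlap_bias(overlap_scenario(
  n_exposure = 757601, n_cases = 65446, n_controls = 522744,
  overlap_fraction = 1, observational_or_per_10 = 1.6,
  instrument_r2 = 0.04, n_instruments = 399))[, 1:4]
#>       bias type1_error expected_f  se_iv
#>   0.000594      0.0501       79.1 0.0207
```

The overlap diagnostic says: even if every exposure-GWAS participant
were also in the outcome GWAS, an observational OR of 1.6 per 10 mmHg
would bias the per-mmHg MR estimate by only ~0.0006 log-odds, leaving
the nominal 5% test essentially calibrated (0.050) — sample overlap is
immaterial at these instrument strengths.

Drug-target analyses run analogously via
`run_drug_target_analysis()` with a region catalog (BED-like TSV) and
an eQTL catalog; results are odds ratios per 10-mmHg SBP *decrease*,
so protective classes appear below 1. `plot_mr_forest()` and
`autoplot()` draw forest and scatter summaries. A thin command-line
wrapper with `primary`, `drug-target`, `overlap-bias` and `simulate`
subcommands lives at `inst/cli/bpmr.R`.

See the vignette
(`vignettes/bp-af-mendelian-randomization.Rmd`) for the full model
description, parameter choices and limitations.

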