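---
title: "Two-sample Mendelian randomization of blood pressure on atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization of blood pressure on atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpmr)
library(dplyr)
```

## The question and the design

Hypertension is observationally the single largest contributor to the
population burden of atrial fibrillation (AF), but observational
associations are vulnerable to confounding and reverse causation, and
antihypertensive drug trials have given inconsistent answers about AF
prevention. Two-sample Mendelian randomization (MR) sidesteps much of
this: genetic variants associated with blood pressure (BP) are
allocated at conception, so, under the instrumental-variable
assumptions, the association between BP-raising alleles and AF risk
estimates the causal effect of BP on AF. "Two-sample" means only GWAS
summary statistics are needed — one GWAS for the exposure (systolic,
diastolic or pulse pressure, in mmHg) and an independent case-control
GWAS for AF (log-odds scale).

`bpmr` implements this design end to end: instrument construction
(genome-wide selection, LD clumping), exposure-outcome harmonization,
the causal estimators, instrument-strength and sample-overlap
diagnostics, drug-target proxy analyses for antihypertensive classes,
and a synthetic summary-statistics generator that lets every stage run
and be validated without any data download.

## Models and estimators

Write $\hat\gamma_j$ (SE $\sigma_{xj}$) for variant $j$'s per-allele
effect on the exposure and $\hat\Gamma_j$ (SE $\sigma_{yj}$) for its
effect on the outcome, both expressed on the same effect allele after
harmonization.

**Wald ratio.** $\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ with the
first-order SE $\sigma_{yj} / |\hat\gamma_j|$. This ignores the
uncertainty in $\hat\gamma_j$, which is standard practice when all
instruments are strong (F well above 10; here the mean per-variant F is
around 75).

**IVW with multiplicative random effects** (primary model). The
inverse-variance weighted estimate is the $\sigma_{yj}^{-2}$-weighted
regression of $\hat\Gamma_j$ on $\hat\gamma_j$ through the origin.
Heterogeneity is summarised by Cochran's
$Q = \sum_j \left(\frac{\hat\Gamma_j - \hat\theta\,\hat\gamma_j}{\sigma_{yj}}\right)^2$,
and the random-effects SE multiplies the fixed-effects SE by
$\max\!\left(1, \sqrt{Q/(J-1)}\right)$. The multiplicative
(overdispersion) flavour was chosen over an additive between-variant
variance because it is the convention of the standard two-sample MR
toolchain this analysis follows; the floor at 1 means apparent
underdispersion is never allowed to shrink the SE below its
fixed-effects value. With a single instrument the IVW estimate reduces
to the Wald ratio. P-values are two-sided normal.

**Weighted median** (sensitivity). Ratios are ordered and weighted by
first-order inverse variance $(\sigma_{yj}/\hat\gamma_j)^{-2}$; the
estimate linearly interpolates the ordered ratios at the 50% point of
the normalized cumulative weights (breakpoints
$p_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i$). It is consistent when
at least half the weight comes from valid instruments. The SE comes
from a parametric bootstrap (default 1000 resamples of the per-variant
effects from normal distributions with their reported SEs, under a
fixed seed applied in a local RNG scope); a bootstrap was chosen over
an analytic approximation because it is exact under the resampling
model and costs milliseconds at these problem sizes.

**MR-Egger** (pleiotropy diagnosis and correction). After orienting
every instrument so its exposure effect is positive, a weighted linear
regression *with* intercept is fitted. The slope is a
pleiotropy-adjusted causal estimate (valid under the InSIDE
assumption); the intercept estimates the average directional
pleiotropic effect, and its test is the bias intercept test. SEs use
the same multiplicative scaling floored at 1; inference uses a t
reference with $J-2$ degrees of freedom, which is slightly conservative
at small $J$.

Effects on AF are reported as odds ratios per **10-mmHg** increment,
$\mathrm{OR} = e^{10\hat\theta}$, the clinically conventional unit for
BP modification. Drug-class effects are reported per 10-mmHg
*decrease* (sign negated before exponentiation), so a protective
BP-lowering effect appears as OR < 1.

## Instrument construction and harmonization

* **Selection**: variants with exposure $P < 5\times10^{-8}$ (strict
  inequality, as conventionally printed).
* **Clumping**: greedy by ascending p-value; a retained index removes
  every variant within 10 000 kb (center-to-center, 1-based
  coordinates) whose $r^2$ with it exceeds 0.001 (0.1 for the
  drug-target analyses, which need denser coverage of small gene
  regions). Ties are broken by smaller SE, then lexical variant ID, so
  output is deterministic. Variants absent from the LD panel are
  treated as unlinked with a warning — this permits desk-scale runs
  with partial panels; with a complete panel the behaviour is exact.
* **Harmonization**: outcome effects are re-expressed on the exposure's
  effect allele: swapped alleles negate the outcome beta and complement
  its frequency; strand flips (complemented alleles) are recognised;
  irreconcilable pairs are dropped with a reason code, never silently
  aligned. Palindromic variants (A/T, C/G) carry no strand information
  in their labels, so orientation uses allele frequency alone: both
  frequencies must fall outside the ambiguous band (0.42, 0.58),
  otherwise the variant is dropped. The 0.42 cutoff mirrors common
  two-sample MR practice and is configurable; dropping palindromes
  outright is available as `palindrome_policy = "drop"`. Harmonizing an
  already-harmonized pair is the identity, and
  `harmonize_involution_check()` asserts this.
* The pulse-pressure instrument is built independently of the SBP/DBP
  instruments; no cross-trait variant exclusion is applied (none is
  described for the source analysis).

## Instrument strength and sample overlap

Per variant, the proportion of exposure variance explained is
$$R^2 = \frac{2\,\mathrm{MAF}(1-\mathrm{MAF})\,\beta^2}
{2\,\mathrm{MAF}(1-\mathrm{MAF})\,\beta^2 + 2\,\mathrm{MAF}(1-\mathrm{MAF})\,N\,se^2}
= \frac{\beta^2}{\beta^2 + N\,se^2},$$
in which the allele-frequency factor cancels — a property the tests
exercise on random inputs — and the instrument F statistic is
$F = R^2 (N-2)/(1-R^2)$, with the exact inversion
$R^2 = F/(F+N-2)$.

When participants appear in both GWAS, the two-sample estimate
inherits part of the confounded observational association, attenuated
by instrument strength. `overlap_bias()` implements the analytic
weak-instrument approximation
$$\mathrm{bias} \;=\; \rho \times \frac{\log(\mathrm{OR}_{\mathrm{obs}})/10}{E[F]},$$
on the per-mmHg log-odds scale, with $\rho$ the overlap fraction. Two
conventions for $E[F]$ are provided, because the choice is genuinely
open: `"expected"` (default), $(N_x/K)\,R^2/(1-R^2)$ built from the
total variance explained, and `"per_variant"`,
$(R^2/K)(N_x-2)/(1-R^2/K)$, the F of an average single instrument
(which reproduces the observed mean-F scale of the SBP instrument,
$\approx 76$ vs the reported 75). At the study dimensions the two give
biases of $5.9\times10^{-4}$ and $6.2\times10^{-4}$ per mmHg for an
observational OR of 1.6 — materially negligible either way. The
type-I error of the nominal 5% test is
$P(|Z| > z_{0.975})$ for $Z \sim N(\mathrm{bias}/se_{IV}, 1)$, with
$se_{IV} = (N_y\,cf(1-cf)\,R^2)^{-1/2}$ the asymptotic IVW SE for a
binary outcome with case fraction $cf$; it equals $\alpha$ exactly at
zero overlap and is never below it. For a binary outcome the overlap
fraction is interpreted as the fraction of exposure-GWAS participants
appearing anywhere in the outcome GWAS, cases and controls weighted by
their share.

## Drug-target proxies

Two independent routes build genetic proxies for antihypertensive
drug classes; they are never merged:

1. **Gene regions**: variants inside a class's target-gene bodies,
   promoters or enhancers (catalog supplied as a BED-like table,
   1-based inclusive; a flag converts true 0-based half-open BED) that
   pass genome-wide significance for SBP, clumped at $r^2 < 0.1$.
   Boundary positions are inclusive at both ends, and a variant
   mapping to two classes' regions is retained in both with a
   `multi_class` flag. The catalog is consumed as authoritative input;
   curating which genes constitute a class's targets is out of scope.
2. **Validated eQTLs**: per variant-gene pair the smallest
   nominal-p tissue wins (ties broken lexically by tissue label); each
   gene's best eQTLs are validated by two-sample MR of expression on
   SBP — Wald ratio per variant, IVW across a gene's variants — and
   retained at validation $P < 0.05$.

Class effects are estimated by IVW (weighted median as sensitivity
when at least three instruments exist) and reported per 10-mmHg SBP
decrease, the reciprocal of the per-increase OR from the same
instruments. Classes with no qualifying instruments are reported as
structured not-assessable records rather than estimates.

## The synthetic-data generator

`generate_summary_pair()` simulates the summary statistics directly —
no individual-level genotypes — because the analysis consumes only
summary data and direct simulation keeps full calibration studies in
seconds. Per variant: MAF uniform on (0.05, 0.5); true exposure effect
$\gamma_j = |N(0, 0.0165^2)|$ mmHg on a unit-variance phenotype; true
outcome effect $\theta\gamma_j + \alpha_j$ with pleiotropy $\alpha_j$
zero, balanced ($N(0, 0.002^2)$) or directional
($N(0.002, 0.002^2)$); sampling SEs from the closed forms
$\sigma_x = (2\,\mathrm{MAF}(1-\mathrm{MAF})\,N_x)^{-1/2}$ and
$\sigma_y = (2\,\mathrm{MAF}(1-\mathrm{MAF})\,N_y\,cf(1-cf))^{-1/2}$;
observed effects jointly normal with error correlation
$\rho\sqrt{\min(N)/\max(N)}$ for overlap fraction $\rho$. LD is
block-diagonal with constant within-block $r^2$ — the clumping logic
needs nothing richer. One integer seed drives a hierarchical seeding
scheme, so each fixture stream is independently reproducible.

Default scales were chosen once to mirror the source study's
dimensions: $N_x = 757{,}601$; outcome 65,446 cases / 522,744 controls;
$\theta = 0.0157$ per mmHg (OR 1.17 per 10 mmHg); and
$\gamma$-scale 0.0165, which at 400 variants yields a total $R^2$ near
4% and a mean per-variant F near 75 — the instrument strength the SBP
analysis reports.

Two deliberate modelling choices:

* **Effect alleles are exposure-raising** (half-normal $\gamma$).
  Allele coding is arbitrary in real data, but *directional*
  pleiotropy is only well defined relative to a direction of effect;
  with signed $\gamma$ and additive $\alpha$, MR-Egger's orientation
  step would flip $\alpha$'s sign for half the variants and the
  "directional" mean would vanish by construction. Reporting effects
  on the trait-raising allele makes the planted mean pleiotropy the
  estimand the Egger intercept targets. Strength metrics are
  unaffected ($E[\gamma^2]$ is unchanged).
* **Calibration studies select instruments before estimating.** The
  Monte-Carlo checks of the Egger intercept apply the genome-wide
  threshold to the simulated exposure stats first, exactly as the
  pipeline does. Variants with near-zero exposure effects are not
  instruments in any real analysis (every instrument in the source
  study has $F \ge 30$), and feeding them to Egger induces a known
  orientation artefact in which sub-significant variants flip sign and
  dilute the intercept toward zero.

What the generator does **not** emulate: realistic genome-wide LD,
liability-scale subtleties of the binary trait beyond the
case-control variance inflation, allele-frequency differences between
studies, and winner's-curse inflation of published exposure effects.
Passing calibration here validates the estimators and the pipeline
plumbing under the stated sampling model, not robustness to those
real-data complications.

## Numerical and degenerate-input choices

* Strict `<` at the genome-wide threshold; clumping tie-break by
  p-value, then SE, then variant ID.
* LD matrices must be symmetric within $10^{-8}$, unit diagonal, values
  in [0, 1]; asymmetry beyond tolerance is a data error.
* Weighted-median quantile outside the first/last breakpoint clamps to
  the extreme ratio (no extrapolation).
* Zero exposure effects are excluded from ratio-based estimators with
  a warning; an all-zero set is an estimation error.
* MR-Egger requires $J \ge 3$ and nonconstant exposure effects; an
  exact-fit (zero residual) regression yields the unscaled
  (sigma-floored) coefficient SEs rather than NaN.
* Monte-Carlo study sizes (200 oracle instances; 500 replicates at 400
  variants for calibration; 200 replicates for the pleiotropy
  contrast) were chosen to keep Monte-Carlo error a fraction of the
  tolerances while the full suite runs in a few minutes on one CPU.

## Known limitations

* The weak-instrument overlap bias is an analytic approximation whose
  expected-F convention is not uniquely determined; both conventions
  are exposed and reported, and the numbers differ by a few percent
  at study scale.
* First-order Wald SEs ignore exposure-side uncertainty (NOME); fine
  at F ≈ 75, increasingly optimistic below F ≈ 10.
* No MR-PRESSO, mode-based, multivariable or Steiger-filtered
  estimators; those are outside this analysis design.
* Proxy-variant lookup for outcome-missing instruments and genome-build
  liftover are not provided; inputs must share variant IDs and build.
```{r example, eval = FALSE}
# a complete desk-scale run
pair <- generate_summary_pair(synth_config(n_snps = 400, seed = 1))
report <- run_primary_analysis(analysis_config(list(
  exposures = list(SBP = pair$exposure),
  outcome = pair$outcome, ld = pair$ld)))
report$estimates
plot_mr_forest(report$estimates)
```
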