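#' Proportion of phenotype variance explained by one variant
#'
#' Computes, from summary statistics alone,
#' \deqn{R^2 = \frac{2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2}
#'   {2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2 +
#'    2\,\mathrm{MAF}(1-\mathrm{MAF})\,N\,se^2}}
#' which algebraically simplifies to \eqn{\beta^2/(\beta^2 + N se^2)} —
#' the allele-frequency factor cancels, so the value is invariant to MAF.
#'
#' @param beta Per-allele effect estimate in the exposure GWAS.
#' @param se Its standard error (> 0).
#' @param maf Effect-allele frequency, strictly inside (0, 1).
#' @param n GWAS sample size (> 2).
#' @return Proportion of variance explained, in \[0, 1). Vectorised.
#' @export
#' @examples
#' variant_r2(0.1, 0.01, 0.3, 1000) # 0.0909
variant_r2 <- function(beta, se, maf, n) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  if (any(maf <= 0 | maf >= 1)) {
    stop("maf must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(n <= 2)) stop("n must exceed 2", call. = FALSE)
  het <- 2 * maf * (1 - maf)
  (het * beta^2) / (het * beta^2 + het * n * se^2)
}

#' Per-variant F statistic
#'
#' Instrument-strength F statistic from the variance explained:
#' \eqn{F = R^2 (N - 2) / (1 - R^2)}. Strictly increasing in `r2` at
#' fixed `n`, and satisfies the exact inversion
#' `r2 = F / (F + n - 2)`.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n GWAS sample size (> 2).
#' @return Nonnegative F statistic. Vectorised.
#' @export
#' @examples
#' variant_f(0.5, 4) # 2
variant_f <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)", call. = FALSE)
  if (any(n <= 2)) stop("n must exceed 2", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

#' Instrument-strength summary for a clumped instrument set
#'
#' Aggregates per-variant variance explained and F statistics: the total
#' variance explained is the sum over (approximately independent)
#' variants; F is summarised by its mean, minimum and maximum.
#'
#' @param records Validated summary-statistics tibble (post-clumping),
#'   with columns `beta`, `se`, `eaf`, `n`.
#' @return One-row tibble: `n_variants`, `total_r2`, `mean_f`, `min_f`,
#'   `max_f`; the per-variant values are attached as the `per_variant`
#'   attribute (tibble with `variant_id`, `r2`, `f`).
#' @export
instrument_summary <- function(records) {
  if (nrow(records) == 0) {
    stop("instrument set is empty", call. = FALSE)
  }
  r2 <- variant_r2(records$beta, records$se, records$eaf, records$n)
  f <- variant_f(r2, records$n)
  out <- tibble::tibble(
    n_variants = nrow(records), total_r2 = sum(r2),
    mean_f = mean(f), min_f = min(f), max_f = max(f)
  )
  attr(out, "per_variant") <- tibble::tibble(
    variant_id = records$variant_id, r2 = r2, f = f
  )
  out
}

#' Define a sample-overlap scenario
#'
#' @param n_exposure Exposure-GWAS sample size.
#' @param n_cases,n_controls Outcome-GWAS case and control counts.
#' @param overlap_fraction Fraction of exposure-GWAS participants also in
#'   the outcome GWAS, in \[0, 1\].
#' @param observational_or_per_10 Confounded observational odds ratio per
#'   10-mmHg increment.
#' @param instrument_r2 Total variance in the exposure explained by the
#'   instruments.
#' @param n_instruments Number of instruments.
#' @param alpha Nominal two-sided test level.
#' @return A list of class `overlap_scenario`.
#' @export
overlap_scenario <- function(n_exposure, n_cases, n_controls,
                             overlap_fraction, observational_or_per_10,
                             instrument_r2, n_instruments, alpha = 0.05) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_exposure > 0, n_cases > 0, n_controls > 0,
            instrument_r2 > 0, instrument_r2 < 1, n_instruments >= 1,
            observational_or_per_10 > 0, alpha > 0, alpha < 1)
  structure(list(
    n_exposure = n_exposure, n_cases = n_cases, n_controls = n_controls,
    overlap_fraction = overlap_fraction,
    observational_or_per_10 = observational_or_per_10,
    instrument_r2 = instrument_r2, n_instruments = n_instruments,
    alpha = alpha
  ), class = "overlap_scenario")
}

#' Analytic bias and type-I error from exposure-outcome sample overlap
#'
#' Weak-instrument approximation of the bias a two-sample MR estimate
#' inherits from participant overlap: overlapping samples pull the
#' estimate toward the confounded observational association, attenuated
#' by instrument strength,
#' \deqn{\mathrm{bias} = \rho \times \frac{\log(\mathrm{OR_{obs}})/10}
#'   {E[F]}}
#' on the per-mmHg log-odds scale, where \eqn{\rho} is the overlap
#' fraction and \eqn{E[F]} the expected instrument F statistic. Two
#' conventions for \eqn{E[F]} are available: `"expected"` (default),
#' \eqn{(N_x/K)\,R^2/(1-R^2)} from the total variance explained, and
#' `"per_variant"`, \eqn{(R^2/K)(N_x-2)/(1-R^2/K)}, the per-variant F of
#' an average instrument. The type-I error of the nominal two-sided test
#' is \eqn{P(|Z| > z_{1-\alpha/2})} for
#' \eqn{Z \sim N(\mathrm{bias}/se_{IV}, 1)}, with the asymptotic IVW
#' standard error \eqn{se_{IV} = 1/\sqrt{N_y\,cf(1-cf)\,R^2}} (binary
#' outcome, case fraction \eqn{cf}). With zero overlap the bias is
#' exactly 0 and the type-I error exactly `alpha`.
#'
#' @param scenario An [overlap_scenario()].
#' @param f_convention `"expected"` or `"per_variant"` (see above).
#' @return One-row tibble: `bias` (log-odds per mmHg), `type1_error`,
#'   `expected_f`, `se_iv`, plus the scenario inputs echoed.
#' @export
#' @examples
#' sc <- overlap_scenario(757601, 65446, 522744, overlap_fraction = 1,
#'                        observational_or_per_10 = 1.3,
#'                        instrument_r2 = 0.04, n_instruments = 399)
#' overlap_bias(sc)
overlap_bias <- function(scenario,
                         f_convention = c("expected", "per_variant")) {
  f_convention <- match.arg(f_convention)
  stopifnot(inherits(scenario, "overlap_scenario"))
  s <- scenario
  r2 <- s$instrument_r2; k <- s$n_instruments
  expected_f <- switch(
    f_convention,
    expected = (s$n_exposure / k) * r2 / (1 - r2),
    per_variant = (r2 / k) * (s$n_exposure - 2) / (1 - r2 / k)
  )
  beta_obs <- log(s$observational_or_per_10) / 10
  bias <- s$overlap_fraction * beta_obs / expected_f
  n_outcome <- s$n_cases + s$n_controls
  cf <- s$n_cases / n_outcome
  se_iv <- 1 / sqrt(n_outcome * cf * (1 - cf) * r2)
  z <- stats::qnorm(1 - s$alpha / 2)
  mu <- bias / se_iv
  type1 <- if (mu == 0) s$alpha else {
    stats::pnorm(z, mean = mu, lower.tail = FALSE) +
      stats::pnorm(-z, mean = mu)
  }
  tibble::tibble(
    bias = bias, type1_error = type1, expected_f = expected_f,
    se_iv = se_iv, f_convention = f_convention,
    n_exposure = s$n_exposure, n_cases = s$n_cases,
    n_controls = s$n_controls, overlap_fraction = s$overlap_fraction,
    observational_or_per_10 = s$observational_or_per_10,
    instrument_r2 = r2, n_instruments = k, alpha = s$alpha
  )
}
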