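#' Per-variant Wald ratio estimates
#'
#' First-order ratio estimate for each instrument: the outcome effect
#' divided by the exposure effect, with standard error
#' `se_outcome / |beta_exposure|`. Instruments with a zero exposure
#' effect are excluded with a warning.
#'
#' @param instruments Harmonized instrument tibble with columns
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`
#'   (rows flagged `action_taken == "dropped"` are ignored).
#' @return A tibble with `variant_id` (when present), `ratio` and
#'   `ratio_se`, one row per usable instrument.
#' @export
wald_ratios <- function(instruments) {
  d <- .usable_instruments(instruments)
  zero <- d$beta_exposure == 0
  if (any(zero)) {
    warning(sum(zero), " instrument(s) with zero exposure effect excluded",
            call. = FALSE)
    d <- d[!zero, , drop = FALSE]
  }
  tibble::tibble(
    variant_id = if ("variant_id" %in% names(d)) d$variant_id else
      as.character(seq_len(nrow(d))),
    ratio = d$beta_outcome / d$beta_exposure,
    ratio_se = d$se_outcome / abs(d$beta_exposure)
  )
}

.usable_instruments <- function(instruments) {
  d <- tibble::as_tibble(instruments)
  if ("action_taken" %in% names(d)) {
    d <- dplyr::filter(d, .data$action_taken != "dropped")
  }
  req <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(req, names(d))
  if (length(missing) > 0) {
    stop("instrument table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d
}

.mr_row <- function(method, beta, se, n_snp, cochran_q = NA_real_,
                    q_df = NA_real_, df = Inf, or_scale = TRUE) {
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  pvalue <- if (is.finite(df)) {
    2 * stats::pt(abs(beta / se), df, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  }
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  tibble::tibble(
    method = method, n_snp = as.integer(n_snp),
    beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
    pvalue = pvalue, cochran_q = cochran_q, q_df = q_df,
    or_per_10 = if (or_scale) exp(10 * beta) else NA_real_,
    ci_or_low_10 = if (or_scale) exp(10 * ci_low) else NA_real_,
    ci_or_high_10 = if (or_scale) exp(10 * ci_high) else NA_real_
  )
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `se_outcome^-2` (equivalently, the
#' inverse-variance weighted mean of the Wald ratios under first-order
#' weights). Cochran's Q is computed on the ratio estimates. Under the
#' multiplicative random-effects model the fixed-effects standard error
#' is inflated by `max(1, sqrt(Q / (J - 1)))` (J >= 2); with a single
#' instrument the estimate is the Wald ratio. P-values are two-sided
#' normal.
#'
#' @param instruments Harmonized instrument tibble.
#' @param random_effects Inflate the standard error by residual
#'   overdispersion (default `TRUE`).
#' @return One-row estimate tibble (method
#'   `ivw_random_effects`/`ivw_fixed`) with effect on the per-mmHg
#'   log-odds scale, 95% CI, Cochran's Q and the per-10-mmHg odds ratio.
#' @export
mr_ivw <- function(instruments, random_effects = TRUE) {
  d <- .usable_instruments(instruments)
  d <- d[d$beta_exposure != 0, , drop = FALSE]
  j <- nrow(d)
  if (j < 1) stop("IVW requires at least one instrument", call. = FALSE)
  w <- d$se_outcome^-2
  beta <- sum(w * d$beta_exposure * d$beta_outcome) /
    sum(w * d$beta_exposure^2)
  se_fixed <- sqrt(1 / sum(w * d$beta_exposure^2))
  q <- sum(((d$beta_outcome - beta * d$beta_exposure) / d$se_outcome)^2)
  phi <- if (j >= 2) max(1, sqrt(q / (j - 1))) else 1
  se <- if (random_effects) se_fixed * phi else se_fixed
  .mr_row(if (random_effects) "ivw_random_effects" else "ivw_fixed",
          beta, se, j, cochran_q = q, q_df = j - 1)
}

# weighted median of `b` with weights `w`: linear interpolation of the
# cumulative-weight function at 0.5 (breakpoints (cumsum(w) - w/2) / sum(w))
.weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Median of the Wald ratios weighted by first-order inverse variance
#' `(se_outcome / beta_exposure)^-2`, consistent when at least half the
#' weight comes from valid instruments. The point estimate linearly
#' interpolates the ordered ratios at the 50% point of the normalized
#' cumulative weights. The standard error comes from a parametric
#' bootstrap: per-SNP exposure and outcome effects are resampled from
#' normal distributions with their reported standard errors and the
#' weighted median recomputed.
#'
#' @param instruments Harmonized instrument tibble (>= 3 instruments).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap (applied in a local RNG
#'   scope; the global stream is untouched).
#' @return One-row estimate tibble (method `weighted_median`).
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1L) {
  d <- .usable_instruments(instruments)
  d <- d[d$beta_exposure != 0, , drop = FALSE]
  j <- nrow(d)
  if (j < 3) {
    stop("weighted median requires at least 3 instruments", call. = FALSE)
  }
  ratio <- d$beta_outcome / d$beta_exposure
  w <- (d$se_outcome / d$beta_exposure)^-2
  beta <- .weighted_median(ratio, w)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(j, d$beta_exposure, d$se_exposure)
      by <- stats::rnorm(j, d$beta_outcome, d$se_outcome)
      ok <- bx != 0
      .weighted_median(by[ok] / bx[ok], (d$se_outcome[ok] / bx[ok])^-2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  .mr_row("weighted_median", beta, se, j)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' an intercept, after orienting every instrument so its exposure effect
#' is positive (both effects negated where needed). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the
#' average directional pleiotropic effect, and its test is the bias
#' intercept test. Weights are `se_outcome^-2`; coefficient standard
#' errors use multiplicative residual scaling floored at 1, and p-values
#' use a t reference with J - 2 degrees of freedom.
#'
#' @param instruments Harmonized instrument tibble (>= 3 instruments with
#'   nonconstant exposure effects).
#' @return Two-row estimate tibble: methods `egger_slope` and
#'   `egger_intercept` (the intercept row carries no per-10 odds ratio —
#'   it is a per-variant log-odds, not a per-mmHg effect).
#' @export
mr_egger <- function(instruments) {
  d <- .usable_instruments(instruments)
  j <- nrow(d)
  if (j < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- d$beta_exposure < 0
  bx <- abs(d$beta_exposure)
  by <- ifelse(flip, -d$beta_outcome, d$beta_outcome)
  if (stats::var(bx) == 0) {
    stop("MR-Egger requires variation in exposure effects", call. = FALSE)
  }
  w <- d$se_outcome^-2
  fit <- stats::lm(by ~ bx, weights = w)
  beta_hat <- stats::coef(fit)
  q <- sum(w * stats::residuals(fit)^2)
  sigma <- sqrt(q / (j - 2))
  # unscaled (sigma = 1) coefficient SEs, then multiplicative residual
  # scaling floored at 1
  x_mat <- cbind(1, bx)
  se_unscaled <- unname(sqrt(diag(solve(crossprod(x_mat, w * x_mat)))))
  se_coef <- se_unscaled * max(1, sigma)
  slope <- .mr_row("egger_slope", unname(beta_hat["bx"]), se_coef[2], j,
                   cochran_q = q, q_df = j - 2, df = j - 2)
  icpt <- .mr_row("egger_intercept", unname(beta_hat["(Intercept)"]),
                  se_coef[1], j, df = j - 2, or_scale = FALSE)
  dplyr::bind_rows(slope, icpt)
}

#' Express an estimate as an odds ratio per 10 mmHg
#'
#' Adds/overwrites the `or_per_10`, `ci_or_low_10` and `ci_or_high_10`
#' columns as `exp(10 * beta)` and the monotone transforms of the CI
#' bounds. Blood-pressure effects are conventionally reported per
#' 10-mmHg increment.
#'
#' @param estimate Estimate tibble with `beta`, `ci_low`, `ci_high`.
#' @return The tibble with per-10-mmHg odds-ratio columns filled.
#' @export
to_or_per_10mmHg <- function(estimate) {
  dplyr::mutate(estimate,
                or_per_10 = exp(10 * .data$beta),
                ci_or_low_10 = exp(10 * .data$ci_low),
                ci_or_high_10 = exp(10 * .data$ci_high))
}

#' Fit the full set of MR estimators
#'
#' Runs IVW with multiplicative random effects (the primary model) and,
#' when at least three instruments are available, the weighted-median and
#' MR-Egger sensitivity models, returning an `mr_fit` object.
#'
#' @param instruments Harmonized instrument tibble.
#' @param methods Character subset of
#'   `c("ivw_random_effects", "weighted_median", "egger")`.
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @param exposure,outcome Optional trait labels stored on the fit.
#' @return An object of class `mr_fit`: list with `estimates` (tidy
#'   tibble, one row per method), `instruments`, `exposure`, `outcome`.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   beta_exposure = rnorm(25, 0.05, 0.01), se_exposure = 0.002,
#'   beta_outcome = 0.0157 * beta_exposure + rnorm(25, 0, 0.004),
#'   se_outcome = 0.004
#' )
#' fit <- mr_analysis(d, exposure = "SBP", outcome = "AF")
#' tidy(fit)
mr_analysis <- function(instruments,
                        methods = c("ivw_random_effects",
                                    "weighted_median", "egger"),
                        n_boot = 1000, seed = 1L,
                        exposure = NA_character_, outcome = NA_character_) {
  d <- .usable_instruments(instruments)
  est <- list()
  if ("ivw_random_effects" %in% methods) {
    est <- c(est, list(mr_ivw(d, random_effects = TRUE)))
  }
  if ("weighted_median" %in% methods && nrow(d) >= 3) {
    est <- c(est, list(mr_weighted_median(d, n_boot = n_boot, seed = seed)))
  }
  if ("egger" %in% methods && nrow(d) >= 3) {
    est <- c(est, list(mr_egger(d)))
  }
  estimates <- dplyr::bind_rows(est)
  structure(
    list(estimates = tibble::as_tibble(estimates), instruments = d,
         exposure = exposure, outcome = outcome),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample MR fit", if (!is.na(x$exposure))
    paste0("(", x$exposure, " -> ", x$outcome, ")"), "\n")
  cat("Instruments:", nrow(x$instruments), "\n\n")
  print(as.data.frame(dplyr::select(
    x$estimates, "method", "n_snp", "beta", "se", "pvalue",
    "or_per_10", "ci_or_low_10", "ci_or_high_10")), digits = 4,
    row.names = FALSE)
  invisible(x)
}

#' Tidy an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return The estimates tibble, one row per method, with trait labels.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  dplyr::mutate(x$estimates, exposure = x$exposure, outcome = x$outcome,
                .before = 1)
}

#' One-row summary of an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return One-row tibble: instrument count, primary (IVW) estimate and
#'   heterogeneity, Egger intercept p-value when available.
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  e <- x$estimates
  ivw <- dplyr::filter(e, grepl("^ivw", .data$method))[1, ]
  icpt <- dplyr::filter(e, .data$method == "egger_intercept")
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome,
    n_snp = nrow(x$instruments),
    beta_ivw = ivw$beta, se_ivw = ivw$se, p_ivw = ivw$pvalue,
    or_per_10 = ivw$or_per_10,
    cochran_q = ivw$cochran_q, q_df = ivw$q_df,
    q_pvalue = stats::pchisq(ivw$cochran_q, ivw$q_df, lower.tail = FALSE),
    egger_intercept_p = if (nrow(icpt) > 0) icpt$pvalue else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
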