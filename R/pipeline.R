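#' Read an analysis configuration
#'
#' YAML key-value file describing inputs and thresholds. Recognised
#' keys: `exposures` (named map of trait label to summary-stat path),
#' `outcome`, `ld`, `regions`, `eqtl` (paths), `p_genomewide`,
#' `clump_r2_primary`, `clump_r2_drug_target`, `window_kb`,
#' `eqtl_validation_p`, `palindrome_policy`, `freq_cutoff`, `n_boot`,
#' `seed`, `output_dir`, `overlap` (scenario key-value block). Unset
#' thresholds default to the published pipeline's values (5e-8; 0.001
#' primary / 0.1 drug target; 10 000 kb; 0.05).
#'
#' @param path YAML file path.
#' @return A list of class `analysis_config` with defaults filled in.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  analysis_config(cfg)
}

#' Build an analysis configuration from a list
#'
#' @param cfg Named list of settings (see [read_analysis_config()]).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cfg = list()) {
  defaults <- list(
    exposures = NULL, outcome = NULL, ld = NULL, regions = NULL,
    eqtl = NULL,
    p_genomewide = 5e-8, clump_r2_primary = 0.001,
    clump_r2_drug_target = 0.1, window_kb = 10000,
    eqtl_validation_p = 0.05,
    palindrome_policy = "infer_by_frequency", freq_cutoff = 0.42,
    n_boot = 1000, seed = 1L, output_dir = NULL, overlap = NULL
  )
  out <- utils::modifyList(defaults, cfg)
  stopifnot(out$p_genomewide > 0, out$clump_r2_primary > 0,
            out$clump_r2_drug_target > 0, out$window_kb > 0,
            out$eqtl_validation_p > 0)
  structure(out, class = "analysis_config")
}

.as_stats <- function(x, trait = NA_character_) {
  if (is.character(x)) read_summary_stats(x, trait = trait) else
    tibble::as_tibble(x)
}

.as_ld <- function(x) {
  if (is.null(x)) NULL else if (is.character(x)) read_ld_matrix(x) else x
}

# accept an eQTL catalog as a path, a canonical-name tibble, or a tibble
# in the on-disk dialect (gene/beta/se/p)
.as_eqtl <- function(x) {
  if (is.character(x)) return(read_eqtl_catalog(x))
  x <- tibble::as_tibble(x)
  if ("target_gene" %in% names(x)) return(x)
  dplyr::rename(x, target_gene = "gene", beta_expression = "beta",
                se_expression = "se", pvalue_nominal = "p")
}

.log_stage <- function(log, trait, stage, n_in, n_out) {
  dplyr::bind_rows(log, tibble::tibble(
    trait = trait, stage = stage, n_in = n_in, n_out = n_out
  ))
}

#' Run the primary blood-pressure-to-AF analysis
#'
#' For each exposure trait: genome-wide selection, LD clumping,
#' harmonization against the outcome, then IVW with random effects,
#' weighted median and MR-Egger, reported as odds ratios per 10-mmHg
#' increment, with an instrument-strength summary. A trait whose
#' pipeline empties at any stage is reported as a structured
#' no-instruments record; other traits continue.
#'
#' @param config An `analysis_config` (or list coerced by
#'   [analysis_config()]). `exposures` may map trait labels to file
#'   paths or in-memory tibbles; `outcome` and `ld` likewise.
#' @return List of class `bpmr_report`: `estimates` (tidy tibble, one
#'   row per trait and method), `strength` (per-trait instrument
#'   metrics), `log` (per-stage variant counts), `errors` (structured
#'   failures), `fits` (named list of `mr_fit` objects).
#' @export
run_primary_analysis <- function(config) {
  if (!inherits(config, "analysis_config")) config <- analysis_config(config)
  stopifnot(!is.null(config$exposures), !is.null(config$outcome))
  outcome <- .as_stats(config$outcome, trait = "outcome")
  ld <- .as_ld(config$ld)

  log <- tibble::tibble(); errors <- tibble::tibble()
  estimates <- list(); strength <- list(); fits <- list()

  for (trait in names(config$exposures)) {
    res <- tryCatch({
      exp_stats <- .as_stats(config$exposures[[trait]], trait = trait)
      sig <- select_genomewide(exp_stats, config$p_genomewide)
      log <- .log_stage(log, trait, "select_genomewide",
                         nrow(exp_stats), nrow(sig))
      if (nrow(sig) == 0) stop("no genome-wide-significant variants")
      clumped <- clump(sig, ld = ld,
                       r2_threshold = config$clump_r2_primary,
                       window_kb = config$window_kb)
      log <- .log_stage(log, trait, "clump", nrow(sig), nrow(clumped))
      harm <- keep_harmonized(harmonize(
        clumped, outcome,
        palindrome_policy = config$palindrome_policy,
        freq_cutoff = config$freq_cutoff))
      log <- .log_stage(log, trait, "harmonize", nrow(clumped), nrow(harm))
      if (nrow(harm) == 0) stop("no instruments after harmonization")
      fit <- mr_analysis(harm, n_boot = config$n_boot,
                         seed = config$seed, exposure = trait,
                         outcome = "AF")
      kept <- dplyr::semi_join(clumped, harm, by = "variant_id")
      list(fit = fit, strength = dplyr::mutate(
        instrument_summary(kept), trait = trait, .before = 1))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- dplyr::bind_rows(errors, tibble::tibble(
        trait = trait, stage = "primary", message = conditionMessage(res)))
      next
    }
    fits[[trait]] <- res$fit
    estimates[[trait]] <- tidy(res$fit)
    strength[[trait]] <- res$strength
  }

  structure(list(
    estimates = dplyr::bind_rows(estimates),
    strength = dplyr::bind_rows(strength),
    log = log, errors = errors, fits = fits
  ), class = "bpmr_report")
}

#' Run the drug-target proxy analyses
#'
#' Per drug class and route: instrument selection (target-gene regions
#' and/or validated eQTLs), harmonization against the outcome, IVW and
#' weighted-median estimation, reported as odds ratios per 10-mmHg SBP
#' decrease. Classes without instruments are reported as
#' not-assessable. An absent eQTL catalog skips the eQTL route with a
#' notice (and vice versa).
#'
#' @param config An `analysis_config`; uses `exposures$SBP` (or the
#'   first exposure) as the SBP statistics, plus `outcome`, `regions`,
#'   `eqtl`, `ld`.
#' @return List of class `bpmr_drug_report`: `estimates`,
#'   `instruments`, `log`, `errors`.
#' @export
run_drug_target_analysis <- function(config) {
  if (!inherits(config, "analysis_config")) config <- analysis_config(config)
  stopifnot(!is.null(config$exposures), !is.null(config$outcome))
  if (is.null(config$regions) && is.null(config$eqtl)) {
    stop("drug-target analysis needs a region and/or eQTL catalog",
         call. = FALSE)
  }
  sbp_key <- if ("SBP" %in% names(config$exposures)) "SBP" else
    names(config$exposures)[1]
  sbp <- .as_stats(config$exposures[[sbp_key]], trait = sbp_key)
  outcome <- .as_stats(config$outcome, trait = "outcome")
  ld <- .as_ld(config$ld)

  log <- tibble::tibble(); errors <- tibble::tibble()
  estimates <- list(); instruments <- list()

  if (!is.null(config$regions)) {
    regions <- if (is.character(config$regions))
      read_region_catalog(config$regions) else
        validate_region_catalog(config$regions)
    sel <- select_gene_region_instruments(
      sbp, regions, p_threshold = config$p_genomewide,
      r2_threshold = config$clump_r2_drug_target, ld = ld,
      window_kb = config$window_kb)
    for (cl in unique(regions$drug_class)) {
      cl_sel <- if (nrow(sel) > 0)
        dplyr::filter(sel, .data$drug_class == cl) else sel
      harm <- if (nrow(cl_sel) > 0) {
        h <- keep_harmonized(harmonize(
          cl_sel, outcome, palindrome_policy = config$palindrome_policy,
          freq_cutoff = config$freq_cutoff))
        dplyr::mutate(h, drug_class = cl, route = "gene_region")
      } else tibble::tibble()
      log <- .log_stage(log, cl, "gene_region_selection",
                        nrow(cl_sel), nrow(harm))
      est <- estimate_drug_class_effect(
        harm, drug_class = cl, route = "gene_region",
        n_boot = config$n_boot, seed = config$seed)
      estimates[[paste(cl, "gene_region")]] <- est
      instruments[[paste(cl, "gene_region")]] <- harm
      if (!any(est$assessable)) {
        errors <- dplyr::bind_rows(errors, tibble::tibble(
          trait = cl, stage = "gene_region",
          message = "no instruments; not assessable"))
      }
    }
  } else {
    message("no region catalog supplied; gene-region route skipped")
  }

  if (!is.null(config$eqtl)) {
    eqtl <- .as_eqtl(config$eqtl)
    sel <- select_eqtl_instruments(
      eqtl, sbp, outcome, validation_p = config$eqtl_validation_p,
      palindrome_policy = config$palindrome_policy,
      freq_cutoff = config$freq_cutoff)
    for (cl in unique(eqtl$drug_class)) {
      cl_sel <- if (nrow(sel) > 0)
        dplyr::filter(sel, .data$drug_class == cl) else tibble::tibble()
      log <- .log_stage(log, cl, "eqtl_selection", NA_integer_,
                        nrow(cl_sel))
      est <- estimate_drug_class_effect(
        cl_sel, drug_class = cl, route = "eqtl",
        n_boot = config$n_boot, seed = config$seed)
      estimates[[paste(cl, "eqtl")]] <- est
      instruments[[paste(cl, "eqtl")]] <- cl_sel
      if (!any(est$assessable)) {
        errors <- dplyr::bind_rows(errors, tibble::tibble(
          trait = cl, stage = "eqtl",
          message = "no validated instruments; not assessable"))
      }
    }
  } else {
    message("no eQTL catalog supplied; eQTL route skipped")
  }

  structure(list(
    estimates = dplyr::bind_rows(estimates),
    instruments = instruments, log = log, errors = errors
  ), class = "bpmr_drug_report")
}

#' Run the sample-overlap bias scenario from a configuration
#'
#' @param config An `analysis_config` whose `overlap` block supplies the
#'   [overlap_scenario()] fields (`n_exposure`, `n_cases`, `n_controls`,
#'   `overlap_fraction`, `observational_or_per_10`, `instrument_r2`,
#'   `n_instruments`, optional `alpha`, `f_convention`).
#' @return The [overlap_bias()] result tibble.
#' @export
run_overlap_bias <- function(config) {
  if (!inherits(config, "analysis_config")) config <- analysis_config(config)
  ov <- config$overlap
  if (is.null(ov)) stop("config has no overlap block", call. = FALSE)
  sc <- overlap_scenario(
    n_exposure = ov$n_exposure, n_cases = ov$n_cases,
    n_controls = ov$n_controls,
    overlap_fraction = ov$overlap_fraction,
    observational_or_per_10 = ov$observational_or_per_10,
    instrument_r2 = ov$instrument_r2,
    n_instruments = ov$n_instruments,
    alpha = ov$alpha %||% 0.05
  )
  overlap_bias(sc, f_convention = ov$f_convention %||% "expected")
}

#' Write report tables to an output directory
#'
#' @param report A `bpmr_report` or `bpmr_drug_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$estimates, file.path(dir, "estimates.tsv"))
  if (!is.null(report$strength) && nrow(report$strength) > 0) {
    readr::write_tsv(report$strength, file.path(dir, "strength.tsv"))
  }
  readr::write_tsv(report$log, file.path(dir, "stage_log.tsv"))
  if (nrow(report$errors) > 0) {
    readr::write_tsv(report$errors, file.path(dir, "errors.tsv"))
  }
  invisible(dir)
}

#' @export
print.bpmr_report <- function(x, ...) {
  cat("Primary MR report:", length(x$fits), "trait(s),",
      nrow(x$errors), "error(s)\n")
  if (nrow(x$estimates) > 0) {
    print(as.data.frame(dplyr::select(
      x$estimates, "exposure", "method", "n_snp", "or_per_10",
      "ci_or_low_10", "ci_or_high_10", "pvalue")), digits = 3,
      row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.bpmr_drug_report <- function(x, ...) {
  cat("Drug-target MR report:", nrow(x$estimates), "row(s),",
      nrow(x$errors), "not-assessable/error record(s)\n")
  if (nrow(x$estimates) > 0) {
    print(as.data.frame(dplyr::select(
      x$estimates, "drug_class", "route", "method", "n_snp",
      "or_per_10_decrease", "ci_or_low", "ci_or_high", "pvalue")),
      digits = 3, row.names = FALSE)
  }
  invisible(x)
}
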