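#' Antihypertensive drug-class labels
#'
#' The closed set of drug-class labels accepted in region and eQTL
#' catalogs: the five classes with curated target-gene regions (ACEi,
#' ARB, BB, CCB, thiazide) plus the remaining classes of the expanded
#' eQTL scan.
#'
#' @return Character vector of allowed labels.
#' @export
drug_classes <- function() {
  c("ACEi", "ARB", "BB", "CCB", "thiazide",
    "adrenergic_neuron_blocker", "alpha_blocker", "centrally_acting",
    "loop_diuretic", "potassium_sparing_diuretic", "renin_inhibitor",
    "vasodilator")
}

.element_types <- c("gene_body", "promoter", "enhancer")

#' Read a drug-class target-region catalog
#'
#' BED-like TSV with columns `chromosome`, `start`, `end`, `gene_symbol`,
#' `drug_class`, `element_type`. Coordinates are 1-based inclusive by
#' default; set `zero_based = TRUE` to ingest true BED (0-based,
#' half-open) intervals, which are converted on read.
#'
#' @param path File path.
#' @param zero_based Interpret `start`/`end` as 0-based half-open.
#' @return Validated tibble of regions.
#' @export
read_region_catalog <- function(path, zero_based = FALSE) {
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_region_catalog(dat, zero_based = zero_based)
}

#' Validate a drug-class target-region table
#'
#' @param dat Data frame of regions.
#' @param zero_based See [read_region_catalog()].
#' @return Validated tibble (1-based inclusive coordinates).
#' @export
validate_region_catalog <- function(dat, zero_based = FALSE) {
  dat <- tibble::as_tibble(dat)
  req <- c("chromosome", "start", "end", "gene_symbol", "drug_class",
           "element_type")
  missing <- setdiff(req, names(dat))
  if (length(missing) > 0) {
    stop("region catalog lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (zero_based) {
    dat$start <- dat$start + 1L  # end of half-open == inclusive end
  }
  bad_class <- setdiff(unique(dat$drug_class), drug_classes())
  if (length(bad_class) > 0) {
    stop("unknown drug_class label(s): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(dat$element_type), .element_types)
  if (length(bad_type) > 0) {
    stop("unknown element_type label(s): ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  if (any(dat$start > dat$end)) {
    stop("region with start > end", call. = FALSE)
  }
  dplyr::mutate(dat, chromosome = as.character(.data$chromosome),
                start = as.integer(.data$start),
                end = as.integer(.data$end))
}

#' Read an eQTL catalog
#'
#' TSV with columns `variant_id`, `gene`, `tissue`, `beta`, `se`, `p`,
#' `drug_class` (expression effect of the variant on the gene, per
#' tissue).
#'
#' @param path File path.
#' @return Validated tibble with canonical names (`target_gene`,
#'   `beta_expression`, `se_expression`, `pvalue_nominal`).
#' @export
read_eqtl_catalog <- function(path) {
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("variant_id", "gene", "tissue", "beta", "se", "p", "drug_class")
  missing <- setdiff(req, names(dat))
  if (length(missing) > 0) {
    stop("eQTL catalog lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_class <- setdiff(unique(dat$drug_class), drug_classes())
  if (length(bad_class) > 0) {
    stop("unknown drug_class label(s): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  if (any(dat$se <= 0)) stop("eQTL se must be positive", call. = FALSE)
  dplyr::transmute(tibble::as_tibble(dat),
                   variant_id = as.character(.data$variant_id),
                   target_gene = as.character(.data$gene),
                   tissue = as.character(.data$tissue),
                   beta_expression = .data$beta,
                   se_expression = .data$se,
                   pvalue_nominal = .data$p,
                   drug_class = as.character(.data$drug_class))
}

#' Select gene-region instruments per drug class
#'
#' For each drug class: variants whose position falls within any of the
#' class's target-gene regions (1-based inclusive, both boundaries in),
#' associated with SBP below `p_threshold`, then LD-clumped at the
#' drug-target threshold (default r-squared 0.1). A variant mapping to
#' regions of more than one class is retained in each and flagged
#' `multi_class`. Classes with no qualifying variant yield no rows and a
#' warning.
#'
#' @param sbp_stats Validated SBP summary statistics.
#' @param regions Validated region catalog.
#' @param p_threshold Significance threshold (strict `<`).
#' @param r2_threshold Clumping removal threshold.
#' @param ld Optional `ld_matrix`.
#' @param window_kb Clumping window.
#' @return Tibble of selected instruments with `drug_class`,
#'   `gene_symbol`, `element_type`, `multi_class` and route
#'   `"gene_region"` columns prepended to the summary-stat columns.
#' @export
select_gene_region_instruments <- function(sbp_stats, regions,
                                           p_threshold = 5e-8,
                                           r2_threshold = 0.1,
                                           ld = NULL, window_kb = 10000) {
  regions <- validate_region_catalog(regions)
  sig <- select_genomewide(sbp_stats, p_threshold)

  hits <- purrr::map_dfr(unique(regions$drug_class), function(cl) {
    regs <- dplyr::filter(regions, .data$drug_class == cl)
    in_region <- purrr::map_dfr(seq_len(nrow(regs)), function(k) {
      dplyr::filter(sig,
                    .data$chromosome == regs$chromosome[k],
                    .data$position >= regs$start[k],
                    .data$position <= regs$end[k]) |>
        dplyr::mutate(gene_symbol = regs$gene_symbol[k],
                      element_type = regs$element_type[k])
    })
    in_region <- dplyr::distinct(in_region, .data$variant_id,
                                 .keep_all = TRUE)
    if (nrow(in_region) == 0) {
      warning("no qualifying variants for drug class ", cl, call. = FALSE)
      return(tibble::tibble())
    }
    clumped <- clump(in_region, ld = ld, r2_threshold = r2_threshold,
                     window_kb = window_kb)
    dplyr::mutate(clumped, drug_class = cl, route = "gene_region",
                  .before = 1)
  })
  if (nrow(hits) == 0) return(hits)
  dplyr::mutate(hits,
                multi_class = .data$variant_id %in%
                  hits$variant_id[duplicated(hits$variant_id)])
}

#' Select and validate eQTL instruments per drug class
#'
#' For each variant-gene pair, the eQTL with the smallest nominal
#' p-value across tissues is kept (ties broken lexically by tissue).
#' Each gene's best eQTLs are validated as instruments by two-sample MR
#' of gene expression on SBP — a Wald ratio per variant
#' (`beta_SBP / beta_expression`) combined by IVW across a gene's
#' variants — and the gene is retained when the validation p-value is
#' below `validation_p`. Retained variants are harmonized against the
#' outcome GWAS.
#'
#' @param eqtl_records Validated eQTL catalog ([read_eqtl_catalog()]).
#' @param sbp_stats Validated SBP summary statistics.
#' @param outcome_stats Validated outcome summary statistics.
#' @param validation_p Threshold for the expression-to-SBP MR p-value.
#' @param ... Passed to [harmonize()].
#' @return Tibble of harmonized instruments with `drug_class`,
#'   `target_gene`, `validation_pvalue` and route `"eqtl"` columns.
#'   Attribute `validation` holds the per-gene validation table.
#' @export
select_eqtl_instruments <- function(eqtl_records, sbp_stats, outcome_stats,
                                    validation_p = 0.05, ...) {
  best <- eqtl_records |>
    dplyr::arrange(.data$pvalue_nominal, .data$tissue) |>
    dplyr::distinct(.data$drug_class, .data$target_gene, .data$variant_id,
                    .keep_all = TRUE)

  joined <- dplyr::inner_join(
    best,
    dplyr::select(sbp_stats, "variant_id", beta_sbp = "beta",
                  se_sbp = "se"),
    by = "variant_id"
  )
  n_missing <- nrow(best) - nrow(joined)
  if (n_missing > 0) {
    warning(n_missing,
            " eQTL variant(s) absent from the SBP statistics dropped",
            call. = FALSE)
  }
  if (nrow(joined) == 0) return(tibble::tibble())

  # expression -> SBP Wald ratio per variant, IVW across a gene's variants
  validation <- joined |>
    dplyr::mutate(ratio = .data$beta_sbp / .data$beta_expression,
                  ratio_se = .data$se_sbp / abs(.data$beta_expression)) |>
    dplyr::group_by(.data$drug_class, .data$target_gene) |>
    dplyr::summarise(
      beta_mr = sum(.data$ratio / .data$ratio_se^2) /
        sum(1 / .data$ratio_se^2),
      se_mr = sqrt(1 / sum(1 / .data$ratio_se^2)),
      .groups = "drop"
    ) |>
    dplyr::mutate(validation_pvalue =
                    2 * stats::pnorm(abs(.data$beta_mr / .data$se_mr),
                                     lower.tail = FALSE),
                  validated = .data$validation_pvalue < validation_p)

  retained <- joined |>
    dplyr::inner_join(
      dplyr::filter(validation, .data$validated) |>
        dplyr::select("drug_class", "target_gene", "validation_pvalue"),
      by = c("drug_class", "target_gene")
    )
  if (nrow(retained) == 0) {
    out <- tibble::tibble()
    attr(out, "validation") <- validation
    return(out)
  }

  harm <- keep_harmonized(harmonize(
    dplyr::semi_join(sbp_stats, retained, by = "variant_id"),
    outcome_stats, ...
  ))
  out <- dplyr::inner_join(
    dplyr::select(retained, "drug_class", "target_gene", "variant_id",
                  "validation_pvalue"),
    harm, by = "variant_id"
  ) |>
    dplyr::mutate(route = "eqtl", .before = 1)
  attr(out, "validation") <- validation
  out
}

#' Estimate a drug-class effect on the outcome
#'
#' Runs the requested estimators (IVW with random effects; weighted
#' median when at least three instruments are available) on one drug
#' class's instrument set and reports the effect as an odds ratio per
#' 10-mmHg SBP DECREASE: the per-mmHg estimate's sign is negated before
#' exponentiation, so a protective (BP-lowering) drug effect yields an
#' OR below 1. An empty set yields a structured not-assessable row.
#'
#' @param set Instrument tibble for one class and route (columns
#'   `beta_exposure` etc., or a gene-region selection joined to
#'   harmonized outcome effects).
#' @param drug_class,route Labels for the report (taken from the set's
#'   columns when present).
#' @param methods Estimators to run.
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return Tidy tibble, one row per method: `drug_class`, `route`,
#'   `method`, `n_snp`, `beta` (per-mmHg increase scale),
#'   `or_per_10_decrease`, `ci_or_low`, `ci_or_high`, `pvalue`,
#'   `assessable`.
#' @export
estimate_drug_class_effect <- function(set, drug_class = NULL, route = NULL,
                                       methods = c("ivw_random_effects",
                                                   "weighted_median"),
                                       n_boot = 1000, seed = 1L) {
  drug_class <- drug_class %||%
    (if ("drug_class" %in% names(set) && nrow(set) > 0)
      set$drug_class[1] else NA_character_)
  route <- route %||%
    (if ("route" %in% names(set) && nrow(set) > 0)
      set$route[1] else NA_character_)

  not_assessable <- tibble::tibble(
    drug_class = drug_class, route = route, method = NA_character_,
    n_snp = 0L, beta = NA_real_, se = NA_real_,
    or_per_10_decrease = NA_real_, ci_or_low = NA_real_,
    ci_or_high = NA_real_, pvalue = NA_real_, assessable = FALSE
  )
  if (is.null(set) || nrow(set) == 0) return(not_assessable)

  fit <- mr_analysis(set, methods = methods, n_boot = n_boot, seed = seed)
  est <- fit$estimates
  # per 10-mmHg DECREASE: negate the per-mmHg effect, CI bounds swap
  dplyr::transmute(
    est,
    drug_class = drug_class, route = route, method = .data$method,
    n_snp = .data$n_snp, beta = .data$beta, se = .data$se,
    or_per_10_decrease = exp(-10 * .data$beta),
    ci_or_low = exp(-10 * .data$ci_high),
    ci_or_high = exp(-10 * .data$ci_low),
    pvalue = .data$pvalue, assessable = TRUE
  )
}
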