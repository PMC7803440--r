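#' Configuration of a simulated exposure/outcome GWAS pair
#'
#' Parameterizes a direct simulation of two-sample MR summary
#' statistics: a continuous blood-pressure-like exposure (phenotype
#' variance 1) and a binary atrial-fibrillation-like outcome on the
#' log-odds scale. Defaults mirror the scale of a large blood-pressure
#' GWAS feeding an AF case-control GWAS: roughly 400 instruments
#' explaining about 4% of exposure variance (mean per-variant F near
#' 75), exposure N 757,601, outcome 65,446 cases / 522,744 controls, and
#' a true causal effect of 0.0157 log-odds per mmHg (odds ratio 1.17 per
#' 10 mmHg).
#'
#' @param n_snps Number of variants.
#' @param theta True causal effect, log-odds per mmHg.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_sd SD of pleiotropic outcome effects (log-odds).
#' @param pleiotropy_mean Mean pleiotropic effect (directional mode).
#' @param gamma_sd SD of true per-allele exposure effects (mmHg on the
#'   unit-variance phenotype scale). The default 0.0165, with
#'   `maf_range = c(0.05, 0.5)` and the default N, gives a total
#'   variance explained near 4% and mean F near 75 at 400 variants.
#' @param maf_range Uniform range for minor-allele frequencies, within
#'   (0, 0.5\].
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param case_fraction Outcome case fraction in (0, 1).
#' @param overlap_fraction Fraction of exposure participants also in the
#'   outcome GWAS, in \[0, 1\]; induces correlated sampling errors.
#' @param ld_block_size Variants per LD block (1 = all independent).
#' @param ld_within_r2 Constant squared correlation within a block.
#' @param seed Integer seed; a fixed seed makes every output
#'   reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_snps = 400, theta = 0.0157,
                         pleiotropy_mode = c("none", "balanced",
                                             "directional"),
                         pleiotropy_sd = 0.002, pleiotropy_mean = 0.002,
                         gamma_sd = 0.0165, maf_range = c(0.05, 0.5),
                         n_exposure = 757601, n_outcome = 588190,
                         case_fraction = 65446 / 588190,
                         overlap_fraction = 0,
                         ld_block_size = 1, ld_within_r2 = 0,
                         seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            case_fraction > 0, case_fraction < 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            ld_block_size >= 1, ld_within_r2 >= 0, ld_within_r2 <= 1,
            gamma_sd > 0, pleiotropy_sd >= 0)
  structure(list(
    n_snps = n_snps, theta = theta, pleiotropy_mode = pleiotropy_mode,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_mean = pleiotropy_mean,
    gamma_sd = gamma_sd, maf_range = maf_range,
    n_exposure = n_exposure, n_outcome = n_outcome,
    case_fraction = case_fraction, overlap_fraction = overlap_fraction,
    ld_block_size = ld_block_size, ld_within_r2 = ld_within_r2,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# derive a stream-specific child seed from the config seed, keeping it
# inside the 32-bit integer range
.child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + stream * 12345) %% .Machine$integer.max)
}

#' Generate a paired exposure/outcome summary-statistics set
#'
#' Simulates, per variant: a minor-allele frequency uniform on
#' `maf_range`; a true exposure effect drawn half-normal,
#' `gamma = |N(0, gamma_sd^2)|` (the effect allele is reported as the
#' exposure-raising allele, so directional pleiotropy has a well-defined
#' direction); a pleiotropic outcome effect per `pleiotropy_mode`; and
#' the true outcome effect `theta * gamma + alpha`. Sampling standard
#' errors follow the closed forms
#' `se_x = 1 / sqrt(2 maf (1 - maf) n_exposure)` (unit phenotype
#' variance) and `se_y = 1 / sqrt(2 maf (1 - maf) n_outcome cf (1 - cf))`
#' (case-control variance inflation). Observed effects are drawn jointly
#' normal with error correlation
#' `overlap_fraction * sqrt(min(n) / max(n))` between the exposure and
#' outcome streams. Variants are laid out in LD blocks with constant
#' within-block squared correlation.
#'
#' @param config A [synth_config()].
#' @return List with `exposure` and `outcome` summary-stat tibbles
#'   (canonical columns), `ld` (an `ld_matrix`), and `truth` (tibble of
#'   per-variant `gamma`, `alpha`, `big_gamma`, the error draws, and
#'   `theta`).
#' @export
generate_summary_pair <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  j <- cfg$n_snps
  withr::with_seed(.child_seed(cfg$seed, 1L), {
    maf <- stats::runif(j, cfg$maf_range[1], cfg$maf_range[2])
    gamma <- abs(stats::rnorm(j, 0, cfg$gamma_sd))
    alpha <- switch(cfg$pleiotropy_mode,
                    none = rep(0, j),
                    balanced = stats::rnorm(j, 0, cfg$pleiotropy_sd),
                    directional = stats::rnorm(j, cfg$pleiotropy_mean,
                                               cfg$pleiotropy_sd))
    big_gamma <- cfg$theta * gamma + alpha

    het <- 2 * maf * (1 - maf)
    se_x <- 1 / sqrt(het * cfg$n_exposure)
    cf <- cfg$case_fraction
    se_y <- 1 / sqrt(het * cfg$n_outcome * cf * (1 - cf))

    rho <- cfg$overlap_fraction *
      sqrt(min(cfg$n_exposure, cfg$n_outcome) /
             max(cfg$n_exposure, cfg$n_outcome))
    e1 <- stats::rnorm(j)
    e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(j)
    beta_x <- gamma + se_x * e1
    beta_y <- big_gamma + se_y * e2

    n_blocks <- ceiling(j / cfg$ld_block_size)
    block <- rep(seq_len(n_blocks), each = cfg$ld_block_size)[seq_len(j)]
    # 100 blocks per chromosome, 20 Mb apart (beyond any clumping
    # window, and within the integer position range); within-block
    # variants are 10 kb neighbours
    chromosome <- as.character((block - 1L) %/% 100L + 1L)
    position <- as.integer(((block - 1L) %% 100L + 1L) * 2e7 +
                             (seq_len(j) - (block - 1) * cfg$ld_block_size) *
                             1e4)
    ids <- sprintf("rs%06d", seq_len(j))
    alleles_e <- c("A", "C")[1 + (seq_len(j) %% 2)]
    alleles_o <- c("G", "T")[1 + (seq_len(j) %% 2)]

    mk_stats <- function(beta, se, n, trait) {
      tibble::tibble(
        variant_id = ids, chromosome = chromosome, position = position,
        effect_allele = alleles_e, other_allele = alleles_o,
        eaf = maf, beta = beta, se = se,
        pvalue = pmax(2 * stats::pnorm(abs(beta / se),
                                       lower.tail = FALSE), 1e-300),
        n = n, trait = trait
      )
    }
    exposure <- mk_stats(beta_x, se_x, cfg$n_exposure, "exposure")
    outcome <- mk_stats(beta_y, se_y, cfg$n_outcome, "outcome")

    r2 <- outer(block, block, function(a, b)
      ifelse(a == b, cfg$ld_within_r2, 0))
    diag(r2) <- 1
    ld <- ld_matrix(r2, variant_ids = ids, positions = position)

    truth <- tibble::tibble(
      variant_id = ids, maf = maf, gamma = gamma, alpha = alpha,
      big_gamma = big_gamma, error_exposure = e1, error_outcome = e2,
      theta = cfg$theta
    )
    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
  })
}

#' Generate a drug-class region catalog with planted SBP signals
#'
#' Builds a BED-like target-region catalog and matching SBP summary-stat
#' rows: inside each gene region, a fraction `effect_enrichment` of the
#' variants carries a genome-wide-significant SBP effect; variants
#' outside regions (one flanking null variant per gene) are null.
#'
#' @param classes Character vector of drug-class labels
#'   (see [drug_classes()]).
#' @param genes_per_class Genes per class.
#' @param snps_per_gene Variants placed inside each gene region.
#' @param effect_enrichment Fraction of in-region variants with planted
#'   significant effects, in \[0, 1\].
#' @param shared_gene If `TRUE` and at least two classes are given, the
#'   first gene is shared between the first two classes (a multi-class
#'   variant path).
#' @param n Sample size recorded on the generated rows.
#' @param seed Integer seed.
#' @return List with `regions` (catalog tibble) and `sbp_stats`
#'   (summary-stat tibble containing the in-region and flanking rows).
#' @export
generate_region_fixture <- function(classes = c("CCB", "BB"),
                                    genes_per_class = 1,
                                    snps_per_gene = 3,
                                    effect_enrichment = 1,
                                    shared_gene = FALSE,
                                    n = 757601, seed = 1L) {
  stopifnot(genes_per_class >= 1, snps_per_gene >= 1,
            effect_enrichment >= 0, effect_enrichment <= 1)
  withr::with_seed(.child_seed(seed, 2L), {
    regions <- list(); stats_rows <- list(); idx <- 0L
    gene_id <- 0L
    for (ci in seq_along(classes)) {
      for (g in seq_len(genes_per_class)) {
        shared <- shared_gene && ci == 2 && g == 1
        if (!shared) gene_id <- gene_id + 1L
        chrom <- as.character(gene_id)
        start <- 1e6L
        end <- start + 9999L
        regions[[length(regions) + 1]] <- tibble::tibble(
          chromosome = chrom, start = start, end = end,
          gene_symbol = sprintf("GENE%02d", gene_id),
          drug_class = classes[ci], element_type = "gene_body"
        )
        if (shared) next  # variants already emitted for this gene
        n_sig <- round(effect_enrichment * snps_per_gene)
        pos <- as.integer(seq(start, end, length.out = snps_per_gene))
        for (s in seq_len(snps_per_gene)) {
          idx <- idx + 1L
          sig <- s <= n_sig
          maf <- stats::runif(1, 0.1, 0.5)
          se <- 1 / sqrt(2 * maf * (1 - maf) * n)
          beta <- if (sig) se * (6 + stats::runif(1, 0, 4)) else
            se * stats::rnorm(1)
          stats_rows[[idx]] <- tibble::tibble(
            variant_id = sprintf("rsg%05d", idx), chromosome = chrom,
            position = pos[s], effect_allele = "A", other_allele = "G",
            eaf = maf, beta = beta, se = se,
            pvalue = pmax(2 * stats::pnorm(abs(beta / se),
                                           lower.tail = FALSE), 1e-300),
            n = n, trait = "SBP"
          )
        }
        # one flanking null variant outside the region
        idx <- idx + 1L
        maf <- stats::runif(1, 0.1, 0.5)
        se <- 1 / sqrt(2 * maf * (1 - maf) * n)
        beta <- se * stats::rnorm(1)
        stats_rows[[idx]] <- tibble::tibble(
          variant_id = sprintf("rsg%05d", idx), chromosome = chrom,
          position = end + 50000L, effect_allele = "A",
          other_allele = "G", eaf = maf, beta = beta, se = se,
          pvalue = pmax(2 * stats::pnorm(abs(beta / se),
                                         lower.tail = FALSE), 1e-300),
          n = n, trait = "SBP"
        )
      }
    }
    list(regions = dplyr::bind_rows(regions),
         sbp_stats = dplyr::bind_rows(stats_rows))
  })
}

#' Generate an eQTL catalog consistent with planted SBP effects
#'
#' Builds an eQTL catalog of one best variant per gene (plus a decoy
#' worse-p tissue entry) together with SBP summary statistics such that
#' exactly `round(frac_validating * n_genes)` genes pass the
#' expression-to-SBP Wald validation at p < 0.05 by construction
#' (validating genes get a strong planted SBP effect; the rest are
#' null).
#'
#' @param n_genes Number of genes (one eQTL variant each).
#' @param frac_validating Fraction of genes whose eQTL passes
#'   validation, in \[0, 1\].
#' @param drug_class Class label attached to every gene.
#' @param n_sbp SBP GWAS sample size for the generated rows.
#' @param seed Integer seed.
#' @return List with `eqtl` (catalog tibble in the on-disk dialect:
#'   `variant_id`, `gene`, `tissue`, `beta`, `se`, `p`, `drug_class`),
#'   `sbp_stats`, and `truth` (which genes validate).
#' @export
generate_eqtl_fixture <- function(n_genes = 4, frac_validating = 0.5,
                                  drug_class = "CCB", n_sbp = 757601,
                                  seed = 1L) {
  stopifnot(frac_validating >= 0, frac_validating <= 1, n_genes >= 1)
  n_valid <- round(frac_validating * n_genes)
  withr::with_seed(.child_seed(seed, 3L), {
    rows <- purrr::map(seq_len(n_genes), function(g) {
      validating <- g <= n_valid
      id <- sprintf("rse%05d", g)
      maf <- stats::runif(1, 0.1, 0.5)
      se_sbp <- 1 / sqrt(2 * maf * (1 - maf) * n_sbp)
      # strong SBP effect for validating genes, null otherwise
      beta_sbp <- if (validating) se_sbp * (8 + stats::runif(1, 0, 4)) else
        se_sbp * stats::rnorm(1) * 0.1
      eqtl <- tibble::tibble(
        variant_id = id, gene = sprintf("EGENE%02d", g),
        tissue = c("Artery_Tibial", "Whole_Blood"),
        beta = c(0.5, 0.4), se = c(0.05, 0.08),
        p = c(1e-12, 1e-6), drug_class = drug_class
      )
      sbp <- tibble::tibble(
        variant_id = id, chromosome = "20",
        position = 1000000L + g * 100000L,
        effect_allele = "A", other_allele = "G", eaf = maf,
        beta = beta_sbp, se = se_sbp,
        pvalue = pmax(2 * stats::pnorm(abs(beta_sbp / se_sbp),
                                       lower.tail = FALSE), 1e-300),
        n = n_sbp, trait = "SBP"
      )
      list(eqtl = eqtl, sbp = sbp,
           truth = tibble::tibble(gene = sprintf("EGENE%02d", g),
                                  validating = validating))
    })
    list(eqtl = purrr::map_dfr(rows, "eqtl"),
         sbp_stats = purrr::map_dfr(rows, "sbp"),
         truth = purrr::map_dfr(rows, "truth"))
  })
}

#' Write a simulated study to disk
#'
#' Writes the exposure/outcome tables, LD matrix and truth record in the
#' same TSV dialects the readers consume.
#'
#' @param pair Output of [generate_summary_pair()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_summary_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  to_disk <- function(x) {
    dplyr::select(
      dplyr::rename(x, SNP = "variant_id", CHR = "chromosome",
                    BP = "position", A1 = "effect_allele",
                    A2 = "other_allele", EAF = "eaf", BETA = "beta",
                    SE = "se", P = "pvalue", N = "n"),
      -"trait")
  }
  readr::write_tsv(to_disk(pair$exposure), file.path(dir, "exposure.tsv"))
  readr::write_tsv(to_disk(pair$outcome), file.path(dir, "outcome.tsv"))
  ld_df <- tibble::as_tibble(pair$ld$r2, .name_repair = "minimal")
  ld_out <- dplyr::bind_cols(tibble::tibble(SNP = pair$ld$variant_ids),
                             ld_df)
  readr::write_tsv(ld_out, file.path(dir, "ld.tsv"))
  readr::write_tsv(pair$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
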