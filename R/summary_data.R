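#' Default column-name dialect for GWAS summary statistics
#'
#' Maps the canonical field names used throughout the package to the
#' column headers found in common GWAS summary-statistic exports
#' (SNP/CHR/BP/A1/A2/EAF/BETA/SE/P/N).
#'
#' @return A named character vector: names are canonical fields
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`), values are the
#'   column names expected in the file.
#' @export
#' @examples
#' default_dialect()
default_dialect <- function() {
  c(
    variant_id = "SNP", chromosome = "CHR", position = "BP",
    effect_allele = "A1", other_allele = "A2", eaf = "EAF",
    beta = "BETA", se = "SE", pvalue = "P", n = "N"
  )
}

.canonical_fields <- function() names(default_dialect())

#' Read and validate GWAS summary statistics
#'
#' Reads a delimited (tab or comma, optionally gzipped) summary-statistics
#' file, renames columns to the canonical schema via `dialect`, upper-cases
#' alleles, and validates every row against the record invariants:
#' `effect_allele != other_allele`, both alleles in \{A,C,G,T\},
#' `se > 0`, `eaf` in \[0, 1\], `pvalue` in (0, 1\], `n > 0`.
#' Rows that violate an invariant are rejected; the number rejected is
#' reported with a warning and stored in the `n_rejected` attribute.
#'
#' @param path Path to a delimited file with a header row.
#' @param dialect Named character vector mapping canonical field names to
#'   the file's column names; see [default_dialect()].
#' @param trait Optional trait label attached to every record.
#' @param delim Field delimiter; `NULL` (default) guesses from the header
#'   line (tab if it contains one, comma otherwise).
#' @return A tibble of validated records with canonical columns, one row
#'   per retained variant. Attributes: `n_rejected` (count of dropped
#'   rows) and `rejected` (tibble of dropped rows with a `reason` column).
#' @export
read_summary_stats <- function(path, dialect = default_dialect(),
                               trait = NA_character_, delim = NULL) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dat <- raw[, unname(dialect)]
  names(dat) <- names(dialect)
  validate_summary_stats(tibble::as_tibble(dat), trait = trait)
}

#' Validate a summary-statistics table
#'
#' Coerces a raw table (canonical column names) to typed columns, enforces
#' the record invariants and splits off violating rows. Non-numeric `beta`
#' or `se` entries are a hard error listing the offending line numbers.
#'
#' @param dat A data frame with canonical columns (see [default_dialect()]).
#' @param trait Optional trait label.
#' @return A tibble of valid records; attributes `n_rejected`, `rejected`.
#' @export
validate_summary_stats <- function(dat, trait = NA_character_) {
  dat <- tibble::as_tibble(dat)
  req <- .canonical_fields()
  missing <- setdiff(req, names(dat))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  was_char <- is.character(dat$beta) || is.character(dat$se)
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- dplyr::mutate(
    dat,
    variant_id = as.character(.data$variant_id),
    chromosome = as.character(.data$chromosome),
    position = as.integer(num(.data$position)),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    eaf = num(.data$eaf), beta = num(.data$beta), se = num(.data$se),
    pvalue = num(.data$pvalue), n = num(.data$n)
  )

  if (was_char) {
    nonnum <- function(orig, coerced) {
      !is.na(orig) & !(orig %in% c("", "NA")) & is.na(coerced)
    }
    bad <- which(nonnum(as.character(dat$beta), out$beta) |
                   nonnum(as.character(dat$se), out$se))
    if (length(bad) > 0) {
      stop("non-numeric beta/se on line(s): ",
           paste(bad + 1L, collapse = ", "), " (line 1 = header)",
           call. = FALSE)
    }
  }

  ok <- !is.na(out$variant_id) & !is.na(out$beta) & !is.na(out$se) &
    !is.na(out$pvalue) & !is.na(out$eaf) &
    out$effect_allele %in% c("A", "C", "G", "T") &
    out$other_allele %in% c("A", "C", "G", "T") &
    out$effect_allele != out$other_allele &
    out$se > 0 & out$eaf >= 0 & out$eaf <= 1 &
    out$pvalue > 0 & out$pvalue <= 1 & !is.na(out$n) & out$n > 0

  rejected <- out[!ok, , drop = FALSE]
  kept <- out[ok, , drop = FALSE]
  if (!"trait" %in% names(kept) || !is.na(trait)) kept$trait <- trait
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " row(s) rejected for invariant violations",
            call. = FALSE)
  }
  attr(kept, "n_rejected") <- nrow(rejected)
  attr(kept, "rejected") <- rejected
  kept
}

#' Filter variants at genome-wide significance
#'
#' Keeps exactly the records with `pvalue` strictly below the threshold
#' (the conventional genome-wide level is 5e-8). Idempotent.
#'
#' @param records Summary-statistics tibble.
#' @param p_threshold Significance threshold; strict `<` is applied.
#' @return The filtered tibble (possibly zero rows).
#' @export
select_genomewide <- function(records, p_threshold = 5e-8) {
  dplyr::filter(records, .data$pvalue < p_threshold)
}

#' Construct an LD matrix object
#'
#' A square symmetric matrix of squared correlations (r-squared) between
#' variants, with unit diagonal, used by [clump()].
#'
#' @param r2 Square numeric matrix of squared correlations in \[0, 1\].
#' @param variant_ids Character vector of variant IDs in matrix order;
#'   defaults to the matrix dimnames.
#' @param positions Optional integer base-pair positions (1-based).
#' @param tol Symmetry tolerance.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2), positions = NULL,
                      tol = 1e-8) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(variant_ids)) stop("variant_ids required", call. = FALSE)
  if (length(variant_ids) != nrow(r2)) {
    stop("variant_ids length must match matrix dimension", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > tol) {
    stop("LD matrix is asymmetric beyond tolerance", call. = FALSE)
  }
  if (any(r2 < -tol | r2 > 1 + tol)) {
    stop("LD r-squared values must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(diag(r2) - 1)) > tol) {
    stop("LD matrix diagonal must be 1", call. = FALSE)
  }
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r2 = r2,
                 positions = positions),
            class = "ld_matrix")
}

#' Read an LD matrix from a delimited file
#'
#' Expects a square matrix with variant IDs as the header row and first
#' column.
#'
#' @param path File path (tab- or comma-delimited; optional gzip).
#' @param delim Delimiter; guessed from the header when `NULL`.
#' @return An `ld_matrix` object.
#' @export
read_ld_matrix <- function(path, delim = NULL) {
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  dat <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  ids <- as.character(dat[[1]])
  m <- as.matrix(dat[, -1])
  storage.mode(m) <- "double"
  ld_matrix(m, variant_ids = ids)
}

# r-squared between two variants; 0 (with one-time warning upstream) when
# either variant is absent from the panel
.ld_lookup <- function(ld, id_a, id_b) {
  if (is.null(ld)) return(0)
  ia <- match(id_a, ld$variant_ids)
  ib <- match(id_b, ld$variant_ids)
  if (is.na(ia) || is.na(ib)) return(0)
  ld$r2[ia, ib]
}

#' Greedy LD clumping of summary statistics
#'
#' Greedy index-variant selection by ascending p-value: the most
#' significant remaining variant becomes an index, and every remaining
#' variant on the same chromosome within `window_kb` (center-to-center
#' distance, 1-based coordinates) whose r-squared with that index exceeds
#' `r2_threshold` is removed. Ties in p-value are broken by smaller
#' standard error, then lexical variant ID. Variants absent from the LD
#' panel are treated as unlinked (r-squared 0) with a warning.
#'
#' @param records Summary-statistics tibble (validated).
#' @param ld An `ld_matrix`, or `NULL` to treat all pairs as unlinked.
#' @param r2_threshold Removal threshold on squared correlation; the
#'   retained set has all within-window pairs at or below it.
#' @param window_kb Window half-width in kilobases.
#' @return Tibble of retained index variants, ordered by ascending p-value.
#' @export
clump <- function(records, ld = NULL, r2_threshold = 0.001,
                  window_kb = 10000) {
  if (nrow(records) == 0) return(records)
  ord <- order(records$pvalue, records$se,
               records$variant_id, method = "radix")
  rec <- records[ord, , drop = FALSE]
  if (!is.null(ld)) {
    absent <- setdiff(rec$variant_id, ld$variant_ids)
    if (length(absent) > 0) {
      warning(length(absent),
              " variant(s) absent from the LD panel treated as unlinked",
              call. = FALSE)
    }
  }
  window_bp <- window_kb * 1000
  n <- nrow(rec)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    if (i == n) break
    for (j in seq.int(i + 1L, n)) {
      if (!alive[j]) next
      same_chr <- identical(rec$chromosome[j], rec$chromosome[i])
      in_window <- same_chr &&
        abs(rec$position[j] - rec$position[i]) <= window_bp
      if (in_window &&
          .ld_lookup(ld, rec$variant_id[i], rec$variant_id[j]) > r2_threshold) {
        alive[j] <- FALSE
      }
    }
  }
  rec[keep, , drop = FALSE]
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) unname(.complement[a1] == a2)

#' Harmonize exposure and outcome summary statistics
#'
#' Joins exposure and outcome records on variant ID and expresses both
#' effects on the exposure's effect allele. Outcome records whose alleles
#' are swapped relative to the exposure have their beta negated and
#' effect-allele frequency complemented; strand-flipped (complemented)
#' alleles are recognised and aligned. Palindromic variants (A/T, C/G)
#' are dropped under `palindrome_policy = "drop"`, or oriented by allele
#' frequency under `"infer_by_frequency"`: both frequencies must fall
#' outside the ambiguous band (`freq_cutoff`, 1 - `freq_cutoff`),
#' otherwise the variant is dropped. Irreconcilable allele pairs are
#' dropped with a reason, never silently aligned.
#'
#' @param exposure,outcome Validated summary-statistics tibbles.
#' @param palindrome_policy `"infer_by_frequency"` (default) or `"drop"`.
#' @param freq_cutoff Ambiguity cutoff for frequency inference: a
#'   frequency is informative when `eaf <= freq_cutoff` or
#'   `eaf >= 1 - freq_cutoff`. Default 0.42.
#' @return Tibble of harmonized instruments: `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `eaf_exposure`, `eaf_outcome`,
#'   `chromosome`, `position`, `pvalue_exposure`, `palindromic`,
#'   `action_taken` (\{unchanged, allele_flip, dropped\}) and
#'   `drop_reason`. Attributes `n_absent` (variants missing from the
#'   outcome) and `n_dropped`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_frequency", "drop"),
                      freq_cutoff = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  n_absent <- length(setdiff(exposure$variant_id, shared))

  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  e1 <- ex$effect_allele; e2 <- ex$other_allele
  o1 <- ou$effect_allele; o2 <- ou$other_allele
  c1 <- unname(.complement[o1]); c2 <- unname(.complement[o2])
  pal <- .is_palindromic(e1, e2)

  direct <- o1 == e1 & o2 == e2
  swapped <- o1 == e2 & o2 == e1
  strand <- c1 == e1 & c2 == e2
  strand_swapped <- c1 == e2 & c2 == e1

  informative <- function(f) f <= freq_cutoff | f >= 1 - freq_cutoff
  pal_same_alleles <- pal & (direct | swapped)
  pal_ambiguous <- pal_same_alleles & palindrome_policy != "drop" &
    !(informative(ex$eaf) & informative(ou$eaf))
  # a palindrome's allele labels carry no strand information;
  # orientation comes from the frequency side alone
  pal_flip <- pal_same_alleles & !pal_ambiguous &
    ((ex$eaf < 0.5) != (ou$eaf < 0.5))

  action <- dplyr::case_when(
    pal & !pal_same_alleles ~ "dropped",
    pal & palindrome_policy == "drop" ~ "dropped",
    pal_ambiguous ~ "dropped",
    pal_flip ~ "allele_flip",
    pal ~ "unchanged",
    direct | strand ~ "unchanged",
    swapped | strand_swapped ~ "allele_flip",
    TRUE ~ "dropped"
  )
  reason <- dplyr::case_when(
    pal & !pal_same_alleles ~ "allele_mismatch",
    pal & palindrome_policy == "drop" ~ "palindromic",
    pal_ambiguous ~ "palindromic_ambiguous_frequency",
    action == "dropped" ~ "allele_mismatch",
    TRUE ~ NA_character_
  )
  flip <- action == "allele_flip"

  res <- tibble::tibble(
    variant_id = shared,
    effect_allele = e1, other_allele = e2,
    beta_exposure = ex$beta, se_exposure = ex$se,
    beta_outcome = ifelse(flip, -ou$beta, ou$beta),
    se_outcome = ou$se,
    eaf_exposure = ex$eaf,
    eaf_outcome = ifelse(flip, 1 - ou$eaf, ou$eaf),
    chromosome = ex$chromosome, position = ex$position,
    pvalue_exposure = ex$pvalue,
    palindromic = pal, action_taken = action, drop_reason = reason
  )
  attr(res, "n_absent") <- n_absent
  attr(res, "n_dropped") <- sum(res$action_taken == "dropped")
  res
}

#' Keep only retained harmonized instruments
#'
#' @param harmonized Output of [harmonize()].
#' @return The rows with `action_taken != "dropped"`.
#' @export
keep_harmonized <- function(harmonized) {
  dplyr::filter(harmonized, .data$action_taken != "dropped")
}

#' Check that harmonization is an involution
#'
#' Re-harmonizing an already-harmonized exposure/outcome pair must be the
#' identity: every retained variant comes back unchanged with identical
#' effects.
#'
#' @param harmonized Output of [harmonize()].
#' @return `TRUE` if re-harmonization changes nothing, else `FALSE`.
#' @export
harmonize_involution_check <- function(harmonized) {
  h <- keep_harmonized(harmonized)
  if (nrow(h) == 0) return(TRUE)
  as_stats <- function(beta, se, eaf) {
    tibble::tibble(
      variant_id = h$variant_id, chromosome = h$chromosome,
      position = h$position, effect_allele = h$effect_allele,
      other_allele = h$other_allele, eaf = eaf, beta = beta, se = se,
      pvalue = pmin(1, pmax(1e-300, h$pvalue_exposure)), n = 1e5
    )
  }
  ex <- as_stats(h$beta_exposure, h$se_exposure, h$eaf_exposure)
  ou <- as_stats(h$beta_outcome, h$se_outcome, h$eaf_outcome)
  re <- keep_harmonized(harmonize(ex, ou, palindrome_policy = "infer_by_frequency"))
  if (nrow(re) != nrow(h)) return(FALSE)
  all(re$action_taken == "unchanged") &&
    isTRUE(all.equal(re$beta_outcome, h$beta_outcome)) &&
    isTRUE(all.equal(re$eaf_outcome, h$eaf_outcome))
}

#' Write a harmonized instrument table
#'
#' @param harmonized Output of [harmonize()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(harmonized, path) {
  readr::write_tsv(harmonized, path)
  invisible(path)
}
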