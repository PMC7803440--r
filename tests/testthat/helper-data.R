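# Small fixture builders shared across test files.

make_stats <- function(variant_id, chromosome = "1",
                       position = seq_along(variant_id) * 1e5,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.1, se = 0.01,
                       pvalue = 1e-10, n = 1e5, trait = "SBP") {
  tibble::tibble(
    variant_id = variant_id, chromosome = chromosome,
    position = as.integer(position), effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf, beta = beta, se = se,
    pvalue = pvalue, n = n, trait = trait
  )
}

make_instruments <- function(j, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      variant_id = sprintf("rs%03d", seq_len(j)),
      beta_exposure = stats::rnorm(j, 0.05, 0.03),
      se_exposure = stats::runif(j, 0.001, 0.01),
      beta_outcome = stats::rnorm(j, 0.001, 0.01),
      se_outcome = stats::runif(j, 0.005, 0.05)
    )
  })
}

write_stats_tsv <- function(dat, path) {
  out <- dplyr::rename(dat, SNP = "variant_id", CHR = "chromosome",
                       BP = "position", A1 = "effect_allele",
                       A2 = "other_allele", EAF = "eaf", BETA = "beta",
                       SE = "se", P = "pvalue", N = "n")
  out$trait <- NULL
  readr::write_tsv(out, path)
  path
}
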