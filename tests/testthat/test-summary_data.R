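test_that("reading a well-formed table yields validated records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_tsv(make_stats(c("rs1", "rs2", "rs3")), path)
  rec <- read_summary_stats(path)
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "n_rejected"), 0)
  expect_type(rec$beta, "double")
  expect_equal(rec$variant_id, c("rs1", "rs2", "rs3"))
})

test_that("rows violating invariants are rejected and counted", {
  path <- withr::local_tempfile(fileext = ".tsv")
  dat <- make_stats(c("rs1", "rs2"))
  dat$se[2] <- 0
  write_stats_tsv(dat, path)
  expect_warning(rec <- read_summary_stats(path), "rejected")
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "n_rejected"), 1)
  expect_equal(attr(rec, "rejected")$variant_id, "rs2")
})

test_that("lowercase alleles are upper-cased with effects untouched", {
  path <- withr::local_tempfile(fileext = ".tsv")
  dat <- make_stats(c("rs1", "rs2"), beta = c(0.12, -0.05))
  dat$effect_allele <- c("a", "c")
  dat$other_allele <- c("g", "t")
  write_stats_tsv(dat, path)
  rec <- read_summary_stats(path)
  expect_equal(rec$effect_allele, c("A", "C"))
  expect_equal(rec$other_allele, c("G", "T"))
  expect_equal(rec$beta, c(0.12, -0.05))
})

test_that("missing mandatory columns and non-numeric effects error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  dat <- make_stats("rs1")
  out <- write_stats_tsv(dat, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  readr::write_tsv(dplyr::select(tab, -"BETA"), path)
  expect_error(read_summary_stats(path), "missing mandatory column")

  write_stats_tsv(make_stats(c("rs1", "rs2")), path)
  lines <- readLines(path)
  lines[3] <- sub("0.1", "not_a_number", lines[3])
  writeLines(lines, path)
  expect_error(read_summary_stats(path), "line")
})

test_that("genome-wide selection is strict and idempotent", {
  rec <- make_stats(c("rs1", "rs2", "rs3"),
                    pvalue = c(1e-9, 5e-8, 1e-7))
  kept <- select_genomewide(rec, 5e-8)
  expect_equal(kept$variant_id, "rs1")  # 5e-8 itself excluded
  expect_equal(select_genomewide(kept, 5e-8), kept)
  expect_equal(nrow(select_genomewide(rec[0, ], 5e-8)), 0)
  all_sig <- make_stats(c("a", "b"), pvalue = 1e-10)
  expect_equal(nrow(select_genomewide(all_sig, 5e-8)), 2)
})

test_that("clumping retains the hand-worked index set", {
  rec <- make_stats(c("SNP1", "SNP2", "SNP3"),
                    position = c(1e6, 1.1e6, 1.2e6),
                    pvalue = c(1e-10, 1e-9, 1e-8))
  r2 <- matrix(c(1, 0.5, 5e-4,
                 0.5, 1, 5e-4,
                 5e-4, 5e-4, 1), 3, 3,
               dimnames = list(rec$variant_id, rec$variant_id))
  ld <- ld_matrix(r2)
  out <- clump(rec, ld, r2_threshold = 0.001, window_kb = 10000)
  expect_equal(out$variant_id, c("SNP1", "SNP3"))

  # unlinked variants all survive; a fully linked locus keeps best p only
  ld0 <- ld_matrix(diag(3), variant_ids = rec$variant_id)
  expect_equal(nrow(clump(rec, ld0, 0.001, 10000)), 3)
  r2_one <- matrix(1, 3, 3, dimnames = list(rec$variant_id, rec$variant_id))
  out1 <- clump(rec, ld_matrix(r2_one), 0.001, 10000)
  expect_equal(out1$variant_id, "SNP1")
})

test_that("variants beyond the window or missing from the panel stay", {
  rec <- make_stats(c("SNP1", "SNP2"), position = c(1e6, 1e6 + 1.1e7),
                    pvalue = c(1e-10, 1e-9))
  r2 <- matrix(c(1, 1, 1, 1), 2, 2,
               dimnames = list(rec$variant_id, rec$variant_id))
  out <- clump(rec, ld_matrix(r2), 0.001, window_kb = 10000)
  expect_equal(nrow(out), 2)  # 11 Mb apart, outside the 10 000 kb window

  ld_partial <- ld_matrix(matrix(1, 1, 1), variant_ids = "SNP1")
  rec2 <- make_stats(c("SNP1", "SNP2"), position = c(1e6, 1.1e6),
                     pvalue = c(1e-10, 1e-9))
  expect_warning(out2 <- clump(rec2, ld_partial, 0.001, 10000),
                 "absent from the LD panel")
  expect_equal(nrow(out2), 2)
})

test_that("an asymmetric LD matrix is refused", {
  m <- matrix(c(1, 0.2, 0.6, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(ld_matrix(m), "asymmetric")
})

test_that("clumping matches the exhaustive greedy reference on random instances", {
  withr::with_seed(42, {
    for (case in seq_len(200)) {
      j <- sample(2:12, 1)
      ids <- sprintf("v%02d", seq_len(j))
      rec <- make_stats(ids,
                        position = sort(sample.int(3e7, j)),
                        pvalue = stats::runif(j)^3,
                        se = stats::runif(j, 0.005, 0.02))
      a <- matrix(stats::runif(j * j), j, j)
      r2 <- (a + t(a)) / 2
      diag(r2) <- 1
      dimnames(r2) <- list(ids, ids)
      thr <- stats::runif(1, 0.001, 0.8)
      win <- sample(c(100, 5000, 10000), 1)
      got <- clump(rec, ld_matrix(r2), thr, win)$variant_id
      want <- oracle_clump_ids(rec, r2, thr, win * 1000)
      expect_identical(got, want)
    }
  })
})

test_that("every clump removal is justified by a retained better variant", {
  withr::with_seed(7, {
    j <- 10
    ids <- sprintf("v%02d", seq_len(j))
    rec <- make_stats(ids, position = sort(sample.int(5e6, j)),
                      pvalue = stats::runif(j))
    a <- matrix(stats::runif(j * j), j, j)
    r2 <- (a + t(a)) / 2; diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)
    kept <- clump(rec, ld_matrix(r2), 0.3, 10000)
    removed <- setdiff(ids, kept$variant_id)
    for (v in removed) {
      pv <- rec$pvalue[rec$variant_id == v]
      linked <- vapply(kept$variant_id, function(k)
        r2[v, k] > 0.3 && rec$pvalue[rec$variant_id == k] <= pv,
        logical(1))
      expect_true(any(linked))
    }
    # retained pairs within the window are mutually unlinked
    for (i in seq_len(nrow(kept))) for (k in seq_len(nrow(kept))) {
      if (i < k &&
          abs(kept$position[i] - kept$position[k]) <= 1e7) {
        expect_lte(r2[kept$variant_id[i], kept$variant_id[k]], 0.3)
      }
    }
  })
})

test_that("allele flips negate the outcome effect and complement its frequency", {
  ex <- make_stats("rs1", effect_allele = "A", other_allele = "G",
                   beta = 0.10)
  ou <- make_stats("rs1", effect_allele = "G", other_allele = "A",
                   beta = -0.05, eaf = 0.30)
  h <- harmonize(ex, ou)
  expect_equal(h$action_taken, "allele_flip")
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$eaf_outcome, 0.70)
  expect_equal(h$effect_allele, "A")

  same <- harmonize(ex, make_stats("rs1", effect_allele = "A",
                                   other_allele = "G", beta = 0.05))
  expect_equal(same$action_taken, "unchanged")
  expect_equal(same$beta_outcome, 0.05)
})

test_that("palindromic variants follow the frequency policy", {
  ex <- make_stats("rs1", effect_allele = "A", other_allele = "T",
                   eaf = 0.50)
  ou <- make_stats("rs1", effect_allele = "A", other_allele = "T",
                   eaf = 0.50, beta = 0.02)
  h <- harmonize(ex, ou, palindrome_policy = "infer_by_frequency",
                 freq_cutoff = 0.42)
  expect_equal(h$action_taken, "dropped")
  expect_equal(h$drop_reason, "palindromic_ambiguous_frequency")

  # informative frequencies on opposite sides imply a strand flip
  ex2 <- make_stats("rs2", effect_allele = "C", other_allele = "G",
                    eaf = 0.10)
  ou2 <- make_stats("rs2", effect_allele = "C", other_allele = "G",
                    eaf = 0.90, beta = 0.03)
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$action_taken, "allele_flip")
  expect_equal(h2$beta_outcome, -0.03)
  expect_equal(h2$eaf_outcome, 0.10)

  expect_equal(
    harmonize(ex, ou, palindrome_policy = "drop")$drop_reason,
    "palindromic")
})

test_that("irreconcilable allele pairs are dropped with a reason", {
  ex <- make_stats("rs1", effect_allele = "A", other_allele = "G")
  ou <- make_stats("rs1", effect_allele = "A", other_allele = "C")
  h <- harmonize(ex, ou)
  expect_equal(h$action_taken, "dropped")
  expect_equal(h$drop_reason, "allele_mismatch")
})

test_that("harmonization conserves |beta| and is an involution", {
  withr::with_seed(11, {
    j <- 30
    ids <- sprintf("rs%03d", seq_len(j))
    al <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                 ncol = 2, byrow = TRUE)
    pick <- sample(nrow(al), j, replace = TRUE)
    ex <- make_stats(ids, effect_allele = al[pick, 1],
                     other_allele = al[pick, 2],
                     beta = stats::rnorm(j), eaf = stats::runif(j, 0.1, 0.35))
    ou <- ex
    flip <- sample(c(TRUE, FALSE), j, replace = TRUE)
    ou$effect_allele[flip] <- ex$other_allele[flip]
    ou$other_allele[flip] <- ex$effect_allele[flip]
    ou$beta <- ifelse(flip, -ex$beta, ex$beta) + 0.01
    ou$eaf <- ifelse(flip, 1 - ex$eaf, ex$eaf)

    h <- harmonize(ex, ou)
    kept <- keep_harmonized(h)
    expect_setequal(round(abs(kept$beta_outcome), 12),
                    round(abs(ou$beta[match(kept$variant_id,
                                            ou$variant_id)]), 12))
    expect_true(harmonize_involution_check(h))

    expect_true(harmonize_involution_check(h[0, ]))
  })

  # an artificially re-flipped palindromic record breaks the involution:
  # its frequencies now sit on opposite sides of 0.5, so a second
  # harmonization pass would flip it again
  pal <- harmonize(
    make_stats("rs9", effect_allele = "A", other_allele = "T", eaf = 0.1),
    make_stats("rs9", effect_allele = "A", other_allele = "T", eaf = 0.1,
               beta = 0.04))
  expect_true(harmonize_involution_check(pal))
  tampered <- pal
  tampered$eaf_outcome <- 0.9
  expect_false(harmonize_involution_check(tampered))
})

test_that("variants absent from the outcome are dropped and counted", {
  ex <- make_stats(c("rs1", "rs2", "rs3"))
  ou <- make_stats(c("rs1", "rs3"))
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 2)
  expect_equal(attr(h, "n_absent"), 1)
})
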