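instr <- function(bx, by, sey, sex = 0.001) {
  tibble::tibble(beta_exposure = bx, se_exposure = sex,
                 beta_outcome = by, se_outcome = sey)
}

test_that("Wald ratios follow the first-order formula and its symmetries", {
  w <- wald_ratios(instr(0.5, 0.1, 0.05))
  expect_equal(w$ratio, 0.2)
  expect_equal(w$ratio_se, 0.1)
  expect_equal(wald_ratios(instr(0.5, 0, 0.05))$ratio, 0)
  # joint sign flip leaves the ratio unchanged
  expect_equal(wald_ratios(instr(-0.5, -0.1, 0.05))$ratio, 0.2)
  expect_warning(out <- wald_ratios(instr(c(0, 0.5), c(0.1, 0.1), 0.05)),
                 "zero exposure effect")
  expect_equal(nrow(out), 1)
})

test_that("IVW reproduces hand-computed weighted least squares", {
  one <- mr_ivw(instr(0.5, 0.1, 0.05))
  expect_equal(one$beta, 0.2)
  expect_equal(one$se, 0.1)

  two <- mr_ivw(instr(c(1, 1), c(0.1, 0.3), c(0.1, 0.1)))
  expect_equal(two$beta, 0.2)
  expect_equal(two$cochran_q, 2)
  expect_equal(two$se, 0.1)  # random-effects: 0.0707 * sqrt(2/1)
  expect_equal(mr_ivw(instr(c(1, 1), c(0.1, 0.3), c(0.1, 0.1)),
                      random_effects = FALSE)$se, sqrt(1 / 200))

  null <- mr_ivw(instr(c(1, 2), c(0, 0), c(0.1, 0.1)))
  expect_equal(null$beta, 0)
  expect_error(mr_ivw(instr(numeric(0), numeric(0), numeric(0))),
               "at least one")
})

test_that("random-effects SE is floored at the fixed-effects SE", {
  withr::with_seed(3, {
    for (k in 1:20) {
      d <- make_instruments(sample(3:12, 1), seed = k)
      re <- mr_ivw(d, random_effects = TRUE)
      fe <- mr_ivw(d, random_effects = FALSE)
      expect_equal(re$beta, fe$beta)
      expect_gte(re$se, fe$se)
      if (re$cochran_q <= re$n_snp - 1) expect_equal(re$se, fe$se)
      expect_lt(re$ci_low, re$beta); expect_gt(re$ci_high, re$beta)
      expect_equal(re$or_per_10, exp(10 * re$beta))
    }
  })
})

test_that("the weighted median interpolates the cumulative weights at 0.5", {
  # ratios 0.1, 0.2, 0.6 realised with beta_exposure 1
  eq <- mr_weighted_median(instr(c(1, 1, 1), c(0.1, 0.2, 0.6), 1),
                           n_boot = 10)
  expect_equal(eq$beta, 0.2)

  # weights 1, 1, 2 via se_outcome 1, 1, 1/sqrt(2)
  wtd <- mr_weighted_median(
    instr(c(1, 1, 1), c(0.1, 0.2, 0.6), c(1, 1, 1 / sqrt(2))),
    n_boot = 10)
  expect_equal(wtd$beta, 1 / 3, tolerance = 1e-12)

  const <- mr_weighted_median(instr(c(1, 2, 4), c(0.3, 0.6, 1.2),
                                    c(0.2, 0.5, 0.1)), n_boot = 10)
  expect_equal(const$beta, 0.3)
  expect_error(mr_weighted_median(instr(c(1, 1), c(0, 0), c(1, 1))),
               "at least 3")
})

test_that("weighted median equals the sample median for equal weights, odd J", {
  withr::with_seed(5, {
    for (k in 1:10) {
      j <- sample(c(3, 5, 7, 9), 1)
      by <- stats::rnorm(j)
      est <- mr_weighted_median(instr(rep(1, j), by, rep(0.3, j)),
                                n_boot = 10)
      expect_equal(est$beta, stats::median(by))
    }
  })
})

test_that("weighted-median bootstrap SE is reproducible and leaves the RNG alone", {
  d <- make_instruments(8, seed = 2)
  before <- withr::with_seed(99, stats::runif(1))
  a <- mr_weighted_median(d, n_boot = 200, seed = 7)
  b <- mr_weighted_median(d, n_boot = 200, seed = 7)
  expect_equal(a$se, b$se)
  expect_gt(a$se, 0)
  after <- withr::with_seed(99, stats::runif(1))
  expect_equal(before, after)
})

test_that("Egger recovers exact linear data and re-orients sign flips", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  exact <- mr_egger(instr(bx, 0.05 + 0.2 * bx, 0.05))
  slope <- exact[exact$method == "egger_slope", ]
  icpt <- exact[exact$method == "egger_intercept", ]
  expect_equal(slope$beta, 0.2)
  expect_equal(icpt$beta, 0.05)
  expect_equal(slope$cochran_q, 0, tolerance = 1e-20)

  # data through the origin: intercept 0, slope equals IVW
  origin <- mr_egger(instr(bx, 0.2 * bx, 0.05))
  expect_equal(origin[origin$method == "egger_intercept", ]$beta, 0,
               tolerance = 1e-12)
  expect_equal(origin[origin$method == "egger_slope", ]$beta,
               mr_ivw(instr(bx, 0.2 * bx, 0.05))$beta, tolerance = 1e-12)

  # negating one instrument's pair is undone by the orientation step
  d <- make_instruments(6, seed = 4)
  d2 <- d
  d2$beta_exposure[2] <- -d2$beta_exposure[2]
  d2$beta_outcome[2] <- -d2$beta_outcome[2]
  e1 <- mr_egger(d); e2 <- mr_egger(d2)
  expect_equal(e1$beta, e2$beta)
  expect_equal(e1$se, e2$se)

  expect_error(mr_egger(instr(c(1, 1), c(0, 0), c(1, 1))), "at least 3")
  expect_error(mr_egger(instr(c(1, 1, 1), c(0, 0, 0.1), c(1, 1, 1))),
               "variation")
})

test_that("estimates scale inversely with the exposure units", {
  d <- make_instruments(9, seed = 6)
  for (c_scale in c(0.5, 2, 10)) {
    d2 <- dplyr::mutate(d, beta_exposure = beta_exposure * c_scale,
                        se_exposure = se_exposure * c_scale)
    expect_equal(mr_ivw(d2)$beta, mr_ivw(d)$beta / c_scale)
    expect_equal(mr_egger(d2)$beta[1], mr_egger(d)$beta[1] / c_scale)
    expect_equal(mr_weighted_median(d2, n_boot = 10)$beta,
                 mr_weighted_median(d, n_boot = 10)$beta / c_scale)
  }
})

test_that("per-10-mmHg odds ratios match the reporting convention", {
  est <- mr_ivw(instr(1, 0.0157, 0.004))
  expect_equal(est$or_per_10, exp(0.157))
  expect_equal(round(est$or_per_10, 2), 1.17)
  est0 <- to_or_per_10mmHg(dplyr::mutate(est, beta = 0, ci_low = -0.01,
                                         ci_high = 0.01))
  expect_equal(est0$or_per_10, 1)
  estn <- to_or_per_10mmHg(dplyr::mutate(est, beta = -0.0416))
  expect_equal(round(estn$or_per_10, 2), 0.66)
})

test_that("mr_analysis bundles methods and supports tidy/glance/autoplot", {
  d <- make_instruments(12, seed = 8)
  fit <- mr_analysis(d, n_boot = 50, seed = 3, exposure = "SBP",
                     outcome = "AF")
  td <- tidy(fit)
  expect_setequal(td$method, c("ivw_random_effects", "weighted_median",
                               "egger_slope", "egger_intercept"))
  expect_equal(unique(td$exposure), "SBP")
  gl <- glance(fit)
  expect_equal(gl$n_snp, 12)
  expect_false(is.na(gl$egger_intercept_p))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  # fewer than 3 instruments: only IVW is fitted
  small <- mr_analysis(d[1:2, ])
  expect_equal(small$estimates$method, "ivw_random_effects")
})
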