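# Genotype association: agreement with explicit normal-equations fits,
# coding equivalences, variance explained, Bonferroni bookkeeping, and QQ
# coordinates.

test_that("additive fit matches the explicit normal-equations oracle", {
  set.seed(12)
  co <- toy_cohort(rbinom(12, 2, 0.6), seed = 12)
  co$y <- rnorm(12) + 0.7 * co$allele_count
  res <- pqtl_test(co, "y")
  X <- cbind(1, co$allele_count, co$sex == "male", co$race == "Caucasian")
  o <- ols_oracle(X, co$y, 2)
  expect_equal(res$beta, o$beta, tolerance = 1e-8)
  expect_equal(res$se, o$se, tolerance = 1e-8)
  expect_equal(res$p_value, o$p, tolerance = 1e-8)

  # recessive coding against the same oracle
  res_r <- pqtl_test(co, "y", model = "recessive")
  Xr <- cbind(1, co$allele_count < 2, co$sex == "male", co$race == "Caucasian")
  or_ <- ols_oracle(Xr, co$y, 2)
  expect_equal(res_r$beta, or_$beta, tolerance = 1e-8)
  expect_equal(res_r$p_value, or_$p, tolerance = 1e-8)
})

test_that("a constant response gives a null association", {
  co <- toy_cohort(c(0, 1, 2, 1, 0, 2, 1, 1, 2, 0))
  co$y <- rep(3.7, 10)
  res <- pqtl_test(co, "y")
  expect_equal(res$beta, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$r2_genotype, 0)
})

test_that("additive and recessive tests coincide on a binary genotype", {
  set.seed(3)
  co <- toy_cohort(sample(c(1L, 2L), 30, replace = TRUE), seed = 3)
  co$y <- rnorm(30) - 0.4 * (co$allele_count < 2)
  ra <- pqtl_test(co, "y", model = "additive")
  rr <- pqtl_test(co, "y", model = "recessive")
  expect_equal(abs(ra$beta), abs(rr$beta), tolerance = 1e-10)
  expect_equal(ra$p_value, rr$p_value, tolerance = 1e-10)
})

test_that("the recessive test without covariates equals the pooled t-test", {
  set.seed(4)
  co <- toy_cohort(c(rep(2L, 12), rep(1L, 10)), seed = 4)
  co$y <- rnorm(22) + 0.8 * (co$allele_count < 2)
  res <- pqtl_test(co, "y", covariates = character(0), model = "recessive")
  tt <- t.test(co$y[co$allele_count < 2], co$y[co$allele_count == 2],
               var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
})

test_that("degenerate designs raise classed errors", {
  co <- toy_cohort(rep(2L, 10))
  co$y <- rnorm(10)
  expect_error(pqtl_test(co, "y", model = "recessive"),
               class = "metapqtl_undefined_test_error")
  co2 <- toy_cohort(rbinom(20, 2, 0.5), seed = 5)
  co2$y <- rnorm(20)
  co2$dup <- co2$allele_count  # perfectly collinear with the genotype term
  err <- expect_error(pqtl_test(co2, "y", covariates = c("sex", "dup")),
                      class = "metapqtl_collinearity_error")
  expect_match(conditionMessage(err), "dup")
})

test_that("variance explained follows its definition", {
  co <- toy_cohort(c(0, 0, 1, 1, 2, 2), seed = 6)
  co$y <- 2 + 1.5 * co$allele_count          # exact linear function
  ve <- suppressWarnings(variance_explained(co, "y"))
  expect_equal(ve$r2_genotype, 1, tolerance = 1e-12)

  # hand-computed 6-sample instance: r2 = 1 - SSE/SST
  co$y2 <- c(1.0, 2.0, 1.5, 2.5, 3.0, 2.0)
  f <- lm(y2 ~ allele_count, co)
  r2_hand <- 1 - sum(residuals(f)^2) / sum((co$y2 - mean(co$y2))^2)
  expect_equal(variance_explained(co, "y2")$r2_genotype, r2_hand,
               tolerance = 1e-12)

  # independence: r2 shrinks to noise level at large n
  set.seed(7)
  big <- toy_cohort(rbinom(1000, 2, 0.7), seed = 7)
  big$y <- rnorm(1000)
  expect_lte(variance_explained(big, "y")$r2_genotype, 0.05)
})

test_that("p is invariant to affine changes of the response; beta scales", {
  set.seed(8)
  co <- toy_cohort(rbinom(25, 2, 0.6), seed = 8)
  co$y <- rnorm(25) + 0.5 * co$allele_count
  base <- pqtl_test(co, "y")
  co$y2 <- 3 * co$y + 10
  scaled <- pqtl_test(co, "y2")
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-12)
  expect_equal(scaled$beta, 3 * base$beta, tolerance = 1e-12)
  co$y3 <- -co$y
  expect_equal(pqtl_test(co, "y3")$beta, -base$beta, tolerance = 1e-12)
})

test_that("the scan divides alpha by the number of tests and flags hits", {
  sim <- simulate_study(sim_config(seed = 17))
  fit <- fit_metaproteins(sim$peptides)
  one <- pqtl_scan(fit$scores[c("sample_id", names(fit$factors)[1])], sim$cohort)
  expect_equal(one$bonferroni_alpha, 0.05)
  full <- pqtl_scan(fit$scores, sim$cohort)
  expect_equal(full$bonferroni_alpha, 0.05 / 10)
  expect_equal(full$n_tests, 10L)
  expect_true(full$results$significant[full$results$target_id == "PROT01"])

  # a constant column yields a null row; an unusable one is skipped, not fatal
  sc <- fit$scores
  sc$flat <- 1
  flat_scan <- pqtl_scan(sc, sim$cohort)
  flat_row <- flat_scan$results[flat_scan$results$target_id == "flat", ]
  expect_equal(flat_row$p_value, 1)
  sc$flat <- NA_real_
  expect_warning(sk <- pqtl_scan(sc, sim$cohort), "skipped")
  expect_equal(sk$n_tests, 10L)
  expect_true("flat" %in% sk$skipped)
})

test_that("QQ coordinates follow the mid-rank uniform quantiles", {
  pt <- qq_points(0.5)
  expect_equal(pt$expected, -log10(0.5), tolerance = 1e-10)
  expect_equal(pt$observed, -log10(0.5), tolerance = 1e-10)

  # the top observed point for a strong hit among 110 tests
  p <- c(9.2e-6, runif(109, 0.05, 1))
  qq <- qq_points(p)
  expect_equal(qq$observed[1], 5.036, tolerance = 1e-3)
  expect_equal(qq$expected[1], -log10(0.5 / 110), tolerance = 1e-10)

  # permutation invariance of the observed coordinates
  expect_equal(qq_points(sample(p))$observed, qq$observed)

  # uniform p-values track the identity line
  set.seed(9)
  u <- qq_points(runif(1000))
  expect_lt(max(abs(u$observed - u$expected)), 0.5)

  expect_error(qq_points(c(0.5, 0)), class = "metapqtl_domain_error")
  expect_error(qq_points(c(0.5, 1.2)), class = "metapqtl_domain_error")
})

test_that("peptide-level tests agree with the scan on the score itself", {
  sim <- simulate_study(sim_config(seed = 19, missing_rate = 0,
                                   residual_sd = 0.2))
  fit <- fit_metaproteins(sim$peptides)
  scan <- pqtl_scan(fit$scores, sim$cohort)
  # feed the score back through the generic test: same numbers as the scan
  d <- dplyr::inner_join(fit$scores, sim$cohort, by = "sample_id")
  direct <- pqtl_test(d, "PROT01")
  entry <- scan$results[scan$results$target_id == "PROT01", ]
  expect_equal(direct$beta, entry$beta, tolerance = 1e-12)
  expect_equal(direct$p_value, entry$p_value, tolerance = 1e-12)

  # member peptides of the true pQTL factor are individually significant
  pep <- peptide_tests(sim$peptides, fit$factors$PROT01$members$feature_id,
                       sim$cohort)
  expect_equal(unique(pep$bonferroni_alpha),
               0.05 / nrow(fit$factors$PROT01$members))
  expect_true(all(pep$significant[pep$target_id %in%
    sim$peptides$feature_id[sim$peptides$protein_id == "PROT01"]]))
})
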