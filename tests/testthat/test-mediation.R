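# Nested logistic fits: agreement with hand-coded Newton-Raphson and glm,
# exact contingency-table odds ratios, profile intervals against the
# established profiling implementation, separation handling, and the
# attenuation verdict on scenarios with known causal structure.

test_that("the logistic fit matches hand-coded Newton-Raphson and glm", {
  set.seed(5)
  d <- toy_cohort(rbinom(40, 2, 0.6), seed = 5)
  d$x <- rnorm(40)
  d$out <- rbinom(40, 1, plogis(0.2 + 0.8 * d$x))
  res <- logistic_fit(d, "out", "x", event = "SVR")

  X <- cbind(1, d$x, d$sex == "male", d$race == "Caucasian")
  beta_ref <- logit_oracle(X, d$out)
  expect_equal(res$beta, beta_ref[2], tolerance = 1e-8)

  g <- glm(out ~ x + sex + race, binomial, d)
  expect_equal(res$beta, unname(coef(g)["x"]), tolerance = 1e-8)
  expect_equal(res$se,
               unname(summary(g)$coefficients["x", "Std. Error"]),
               tolerance = 1e-6)
  lrt_p <- anova(glm(out ~ sex + race, binomial, d), g, test = "LRT")$`Pr(>Chi)`[2]
  expect_equal(res$p_value, lrt_p, tolerance = 1e-8)
})

test_that("profile intervals agree with the established profiler", {
  set.seed(6)
  d <- toy_cohort(rbinom(60, 2, 0.6), seed = 6)
  d$x <- rnorm(60)
  d$out <- rbinom(60, 1, plogis(0.1 + 0.7 * d$x))
  res <- logistic_fit(d, "out", "x")
  g <- glm(out ~ x + sex + race, binomial, d)
  ref <- suppressMessages(exp(confint(g, "x", level = 0.95)))
  expect_equal(unname(res$conf.low), unname(ref[1]), tolerance = 1e-3)
  expect_equal(unname(res$conf.high), unname(ref[2]), tolerance = 1e-3)
  # interval and test agree about significance at matched levels
  expect_equal(res$p_value < 0.05,
               res$conf.low > 1 || res$conf.high < 1)
})

test_that("with a binary predictor and no covariates the OR is the cross-product ratio", {
  # 2x2 table (a, b; c, d) = (10, 5; 5, 10): OR = (10 * 10) / (5 * 5) = 4
  d <- tibble::tibble(
    out = c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10)),
    x = c(rep(1, 15), rep(0, 15)))
  res <- logistic_fit(d, "out", "x", covariates = character(0))
  expect_equal(res$odds_ratio, 4.0, tolerance = 1e-6)
})

test_that("the LRT p-value is invariant to rescaling a continuous predictor", {
  set.seed(7)
  d <- toy_cohort(rbinom(50, 2, 0.6), seed = 7)
  d$x <- rnorm(50)
  d$out <- rbinom(50, 1, plogis(0.5 * d$x))
  p1 <- logistic_fit(d, "out", "x", ci = FALSE)$p_value
  d$x <- d$x * 100 + 3
  p2 <- logistic_fit(d, "out", "x", ci = FALSE)$p_value
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("degenerate outcomes and separation are handled explicitly", {
  d <- toy_cohort(rbinom(20, 2, 0.6), seed = 8)
  d$out <- rep(1, 20)
  d$x <- rnorm(20)
  expect_error(logistic_fit(d, "out", "x"),
               class = "metapqtl_invalid_input_error")

  # perfect separation: ML flagged, Firth row labelled and finite
  d2 <- toy_cohort(rbinom(30, 2, 0.6), seed = 9)
  d2$x <- c(rep(0, 15), rep(1, 15))
  d2$out <- d2$x
  res <- logistic_fit(d2, "out", "x", covariates = character(0))
  expect_equal(nrow(res), 2L)
  expect_equal(res$method, c("ml", "firth"))
  expect_false(res$converged[1])
  expect_true(is.finite(res$beta[2]))
  expect_true(abs(res$beta[2]) < 15)
})

test_that("an irrelevant mediator leaves the genotype fit unchanged", {
  set.seed(10)
  co <- simulate_cohort(sim_config(seed = 10, n_samples = 120,
                                   outcome_beta_geno = -1.5,
                                   outcome_intercept = 1,
                                   pqtl_protein_index = NULL))$cohort
  co$noise <- rnorm(120)
  med <- mediation_analysis(co, "outcome", mediator = "noise", ci = FALSE)
  f <- med$fits
  d_logor <- abs(log(f$odds_ratio[f$model == "g_only"][1]) -
                 log(f$odds_ratio[f$model == "joint_g"][1]))
  expect_lt(d_logor, 0.35)
})

test_that("pleiotropy and full-mediation scenarios get the right verdicts", {
  verdict_for <- function(seed, beta_protein, beta_geno, intercept) {
    cfg <- sim_config(seed = seed, n_samples = 400,
                      outcome_beta_geno = beta_geno,
                      outcome_beta_protein = beta_protein,
                      outcome_intercept = intercept)
    co <- simulate_cohort(cfg)
    d <- co$cohort; d$med <- co$truth$protein_scores[, 1]
    mediation_analysis(d, "outcome", mediator = "med", ci = FALSE)$verdict
  }
  # pleiotropy: genotype drives protein and outcome through separate paths
  v_p <- vapply(1:6, verdict_for, character(1),
                beta_protein = 0, beta_geno = -2, intercept = 1.2)
  expect_gte(sum(v_p == "independent"), 5)
  # full mediation: genotype acts on the outcome only through the protein
  v_m <- vapply(1:6, verdict_for, character(1),
                beta_protein = 1, beta_geno = 0, intercept = 0.3)
  expect_gte(sum(v_m == "mediates"), 5)
})

test_that("mediation output is tidy and serializable", {
  sim <- simulate_study(sim_config(seed = 23))
  fit <- fit_metaproteins(sim$peptides)
  d <- dplyr::inner_join(fit$scores, sim$cohort, by = "sample_id")
  med <- mediation_analysis(d, "outcome", mediator = "PROT01")
  expect_s3_class(tidy(med), "tbl_df")
  expect_true(all(c("m_only", "g_only", "joint_g", "joint_m") %in%
                    tidy(med)$model))
  expect_true(glance(med)$verdict %in% c("independent", "mediates", "ambiguous"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mediation(med, path)
  expect_match(readLines(path)[2], "verdict")
})
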