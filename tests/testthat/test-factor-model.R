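# Metaprotein factor model: seeding rules, the spike-and-slab posterior
# against an independent naive implementation, PCA equivalence with sparsity
# off, ELBO monotonicity, recruitment/exclusion behaviour, and recovery of
# simulated ground truth.

test_that("factors are seeded only for proteins with two or more identified peptides", {
  tab <- toy_isotope(rnorm(10), c(1, 1, 1), noise_sd = 0.1, protein = "A")
  tab2 <- toy_isotope(rnorm(10), c(1, 1), noise_sd = 0.1, protein = "B", seed = 2)
  tab3 <- toy_isotope(rnorm(10), 1, noise_sd = 0.1, protein = "C", seed = 3)
  combined <- dplyr::bind_rows(tab, tab2, tab3)
  seeds <- seed_factors(combined)
  expect_equal(seeds$protein_id, c("A", "B"))
  expect_equal(seeds$n_features, c(3L, 2L))

  # unidentified features never seed
  tab3$protein_id <- NA_character_
  expect_error(seed_factors(dplyr::mutate(tab3)),
               class = "metapqtl_empty_seed_error")
})

test_that("two identical noiseless peptides form a factor carrying their shared signal", {
  f <- rnorm(30)
  tab <- toy_isotope(f, c(1, 1), noise_sd = 0)
  mp <- fit_metaprotein(tab, "CBG")
  expect_equal(nrow(mp$members), 2L)
  expect_true(all(mp$members$inclusion_prob > 0.999))
  expect_equal(abs(cor(mp$score, f)), 1, tolerance = 1e-8)
  expect_equal(mean(mp$score), 0, tolerance = 1e-6)
  expect_equal(var(mp$score), 1, tolerance = 1e-6)
})

test_that("the fitted posterior matches a naive reference implementation", {
  set.seed(8)
  f <- rnorm(25)
  extra <- cbind(18 + 0.9 * f + rnorm(25, sd = 0.4),   # concordant foreign peptide
                 rnorm(25, sd = 1))                     # pure noise
  tab <- toy_isotope(f, c(1.1, 0.9, 1.0), noise_sd = 0.4, extra = extra)
  hp <- factor_hyperparams(pi_seed = 0.95, pi_other = 0.1, tol = 1e-12,
                           max_iter = 2000)
  mp <- fit_metaprotein(tab, "CBG", hp = hp)

  X <- intensity_matrix(tab)
  ref <- ref_cavi(X, pi_j = c(rep(0.95, 3), rep(0.1, 2)), tau = 1,
                  n_iter = 2000)
  ord <- match(colnames(X), mp$membership$feature_id)
  expect_equal(mp$membership$inclusion_prob[ord], ref$p, tolerance = 1e-4)
  expect_equal(abs(mp$membership$loading[ord]), abs(ref$m), tolerance = 1e-3)
  expect_gt(abs(cor(mp$score, ref$a)), 0.9999)
})

test_that("a foreign peptide tracking the seed signal is recruited, noise is not", {
  f <- rnorm(40)
  extra <- cbind(20 + f,                 # exact copy of the latent signal
                 rnorm(40, sd = 1))      # unrelated
  tab <- toy_isotope(f, c(1, 1, 1), noise_sd = 1e-6, extra = extra)
  mp <- fit_metaprotein(tab, "CBG")
  memb <- mp$membership
  expect_gte(memb$inclusion_prob[memb$feature_id == "OTHER_p1"], 0.5)
  expect_lt(memb$inclusion_prob[memb$feature_id == "OTHER_p2"], 0.5)
  expect_true("OTHER_p1" %in% mp$members$feature_id)
})

test_that("with sparsity off the score reproduces the first principal component", {
  cfg <- sim_config(seed = 3, n_samples = 41, missing_rate = 0, n_proteins = 1,
                    peptides_per_protein = 8, residual_sd = 0.2,
                    pqtl_protein_index = NULL, promiscuous_fraction = 0)
  sim <- simulate_study(cfg)
  hp <- factor_hyperparams(pi_seed = 1 - 1e-9, pi_other = 1 - 2e-9)
  mp <- fit_metaprotein(sim$peptides, "PROT01", hp = hp)
  pc <- prcomp(intensity_matrix(sim$peptides))$x[, 1]
  expect_gte(abs(cor(mp$score, pc)), 0.999)
})

test_that("the ELBO is non-decreasing, with and without missing data", {
  for (mr in c(0, 0.15)) {
    cfg <- sim_config(seed = 6, missing_rate = mr, n_proteins = 3)
    sim <- simulate_study(cfg)
    mp <- fit_metaprotein(sim$peptides, "PROT02")
    d <- diff(mp$elbo)
    expect_true(all(d >= -1e-8 * pmax(1, abs(mp$elbo[-1]))))
    expect_true(mp$converged)
  }
})

test_that("inclusion probability rises with a candidate's correlation to the factor", {
  f <- rnorm(60)
  p_at_noise <- vapply(c(2, 1, 0.5, 0.2, 0.05), function(noise) {
    set.seed(99)
    cand <- 19 + f + rnorm(60, sd = noise)
    tab <- toy_isotope(f, c(1, 1, 1), noise_sd = 0.2, extra = cbind(cand))
    mp <- fit_metaprotein(tab, "CBG",
                          hp = factor_hyperparams(pi_other = 0.05))
    mp$membership$inclusion_prob[mp$membership$feature_id == "OTHER_p1"]
  }, numeric(1))
  expect_true(all(diff(p_at_noise) >= -1e-10))
})

test_that("scores are standardized, sign-aligned, and the fit is deterministic", {
  sim <- simulate_study(sim_config(seed = 13))
  fit1 <- fit_metaproteins(sim$peptides)
  fit2 <- fit_metaproteins(sim$peptides)
  expect_identical(fit1$scores, fit2$scores)
  for (nm in names(fit1$factors)) {
    sc <- fit1$factors[[nm]]$score
    expect_equal(mean(sc), 0, tolerance = 1e-6)
    expect_equal(var(sc), 1, tolerance = 1e-6)
    mem <- fit1$factors[[nm]]$members
    expect_gt(mean(mem$loading[mem$is_seed]), 0)
  }
  expect_length(fit1$factors, 10L)
})

test_that("membership recovers the simulated ground truth at low noise", {
  cfg <- sim_config(seed = 2, n_samples = 50, residual_sd = 0.2,
                    promiscuous_fraction = 0, missing_rate = 0.05)
  sim <- simulate_study(cfg)
  fit <- fit_metaproteins(sim$peptides)
  memb <- tidy(fit)
  # every member of factor g should really come from protein g
  expect_gte(mean(memb$protein_id == memb$factor, na.rm = TRUE), 0.95)
  # and every peptide should appear in its parent's factor
  found <- vapply(seq_len(nrow(sim$peptides)), function(j) {
    pid <- sim$peptides$protein_id[j]
    sim$peptides$feature_id[j] %in% fit$factors[[pid]]$members$feature_id
  }, logical(1))
  expect_gte(mean(found), 0.95)
})

test_that("composition metrics follow their defining arithmetic", {
  f <- rnorm(30)
  extra <- sapply(1:3, function(i) 19 + f)  # three recruited foreign copies
  tab <- toy_isotope(f, rep(1, 5), noise_sd = 1e-6, extra = extra)
  mp <- fit_metaprotein(tab, "CBG")
  cm <- composition_metrics(mp, tab)
  expect_equal(cm$coverage_pct, 100)
  expect_equal(cm$signature_pct, 100 * 5 / 8)

  # no foreign members: signature 100
  tab2 <- toy_isotope(rnorm(30), c(1, 1), noise_sd = 0.05)
  mp2 <- fit_metaprotein(tab2, "CBG")
  expect_equal(composition_metrics(mp2, tab2)$signature_pct, 100)
})

test_that("member correlations have unit diagonal and detect sign structure", {
  f <- rnorm(25)
  tab <- toy_isotope(f, c(1, 1), noise_sd = 0)          # duplicated peptide
  r <- peptide_correlations(fit_metaprotein(tab, "CBG"), tab)
  expect_equal(unname(r[1, 2]), 1, tolerance = 1e-10)
  expect_equal(diag(r), setNames(c(1, 1), rownames(r)))

  tab3 <- toy_isotope(f, c(1, -1), noise_sd = 0)        # anti-correlated pair
  hp <- factor_hyperparams()
  mp3 <- fit_metaprotein(tab3, "CBG", hp = hp)
  r3 <- peptide_correlations(mp3, tab3)
  if (nrow(r3) == 2) expect_equal(abs(unname(r3[1, 2])), 1, tolerance = 1e-10)

  # sparse overlap: warn and blank the pair
  tab4 <- toy_isotope(rnorm(8), c(1, 1), noise_sd = 0.1)
  tab4[1, c("S001", "S002", "S003", "S004", "S005", "S006")] <- NA_real_
  tab4[2, c("S007", "S008")] <- NA_real_
  mp4 <- structure(list(members = tibble::tibble(feature_id = tab4$feature_id)),
                   class = "metaprotein")
  expect_warning(r4 <- peptide_correlations(mp4, tab4), "fewer than 3")
  expect_true(is.na(r4[1, 2]))
})
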