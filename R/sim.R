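# Synthetic cohort + peptide-quantitation generator with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: Hardy-Weinberg genotypes at one biallelic SNP, latent per-protein
# expression scores, peptides that load on their parent protein's factor with
# noise and missingness, occasional "promiscuous" peptides that also load on a
# foreign factor, a genotype effect on one protein's score, and a logistic
# outcome model that can encode either pleiotropy or true mediation.

#' Simulation configuration
#'
#' Defaults emulate the 41-patient chronic HCV study cohort at one tenth of
#' the proteome scale: HWE genotypes with C-allele frequency 0.707 (so the
#' CC "responder" genotype has expected frequency 0.50), a genotype effect of
#' 1.16 score units per C allele on one target protein, an outcome model with
#' odds ratio 0.03 for the non-CC indicator, and no direct protein effect on
#' the outcome (the pleiotropy scenario).
#'
#' @param n_samples Number of patients (>= 4).
#' @param allele_freq_C Population frequency of the C (responder) allele.
#' @param n_proteins Number of simulated proteins.
#' @param peptides_per_protein Scalar or length-`n_proteins` vector of peptide
#'   counts per protein.
#' @param loading_range Length-2 numeric: peptide loadings are drawn uniformly
#'   from this interval.
#' @param residual_sd Peptide-level residual standard deviation (log2 scale).
#' @param missing_rate Probability that an intensity cell is masked missing.
#' @param pqtl_protein_index 1-based index of the protein whose score carries
#'   the genotype effect, or `NULL` for a global null.
#' @param beta_geno Genotype effect on that protein's score, per C allele
#'   (applied to the centered allele count).
#' @param promiscuous_fraction Probability a peptide additionally loads on a
#'   random foreign factor.
#' @param outcome_intercept Intercept of the outcome logistic model (log-odds
#'   of SVR for a CC patient at protein score 0).
#' @param outcome_beta_geno Log-odds of SVR for the recessive indicator
#'   `1{genotype != CC}`.
#' @param outcome_beta_protein Log-odds of SVR per unit of the pQTL protein's
#'   score; 0 encodes pleiotropy (genotype affects protein and outcome through
#'   separate paths), nonzero encodes mediation.
#' @param seed Integer seed; all randomness is split deterministically from it
#'   by purpose (genotypes, covariates, scores, loadings, noise, masking), so
#'   e.g. changing `missing_rate` does not perturb the genotypes.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 41,
                       allele_freq_C = 0.707,
                       n_proteins = 10,
                       peptides_per_protein = 5,
                       loading_range = c(0.8, 1.2),
                       residual_sd = 0.5,
                       missing_rate = 0.05,
                       pqtl_protein_index = 1,
                       beta_geno = 1.16,
                       promiscuous_fraction = 0.05,
                       outcome_intercept = 2.8,
                       outcome_beta_geno = log(0.03),
                       outcome_beta_protein = 0,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    allele_freq_C = allele_freq_C,
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    loading_range = as.numeric(loading_range),
    residual_sd = residual_sd,
    missing_rate = missing_rate,
    pqtl_protein_index = if (is.null(pqtl_protein_index)) NULL else as.integer(pqtl_protein_index),
    beta_geno = beta_geno,
    promiscuous_fraction = promiscuous_fraction,
    outcome_intercept = outcome_intercept,
    outcome_beta_geno = outcome_beta_geno,
    outcome_beta_protein = outcome_beta_protein,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(allele_freq_C = cfg$allele_freq_C, missing_rate = cfg$missing_rate,
             promiscuous_fraction = cfg$promiscuous_fraction)
  bad <- probs[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad) > 0) {
    stop_invalid_config(paste0("probabilities must lie in [0,1]: ",
                               paste(names(bad), collapse = ", ")))
  }
  if (is.na(cfg$n_samples) || cfg$n_samples < 4) {
    stop_invalid_config("n_samples must be at least 4")
  }
  if (cfg$n_proteins < 1) stop_invalid_config("n_proteins must be at least 1")
  if (any(cfg$peptides_per_protein < 1)) {
    stop_invalid_config("peptides_per_protein must be at least 1")
  }
  if (!length(cfg$peptides_per_protein) %in% c(1L, cfg$n_proteins)) {
    stop_invalid_config("peptides_per_protein must be a scalar or one count per protein")
  }
  if (!is.finite(cfg$residual_sd) || cfg$residual_sd <= 0) {
    stop_invalid_config("residual_sd must be positive")
  }
  if (length(cfg$loading_range) != 2 || diff(cfg$loading_range) < 0) {
    stop_invalid_config("loading_range must be (low, high) with low <= high")
  }
  if (!is.null(cfg$pqtl_protein_index) &&
      (cfg$pqtl_protein_index < 1 || cfg$pqtl_protein_index > cfg$n_proteins)) {
    stop_invalid_config("pqtl_protein_index out of range")
  }
  invisible(cfg)
}

sim_protein_ids <- function(cfg) sprintf("PROT%02d", seq_len(cfg$n_proteins))

#' Simulate a patient cohort
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium at the configured
#' C-allele frequency; sex and race are drawn independently (male 0.61,
#' Caucasian 0.78, the study cohort's margins); true protein factor scores are
#' drawn (standard normal, plus the genotype effect on the pQTL protein); the
#' binary outcome follows the logistic model
#' `intercept + beta_geno_outcome * 1{non-CC} + beta_protein * pqtl score`.
#'
#' @param config A [sim_config()].
#' @return A list with `cohort` (a tibble: sample_id, genotype label, allele
#'   count, sex, race, outcome) and `truth` (genotypes, protein score matrix,
#'   outcome probabilities).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_samples
  p <- config$allele_freq_C

  allele_count <- with_stream(config$seed, "genotype",
                              stats::rbinom(n, size = 2L, prob = p))
  covar <- with_stream(config$seed, "covariates", {
    list(sex = ifelse(stats::rbinom(n, 1L, 0.61) == 1L, "male", "female"),
         race = ifelse(stats::rbinom(n, 1L, 0.78) == 1L, "Caucasian", "African American"))
  })

  scores <- with_stream(config$seed, "scores", {
    m <- matrix(stats::rnorm(n * config$n_proteins), nrow = n,
                dimnames = list(NULL, sim_protein_ids(config)))
    if (!is.null(config$pqtl_protein_index)) {
      k <- config$pqtl_protein_index
      m[, k] <- m[, k] + config$beta_geno * (allele_count - mean(allele_count))
    }
    m
  })

  pqtl_score <- if (is.null(config$pqtl_protein_index)) {
    rep(0, n)
  } else {
    scores[, config$pqtl_protein_index]
  }
  eta <- config$outcome_intercept +
    config$outcome_beta_geno * as.numeric(allele_count < 2L) +
    config$outcome_beta_protein * pqtl_score
  pr_svr <- stats::plogis(eta)
  outcome <- with_stream(config$seed, "outcome",
                         ifelse(stats::rbinom(n, 1L, pr_svr) == 1L, "SVR", "NR"))

  cohort <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    genotype = c("TT", "CT", "CC")[allele_count + 1L],
    allele_count = as.integer(allele_count),
    sex = covar$sex,
    race = covar$race,
    outcome = outcome
  )
  truth <- list(genotypes = as.integer(allele_count),
                protein_scores = scores,
                outcome_prob = pr_svr)
  list(cohort = cohort, truth = truth)
}

#' Simulate an isotope-group quantitation table
#'
#' Each peptide j of protein g gets intensity
#' `x_ij = intercept_j + lambda_j * t_ig (+ lambda'_j * t_ig' if promiscuous)
#' + N(0, residual_sd^2)` where `t` are the true protein scores drawn by
#' [simulate_cohort()]. Cells are masked missing independently at
#' `missing_rate`. Identification metadata (m/z, charge state, peak centroid
#' times, peak time scores) is filled with plausible values but carries no
#' signal.
#'
#' @param config A [sim_config()].
#' @param cohort The cohort tibble from [simulate_cohort()] under the same
#'   config and seed.
#' @param truth The truth list from [simulate_cohort()].
#' @return A list with `peptides` (an isotope-group tibble) and `truth`
#'   (the input truth extended with peptide membership, loadings, intercepts).
#' @export
simulate_peptides <- function(config, cohort, truth) {
  validate_sim_config(config)
  n <- config$n_samples
  if (nrow(cohort) != n || nrow(truth$protein_scores) != n) {
    stop_dimension("cohort/truth sample count does not match config$n_samples")
  }
  counts <- config$peptides_per_protein
  if (length(counts) == 1L) counts <- rep(counts, config$n_proteins)
  n_pep <- sum(counts)
  parent <- rep(seq_len(config$n_proteins), counts)
  prot_ids <- sim_protein_ids(config)

  lambda <- with_stream(config$seed, "loadings",
                        stats::runif(n_pep, config$loading_range[1], config$loading_range[2]))
  memb <- with_stream(config$seed, "membership", {
    promisc <- stats::runif(n_pep) < config$promiscuous_fraction &
      config$n_proteins > 1L
    foreign <- rep(NA_integer_, n_pep)
    foreign_lambda <- rep(NA_real_, n_pep)
    for (j in which(promisc)) {
      foreign[j] <- sample(setdiff(seq_len(config$n_proteins), parent[j]), 1L)
    }
    foreign_lambda[promisc] <- stats::runif(sum(promisc), config$loading_range[1],
                                            config$loading_range[2])
    list(promiscuous = promisc, foreign = foreign, foreign_lambda = foreign_lambda)
  })
  meta <- with_stream(config$seed, "metadata", {
    intercepts <- stats::runif(n_pep, 14, 22)
    mz <- stats::runif(n_pep, 400, 1300)
    charge <- sample(1:3, n_pep, replace = TRUE)
    n_times <- sample(1:3, n_pep, replace = TRUE)
    times <- lapply(n_times, function(k) sort(stats::runif(k, 30, 70)))
    scores <- lapply(n_times, function(k) stats::runif(k, 0.75, 0.99))
    list(intercepts = intercepts, mz = mz, charge = charge,
         times = times, scores = scores)
  })

  signal <- truth$protein_scores[, parent, drop = FALSE] %*% diag(lambda, n_pep)
  fj <- which(memb$promiscuous)
  if (length(fj) > 0) {
    signal[, fj] <- signal[, fj] +
      truth$protein_scores[, memb$foreign[fj], drop = FALSE] %*%
        diag(memb$foreign_lambda[fj], length(fj))
  }
  x <- sweep(signal, 2, meta$intercepts, "+")
  x <- x + with_stream(config$seed, "noise",
                       matrix(stats::rnorm(n * n_pep, sd = config$residual_sd),
                              nrow = n))
  if (config$missing_rate > 0) {
    mask <- with_stream(config$seed, "masking",
                        matrix(stats::runif(n * n_pep) < config$missing_rate,
                               nrow = n))
    x[mask] <- NA_real_
  }

  peptides <- tibble::tibble(
    feature_id = sprintf("F%04d", seq_len(n_pep)),
    peptide_label = prot_ids[parent],
    protein_id = prot_ids[parent],
    monoisotopic_mz = round(meta$mz, 4),
    charge_state = as.integer(meta$charge),
    peak_centroid_times = meta$times,
    peak_time_scores = meta$scores
  )
  intens <- tibble::as_tibble(as.data.frame(t(x)))
  names(intens) <- cohort$sample_id
  peptides <- dplyr::bind_cols(peptides, intens)

  membership <- lapply(seq_len(n_pep), function(j) {
    f <- parent[j]
    if (memb$promiscuous[j]) f <- c(f, memb$foreign[j])
    f
  })
  truth$peptide_membership <- stats::setNames(membership, peptides$feature_id)
  truth$loadings <- stats::setNames(lambda, peptides$feature_id)
  truth$foreign_loadings <- stats::setNames(memb$foreign_lambda, peptides$feature_id)
  truth$intercepts <- stats::setNames(meta$intercepts, peptides$feature_id)
  truth$parent_protein <- stats::setNames(prot_ids[parent], peptides$feature_id)
  list(peptides = peptides, truth = truth)
}

#' Simulate a full study (cohort + peptide table) in one call
#'
#' @param config A [sim_config()].
#' @return A list with `cohort`, `peptides`, and `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  co <- simulate_cohort(config)
  pe <- simulate_peptides(config, co$cohort, co$truth)
  list(cohort = co$cohort, peptides = pe$peptides, truth = pe$truth)
}
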