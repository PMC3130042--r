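# End-to-end pipeline glue: simulate-to-disk, run all stages in order, and
# emit replication-style summary tables. The thin command-line wrapper at
# inst/cli/metapqtl.R calls these functions.

#' Write a simulated study to disk
#'
#' Generates a cohort and isotope-group table under `config` and writes
#' `isotope.tsv`, `cohort.tsv`, and `truth.tsv` (per-peptide ground truth:
#' parent factor, loading, promiscuous foreign factor/loading, intercept)
#' with provenance headers. Re-running with the same config and seed
#' reproduces the files byte-for-byte apart from the header timestampless
#' provenance lines.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the list from [simulate_study()].
#' @export
write_simulation <- function(config, dir, force = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("isotope.tsv", "cohort.tsv", "truth.tsv"))
  if (!force && any(file.exists(paths))) {
    stop_invalid_config(sprintf("outputs already exist in %s (use force = TRUE)", dir))
  }
  sim <- simulate_study(config)
  prov <- c(sprintf("seed: %d", config$seed),
            sprintf("config_hash: %s",
                    rlang::hash(config)))
  write_isotope_table(sim$peptides, paths[1], provenance = prov)
  write_cohort_table(sim$cohort, paths[2], provenance = prov)
  truth_tbl <- tibble::tibble(
    feature_id = names(sim$truth$parent_protein),
    parent_protein = unname(sim$truth$parent_protein),
    loading = unname(sim$truth$loadings),
    foreign_loading = unname(sim$truth$foreign_loadings),
    intercept = unname(sim$truth$intercepts),
    factors = vapply(sim$truth$peptide_membership, paste, character(1), collapse = ",")
  )
  write_with_header(truth_tbl, paths[3], "\t", prov)
  invisible(sim)
}

#' Run the full analysis pipeline
#'
#' Stages in order: factor seeding, metaprotein fitting, the genotype scan
#' with Bonferroni control, per-peptide tests for each Bonferroni-significant
#' factor, and (when an outcome column is present and some factor is
#' significant) the nested-logistic mediation analysis with the top factor as
#' mediator.
#'
#' @param peptides Isotope-group tibble.
#' @param cohort Cohort tibble (with `allele_count`; `outcome` optional).
#' @param hp A [factor_hyperparams()].
#' @param model Genotype coding for the scan.
#' @param covariates Covariate columns in `cohort`.
#' @param family_alpha Family-wise error rate for the scan.
#' @param output_dir If non-`NULL`, writes the fit directory, `scan.tsv`,
#'   `qq.tsv`, `mediation.tsv` (when run) and `report.txt` there.
#' @return A list with `fit` (`metaprotein_fit`), `scan` (`pqtl_scan`),
#'   `peptide_tests` (tibble or `NULL`), `mediation` (`mediation_result` or
#'   `NULL`), and `report` (character lines).
#' @export
run_pipeline <- function(peptides, cohort, hp = factor_hyperparams(),
                         model = "additive", covariates = c("sex", "race"),
                         family_alpha = 0.05, output_dir = NULL) {
  fit <- fit_metaproteins(peptides, hp)
  scan <- pqtl_scan(fit$scores, cohort, model = model, covariates = covariates,
                    family_alpha = family_alpha)
  hits <- dplyr::filter(scan$results, .data$significant)
  hits <- dplyr::arrange(hits, .data$p_value)

  pep <- NULL
  if (nrow(hits) > 0) {
    pep <- dplyr::bind_rows(lapply(hits$target_id, function(f) {
      ids <- fit$factors[[f]]$members$feature_id
      out <- peptide_tests(peptides, ids, cohort, model = model,
                           covariates = covariates, family_alpha = family_alpha)
      dplyr::mutate(out, factor = f, .before = 1)
    }))
  }

  med <- NULL
  have_outcome <- "outcome" %in% names(cohort) && any(!is.na(cohort$outcome))
  if (nrow(hits) > 0 && have_outcome) {
    top <- hits$target_id[1]
    d <- dplyr::inner_join(fit$scores[c("sample_id", top)], cohort, by = "sample_id")
    med <- mediation_analysis(d, "outcome", mediator = top,
                              covariates = covariates)
  } else if (!have_outcome) {
    message("no outcome column present; mediation stage skipped")
  }

  report <- c(
    sprintf("metaproteins fitted: %d (skipped: %d)", length(fit$factors),
            length(fit$skipped)),
    sprintf("scan: %d tests, %s model, Bonferroni alpha %.3g",
            scan$n_tests, model, scan$bonferroni_alpha),
    if (nrow(hits) == 0) "significant factors: none" else
      sprintf("significant factor: %s (p = %.3g, r2 = %.3f, coverage %.1f%%, signature %.1f%%)",
              hits$target_id,
              hits$p_value, hits$r2_genotype,
              fit$composition$coverage_pct[match(hits$target_id, fit$composition$factor)],
              fit$composition$signature_pct[match(hits$target_id, fit$composition$factor)]),
    if (!is.null(med)) sprintf("mediation verdict (mediator %s): %s",
                               med$mediator, med$verdict)
    else "mediation: not run"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_metaprotein_fit(fit, file.path(output_dir, "fit"))
    write_scan(scan, output_dir)
    if (!is.null(pep)) {
      write_with_header(pep, file.path(output_dir, "peptide_tests.tsv"), "\t")
    }
    if (!is.null(med)) write_mediation(med, file.path(output_dir, "mediation.tsv"))
    writeLines(report, file.path(output_dir, "report.txt"))
  }
  list(fit = fit, scan = scan, peptide_tests = pep, mediation = med,
       report = report)
}

#' Replication-style summary tables
#'
#' Produces the two summary layouts of the study report: the statistical-
#' association table (mediator-only, genotype-only and joint logistic fits of
#' the outcome, plus the recessive linear-model beta for the target factor
#' score) and the per-peptide association table for the target factor's
#' members.
#'
#' @param peptides Isotope-group tibble (or from [read_mat_workspace()]).
#' @param cohort Cohort tibble.
#' @param scores Optional precomputed score tibble (`sample_id` + factors);
#'   when `NULL`, metaproteins are fitted with `hp`.
#' @param target Factor column to summarize; default = lowest recessive-scan
#'   p-value.
#' @param hp A [factor_hyperparams()].
#' @param covariates Covariate columns.
#' @return A list with `associations` (tibble: dependent variable,
#'   independent variable, OR / beta, CI, p) and `peptides` (per-member test
#'   tibble, `NULL` when scores were precomputed without a fit).
#' @export
replicate_tables <- function(peptides, cohort, scores = NULL, target = NULL,
                             hp = factor_hyperparams(),
                             covariates = c("sex", "race")) {
  fit <- NULL
  if (is.null(scores)) {
    fit <- fit_metaproteins(peptides, hp)
    scores <- fit$scores
  }
  scan <- pqtl_scan(scores, cohort, model = "recessive", covariates = covariates)
  if (is.null(target)) {
    target <- dplyr::arrange(scan$results, .data$p_value)$target_id[1]
  }
  d <- dplyr::inner_join(scores[c("sample_id", target)], cohort, by = "sample_id")
  lin <- pqtl_test(d, target, covariates = covariates, model = "recessive")
  assoc <- NULL
  med <- NULL
  if ("outcome" %in% names(d) && any(!is.na(d$outcome))) {
    med <- mediation_analysis(d, "outcome", mediator = target,
                              covariates = covariates)
    fits <- med$fits
    assoc <- tibble::tibble(
      dependent = "outcome",
      independent = c(target, "genotype (non-CC)", "genotype (non-CC) | mediator",
                      paste0(target, " | genotype"))[match(fits$model,
                        c("m_only", "g_only", "joint_g", "joint_m"))],
      method = fits$method,
      estimate = fits$odds_ratio, conf.low = fits$conf.low,
      conf.high = fits$conf.high, p_value = fits$p_value,
      scale = "odds ratio"
    )
  }
  assoc <- dplyr::bind_rows(assoc, tibble::tibble(
    dependent = target, independent = "genotype (non-CC)", method = "ols",
    estimate = lin$beta, conf.low = lin$conf.low, conf.high = lin$conf.high,
    p_value = lin$p_value, scale = "beta (score difference, non-CC vs CC)"))

  pep <- NULL
  if (!is.null(fit) && target %in% names(fit$factors)) {
    ids <- fit$factors[[target]]$members$feature_id
    pep <- peptide_tests(peptides, ids, cohort, model = "additive",
                         covariates = covariates)
    meta <- peptides[match(pep$target_id, peptides$feature_id),
                     intersect(c("peptide_label", "monoisotopic_mz", "charge_state"),
                               names(peptides))]
    pep <- dplyr::bind_cols(meta, pep)
  }
  list(associations = assoc, peptides = pep, target = target, scan = scan,
       mediation = med)
}
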