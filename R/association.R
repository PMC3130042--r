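# pQTL association: metaprotein scores (or single peptides) against one
# biallelic SNP with covariate adjustment, Bonferroni control over the factor
# family, QQ diagnostics, and variance explained by the genotype term.

genotype_term <- function(allele_count, model) {
  switch(model,
    additive = as.numeric(allele_count),
    recessive = as.numeric(allele_count < 2),  # 1{non-CC}
    categorical = factor(allele_count, levels = 0:2),
    stop_invalid_config(sprintf("unknown genotype model '%s'", model))
  )
}

build_assoc_frame <- function(data, response, genotype, covariates, model) {
  cols <- c(response, genotype, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  d <- data[cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$..g <- genotype_term(d[[genotype]], model)
  d
}

check_design <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort_class(paste0("collinear design; redundant column(s): ",
                       paste(dropped, collapse = ", ")),
                "metapqtl_collinearity_error")
  }
}

#' Test one response for association with genotype
#'
#' Linear regression of the response on a genotype term plus covariates, with
#' a two-sided t-test on the genotype coefficient. Under the additive model
#' the term is the C-allele count (a trend test, the covariate-adjusted
#' analogue of one-way ANOVA); under the recessive model it is the indicator
#' `1{genotype != CC}`, so negative effects mean the non-CC group is lower.
#' `model = "categorical"` fits genotype as a 3-level factor and reports the
#' joint F-test instead of a single coefficient.
#'
#' @param data A tibble holding the response, an `allele_count` column
#'   (C-allele counts 0/1/2), and the covariate columns.
#' @param response Name of the response column (a metaprotein score or a
#'   peptide intensity).
#' @param genotype Name of the allele-count column.
#' @param covariates Character vector of covariate column names (default sex
#'   and race). Samples with any missing value are dropped listwise.
#' @param model `"additive"`, `"recessive"`, or `"categorical"`.
#' @return A one-row tibble: `target_id`, `model`, `beta`, `se`, `statistic`,
#'   `p_value`, `conf.low`/`conf.high` (95% CI for the genotype coefficient),
#'   `r2_genotype` (variance explained by the genotype term alone),
#'   `r2_partial` (partial R-squared given covariates), `n_used`,
#'   `covariates`.
#' @export
pqtl_test <- function(data, response, genotype = "allele_count",
                      covariates = c("sex", "race"),
                      model = c("additive", "recessive", "categorical")) {
  model <- match.arg(model)
  d <- build_assoc_frame(data, response, genotype, covariates, model)
  g_num <- if (model == "categorical") as.numeric(as.character(d$..g)) else d$..g
  if (length(unique(g_num)) < 2) {
    abort_class("genotype term is constant in the analysis sample",
                "metapqtl_undefined_test_error")
  }
  for (cv in covariates) if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  rhs <- paste(c("..g", covariates), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  n_used <- nrow(d)
  if (n_used <= ncol(X) + 1) {
    abort_class("too few complete samples for the requested design",
                "metapqtl_undefined_test_error")
  }
  check_design(X)

  y <- d[[response]]
  g_cols <- grep("^\\.\\.g", colnames(X))
  Xcov <- X[, -g_cols, drop = FALSE]
  ve <- variance_explained_qr(y, g_cols, X, Xcov, model)
  if (stats::sd(y) == 0) {
    # constant response: no association by construction
    return(assoc_row(response, model, beta = 0, se = 0, statistic = 0,
                     p_value = 1, conf.low = 0, conf.high = 0,
                     r2 = 0, r2_partial = 0, n_used = n_used, covariates = covariates))
  }

  qr_full <- qr(X)
  coefs <- qr.coef(qr_full, y)
  res <- qr.resid(qr_full, y)
  df_res <- n_used - ncol(X)
  sigma2 <- sum(res^2) / df_res
  if (model == "categorical") {
    res0 <- qr.resid(qr(Xcov), y)
    sse0 <- sum(res0^2); sse1 <- sum(res^2)
    df_g <- length(g_cols)
    f <- ((sse0 - sse1) / df_g) / (sse1 / df_res)
    return(assoc_row(response, model, beta = NA_real_, se = NA_real_,
                     statistic = f,
                     p_value = stats::pf(f, df_g, df_res, lower.tail = FALSE),
                     conf.low = NA_real_, conf.high = NA_real_,
                     r2 = ve$r2_genotype, r2_partial = ve$r2_partial,
                     n_used = n_used, covariates = covariates))
  }
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- unname(coefs[g_cols])
  se <- sqrt(sigma2 * XtXinv[g_cols, g_cols])
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  ci <- beta + c(-1, 1) * stats::qt(0.975, df_res) * se
  assoc_row(response, model, beta = beta, se = se, statistic = tval,
            p_value = pval, conf.low = ci[1], conf.high = ci[2],
            r2 = ve$r2_genotype, r2_partial = ve$r2_partial,
            n_used = n_used, covariates = covariates)
}

variance_explained_qr <- function(y, g_cols, X, Xcov, model) {
  if (stats::sd(y) == 0) return(list(r2_genotype = 0, r2_partial = 0))
  Xg <- X[, c(1L, g_cols), drop = FALSE]  # intercept + genotype term only
  sst <- sum((y - mean(y))^2)
  sse_g <- sum(qr.resid(qr(Xg), y)^2)
  sse_cov <- sum(qr.resid(qr(Xcov), y)^2)
  sse_full <- sum(qr.resid(qr(X), y)^2)
  list(r2_genotype = 1 - sse_g / sst,
       r2_partial = if (sse_cov > 0) (sse_cov - sse_full) / sse_cov else 0)
}

assoc_row <- function(target, model, beta, se, statistic, p_value, conf.low,
                      conf.high, r2, r2_partial, n_used, covariates) {
  tibble::tibble(target_id = target, model = model, beta = beta, se = se,
                 statistic = statistic, p_value = p_value,
                 conf.low = conf.low, conf.high = conf.high,
                 r2_genotype = r2, r2_partial = r2_partial,
                 n_used = n_used, covariates = paste(covariates, collapse = ","))
}

variance_explained_ <- function(y, g, d, covariates, model) {
  if (stats::sd(y) == 0) return(list(r2_genotype = 0, r2_partial = 0))
  f1 <- stats::lm(y ~ g)
  r2 <- summary(f1)$r.squared
  dd <- d
  dd$..y <- y
  f_cov <- stats::lm(stats::as.formula(
    paste("..y ~", paste(covariates, collapse = " + "))), data = dd)
  f_full <- stats::lm(stats::as.formula(
    paste("..y ~ ..g +", paste(covariates, collapse = " + "))), data = dd)
  sse_cov <- sum(stats::residuals(f_cov)^2)
  sse_full <- sum(stats::residuals(f_full)^2)
  list(r2_genotype = r2,
       r2_partial = if (sse_cov > 0) (sse_cov - sse_full) / sse_cov else 0)
}

#' Variance in a response explained by the genotype term
#'
#' The primary definition is the marginal R-squared of the regression of the
#' response on the genotype term alone (no covariates); the partial
#' R-squared given the covariates is reported alongside.
#'
#' @inheritParams pqtl_test
#' @return A one-row tibble with `r2_genotype` and `r2_partial`.
#' @export
variance_explained <- function(data, response, genotype = "allele_count",
                               covariates = c("sex", "race"),
                               model = c("additive", "recessive", "categorical")) {
  model <- match.arg(model)
  d <- build_assoc_frame(data, response, genotype, covariates, model)
  g_num <- if (model == "categorical") as.numeric(as.character(d$..g)) else d$..g
  if (length(unique(g_num)) < 2) {
    abort_class("genotype term is constant in the analysis sample",
                "metapqtl_undefined_test_error")
  }
  for (cv in covariates) if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  ve <- variance_explained_(d[[response]], d$..g, d, covariates, model)
  tibble::as_tibble(ve)
}

#' Scan all metaprotein scores for genotype association
#'
#' Applies [pqtl_test()] to every score column, controls the family-wise
#' error rate by Bonferroni over the number of tests, and flags significant
#' factors. Per-column failures are downgraded to skipped entries with a
#' warning.
#'
#' @param scores Tibble with `sample_id` plus one column per metaprotein
#'   score (the `scores` element of a `metaprotein_fit`).
#' @param cohort Cohort tibble with `sample_id`, `allele_count`, covariates.
#' @param model Genotype coding passed to [pqtl_test()].
#' @param covariates Covariate column names in `cohort`.
#' @param family_alpha Family-wise error rate (default 0.05).
#' @return An object of class `pqtl_scan`: the per-factor results tibble
#'   (with a `significant` flag), `n_tests`, `bonferroni_alpha`, and skipped
#'   columns. `tidy()` returns the results; `autoplot()` draws the QQ plot.
#' @export
pqtl_scan <- function(scores, cohort, model = "additive",
                      covariates = c("sex", "race"), family_alpha = 0.05) {
  targets <- setdiff(names(scores), "sample_id")
  if (length(targets) == 0) stop_schema("scores has no factor columns")
  d <- dplyr::inner_join(scores, cohort, by = "sample_id")
  if (nrow(d) == 0) stop_dimension("no overlapping sample_id between scores and cohort")
  res <- list(); skipped <- character(0)
  for (tg in targets) {
    row <- tryCatch(pqtl_test(d, tg, covariates = covariates, model = model),
                    metapqtl_error = function(e) e)
    if (inherits(row, "error")) skipped <- c(skipped, tg) else res[[length(res) + 1]] <- row
  }
  if (length(skipped) > 0) {
    warning(sprintf("%d scan column(s) skipped: %s", length(skipped),
                    paste(skipped, collapse = ", ")))
  }
  results <- dplyr::bind_rows(res)
  n_tests <- nrow(results)
  alpha <- family_alpha / n_tests
  results$significant <- results$p_value <= alpha
  structure(list(results = results, n_tests = n_tests,
                 bonferroni_alpha = alpha, family_alpha = family_alpha,
                 model = model, skipped = skipped),
            class = "pqtl_scan")
}

#' @export
print.pqtl_scan <- function(x, ...) {
  cat(sprintf("<pqtl_scan> %d tests (%s model), Bonferroni alpha %.3g, %d significant\n",
              x$n_tests, x$model, x$bonferroni_alpha, sum(x$results$significant)))
  invisible(x)
}

#' @export
tidy.pqtl_scan <- function(x, ...) dplyr::arrange(x$results, .data$p_value)

#' @export
glance.pqtl_scan <- function(x, ...) {
  tibble::tibble(n_tests = x$n_tests, bonferroni_alpha = x$bonferroni_alpha,
                 family_alpha = x$family_alpha, model = x$model,
                 n_significant = sum(x$results$significant),
                 n_skipped = length(x$skipped))
}

#' Expected-versus-observed QQ coordinates on the -log10 scale
#'
#' For K p-values, the i-th ranked observed point is paired with the
#' mid-rank uniform quantile `-log10((i - 0.5) / K)`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return A tibble with `expected` and `observed` columns, largest first.
#' @export
qq_points <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort_class("p-values must lie in (0, 1]", "metapqtl_domain_error")
  }
  k <- length(p)
  tibble::tibble(
    expected = -log10((seq_len(k) - 0.5) / k),
    observed = sort(-log10(p), decreasing = TRUE)
  )
}

#' Per-peptide genotype association for a metaprotein's members
#'
#' Applies the same covariate-adjusted test to each member feature's
#' intensity vector, with a Bonferroni threshold over the member count.
#'
#' @param table Isotope-group tibble.
#' @param members Character vector of member feature ids (e.g.
#'   `mp$members$feature_id`).
#' @param cohort Cohort tibble.
#' @param model,covariates,family_alpha As in [pqtl_scan()].
#' @return A tibble, one row per member feature, with `significant` flags at
#'   `family_alpha / n_members`.
#' @export
peptide_tests <- function(table, members, cohort, model = "additive",
                          covariates = c("sex", "race"), family_alpha = 0.05) {
  absent <- setdiff(members, table$feature_id)
  if (length(absent) > 0) {
    stop_schema(paste0("member feature(s) not in table: ",
                       paste(absent, collapse = ", ")))
  }
  X <- intensity_matrix(table)
  d0 <- tibble::tibble(sample_id = rownames(X))
  rows <- lapply(members, function(fid) {
    d <- dplyr::inner_join(dplyr::mutate(d0, y = X[, fid]), cohort, by = "sample_id")
    out <- pqtl_test(d, "y", covariates = covariates, model = model)
    out$target_id <- fid
    out
  })
  res <- dplyr::bind_rows(rows)
  res$bonferroni_alpha <- family_alpha / length(members)
  res$significant <- res$p_value <= res$bonferroni_alpha
  res
}

#' Write scan results and QQ coordinates
#'
#' @param scan A `pqtl_scan`.
#' @param dir Output directory; writes `scan.tsv` and `qq.tsv`.
#' @return `dir`, invisibly.
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_with_header(tidy.pqtl_scan(scan), file.path(dir, "scan.tsv"), "\t",
                    sprintf("model: %s; bonferroni_alpha: %g", scan$model,
                            scan$bonferroni_alpha))
  write_with_header(qq_points(scan$results$p_value), file.path(dir, "qq.tsv"), "\t")
  invisible(dir)
}
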