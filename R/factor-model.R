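# Metaprotein factor model.
#
# One sparse latent factor per seed protein:
#
#   x_ij = mu_j + rho_j * lambda_j * f_i + eps_ij,   eps_ij ~ N(0, psi_j)
#   f_i ~ N(0, 1),  lambda_j ~ N(0, tau),  rho_j ~ Bernoulli(pi_j)
#
# with pi_j = pi_seed for the seed protein's own identified peptides and
# pi_other for every other candidate peptide (identified elsewhere or
# unidentified). Fitted by coordinate-ascent variational EM: closed-form
# updates for q(f_i) = N(a_i, s_i) and the spike-and-slab block
# q(rho_j, lambda_j) (exact posterior inclusion probability p_j given the
# other blocks), M-steps for mu and psi, and an evidence lower bound (ELBO)
# that is non-decreasing across sweeps and drives convergence. Missing
# intensities are simply omitted from the likelihood (MAR).

#' Hyperparameters of the metaprotein factor model
#'
#' @param pi_seed Prior inclusion probability for the seed protein's own
#'   peptides. The default 0.95 encodes a strong tie to the protein
#'   identification while still letting discordant peptides drop out.
#' @param pi_other Prior inclusion probability for all other candidate
#'   peptides; the default 0.001 makes cross-protein recruitment rare and
#'   evidence-driven.
#' @param tau Prior variance of the loadings.
#' @param membership_threshold Posterior inclusion probability above which a
#'   peptide counts as a member of the metaprotein.
#' @param max_iter Maximum number of coordinate-ascent sweeps.
#' @param tol Convergence tolerance: sweeps stop when the ELBO change falls
#'   below `tol * (1 + |ELBO|)` or every parameter moves by less than `tol`.
#' @param seed Integer seed recorded with the fit (the algorithm itself is
#'   deterministic).
#' @return A list of class `factor_hyperparams`.
#' @export
factor_hyperparams <- function(pi_seed = 0.95, pi_other = 0.001, tau = 1.0,
                               membership_threshold = 0.5, max_iter = 2000,
                               tol = 1e-6, seed = 1L) {
  if (!(pi_other > 0 && pi_other < pi_seed && pi_seed < 1)) {
    stop_invalid_config("need 0 < pi_other < pi_seed < 1")
  }
  if (tau <= 0) stop_invalid_config("tau must be positive")
  if (!(membership_threshold > 0 && membership_threshold < 1)) {
    stop_invalid_config("membership_threshold must be in (0, 1)")
  }
  structure(list(pi_seed = pi_seed, pi_other = pi_other, tau = tau,
                 membership_threshold = membership_threshold,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "factor_hyperparams")
}

#' Seed metaprotein factors from protein identifications
#'
#' One factor is seeded per protein with at least two identified isotope
#' groups. Features without a protein identification are excluded from
#' seeding but remain available as recruitment candidates.
#'
#' @param table An isotope-group tibble.
#' @return A tibble with `protein_id`, `name` (predominant peptide label),
#'   `n_features`, and a `feature_ids` list-column, ordered by `protein_id`.
#' @export
seed_factors <- function(table) {
  identified <- dplyr::filter(table, !is.na(.data$protein_id))
  seeds <- identified |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      name = names(sort(table(.data$peptide_label), decreasing = TRUE))[1],
      n_features = dplyr::n(),
      feature_ids = list(.data$feature_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_features >= 2L) |>
    dplyr::arrange(.data$protein_id)
  if (nrow(seeds) == 0) {
    abort_class("no protein has two or more identified isotope groups",
                "metapqtl_empty_seed_error")
  }
  seeds
}

#' Fit one metaprotein factor
#'
#' @param table An isotope-group tibble.
#' @param seed_protein Protein id whose identified peptides seed the factor.
#' @param candidates Feature ids eligible for recruitment at prior
#'   `pi_other`; defaults to every feature not assigned to `seed_protein`
#'   (identified elsewhere or unidentified).
#' @param hp A [factor_hyperparams()].
#' @return An object of class `metaprotein`: name, seed protein, the full
#'   posterior membership table, the member subset at the threshold, the
#'   standardized score vector (posterior mean of f, sign-aligned so the mean
#'   seed-member loading is positive), residual variances, ELBO trace, and
#'   convergence state. Non-convergence returns the fit with
#'   `converged = FALSE` and a warning.
#' @export
fit_metaprotein <- function(table, seed_protein, candidates = NULL,
                            hp = factor_hyperparams()) {
  stopifnot(inherits(hp, "factor_hyperparams"))
  seed_ids <- table$feature_id[!is.na(table$protein_id) &
                                 table$protein_id == seed_protein]
  if (is.null(candidates)) {
    candidates <- setdiff(table$feature_id, seed_ids)
  }
  X_all <- intensity_matrix(table)
  keep <- c(seed_ids, setdiff(candidates, seed_ids))
  X <- X_all[, keep, drop = FALSE]

  n_obs <- colSums(!is.na(X))
  usable <- n_obs >= 3L
  if (sum(usable[seq_along(seed_ids)]) < 2L) {
    abort_class(sprintf("seed protein %s needs >= 2 peptides with >= 3 observed samples",
                        seed_protein), "metapqtl_degenerate_factor_error")
  }
  X <- X[, usable, drop = FALSE]
  is_seed <- colnames(X) %in% seed_ids
  n <- nrow(X); J <- ncol(X)

  W <- !is.na(X)
  X0 <- X; X0[!W] <- 0
  Wn <- W * 1
  nj <- colSums(Wn)
  pi_j <- ifelse(is_seed, hp$pi_seed, hp$pi_other)
  psi_min <- 1e-10

  # deterministic init: f <- first PC of the mean-imputed seed submatrix
  Xs <- X[, is_seed, drop = FALSE]
  cm <- colMeans(Xs, na.rm = TRUE)
  Xs_imp <- sweep(Xs, 2, cm)
  Xs_imp[is.na(Xs_imp)] <- 0
  sv <- svd(Xs_imp, nu = 1, nv = 0)
  pc <- sv$u[, 1] * sv$d[1]
  if (stats::sd(pc) < 1e-12) {
    abort_class(sprintf("seed peptides of %s carry no shared variation", seed_protein),
                "metapqtl_degenerate_factor_error")
  }
  a <- standardize(pc)
  s <- rep(0.1, n)
  mu <- colMeans(X, na.rm = TRUE)
  psi <- pmax(apply(X, 2, stats::var, na.rm = TRUE), psi_min)
  psi[is.na(psi)] <- 1
  m <- rep(0, J); v <- rep(hp$tau, J); p <- pi_j

  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  p_prev <- p; m_prev <- m; a_prev <- a

  for (iter in seq_len(hp$max_iter)) {
    Ea2 <- a^2 + s

    # spike-and-slab block: exact posterior for (rho_j, lambda_j)
    Xc <- sweep(X0, 2, mu) * Wn
    cj <- drop(crossprod(Xc, a))
    v <- 1 / (drop(crossprod(Wn, Ea2)) / psi + 1 / hp$tau)
    m <- v * cj / psi
    logodds <- stats::qlogis(pi_j) + 0.5 * log(v / hp$tau) + m^2 / (2 * v)
    p <- stats::plogis(logodds)

    # M-step for mu, psi
    pm <- p * m
    R <- X0 - outer(a, pm)
    mu <- colSums(R * Wn) / nj
    Xc <- sweep(X0, 2, mu) * Wn
    t1 <- colSums(Xc^2)
    t2 <- drop(crossprod(Xc, a)) * pm
    t3 <- drop(crossprod(Wn, Ea2)) * (p * (m^2 + v))
    psi <- pmax((t1 - 2 * t2 + t3) / nj, psi_min)

    # q(f) block
    prec <- 1 + drop(Wn %*% (p * (m^2 + v) / psi))
    s <- 1 / prec
    a <- s * drop(Xc %*% (pm / psi))

    # ELBO
    Ea2 <- a^2 + s
    Eq2 <- colSums(Xc^2) - 2 * drop(crossprod(Xc, a)) * pm +
      drop(crossprod(Wn, Ea2)) * (p * (m^2 + v))
    elogpx <- sum(-0.5 * nj * log(2 * pi * psi) - Eq2 / (2 * psi))
    klf <- sum(0.5 * (a^2 + s - log(s) - 1))
    pc_ <- pmin(pmax(p, 1e-300), 1 - 1e-16)
    klrho <- sum(pc_ * log(pc_ / pi_j) + (1 - pc_) * log((1 - pc_) / (1 - pi_j)) +
                   p * 0.5 * (log(hp$tau / v) + (v + m^2) / hp$tau - 1))
    elbo <- elogpx - klf - klrho
    elbo_trace <- c(elbo_trace, elbo)
    # converge on ELBO stability, or on parameter stability (the ELBO keeps
    # drifting when residual variances sit on their floor in noiseless data)
    par_delta <- max(abs(p - p_prev), abs(m - m_prev), abs(a - a_prev))
    if ((is.finite(elbo) && is.finite(elbo_prev) &&
         abs(elbo - elbo_prev) < hp$tol * (1 + abs(elbo))) ||
        (iter > 1L && par_delta < hp$tol)) {
      converged <- TRUE
      break
    }
    elbo_prev <- elbo
    p_prev <- p; m_prev <- m; a_prev <- a
  }
  if (!converged) {
    warning(sprintf("metaprotein fit for %s did not converge in %d iterations",
                    seed_protein, hp$max_iter))
  }

  membership <- tibble::tibble(
    feature_id = colnames(X),
    protein_id = table$protein_id[match(colnames(X), table$feature_id)],
    is_seed = is_seed,
    loading = unname(m),
    inclusion_prob = unname(p)
  )
  members <- dplyr::filter(membership, .data$inclusion_prob >= hp$membership_threshold)
  if (!any(members$is_seed)) {
    abort_class(sprintf("all seed peptides of %s were excluded from the factor",
                        seed_protein), "metapqtl_degenerate_factor_error")
  }

  # sign convention: mean seed-member loading positive
  if (mean(members$loading[members$is_seed]) < 0) {
    a <- -a
    membership$loading <- -membership$loading
    members$loading <- -members$loading
  }
  score <- standardize(a)
  names(score) <- rownames(X)

  lbl <- table$peptide_label[match(seed_ids, table$feature_id)]
  structure(list(
    name = names(sort(table(lbl), decreasing = TRUE))[1],
    seed_protein = seed_protein,
    membership = membership,
    members = members,
    score = score,
    residual_variances = stats::setNames(psi, colnames(X)),
    mu = stats::setNames(mu, colnames(X)),
    elbo = elbo_trace,
    n_iterations = iter,
    converged = converged,
    hp = hp
  ), class = "metaprotein")
}

#' @export
print.metaprotein <- function(x, ...) {
  cat(sprintf("<metaprotein %s (seed %s)> %d members (%d seed), %s in %d iterations\n",
              x$name, x$seed_protein, nrow(x$members), sum(x$members$is_seed),
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' Coverage and signature of a fitted metaprotein
#'
#' Coverage is the percentage of the seed protein's identified isotope groups
#' that made it into the factor; signature is the percentage of the factor's
#' members that come from the seed protein.
#'
#' @param mp A fitted `metaprotein`.
#' @param table The isotope-group tibble the factor was fitted on.
#' @return A one-row tibble with `factor`, `coverage_pct`, `signature_pct`
#'   (unrounded).
#' @export
composition_metrics <- function(mp, table) {
  seed_feats <- table$feature_id[!is.na(table$protein_id) &
                                   table$protein_id == mp$seed_protein]
  in_factor <- sum(seed_feats %in% mp$members$feature_id)
  tibble::tibble(
    factor = mp$name,
    coverage_pct = 100 * in_factor / length(seed_feats),
    signature_pct = 100 * sum(mp$members$is_seed) / nrow(mp$members)
  )
}

#' Pairwise correlations among a metaprotein's member peptides
#'
#' Pearson correlations on pairwise-complete samples. Pairs with fewer than
#' three overlapping samples get `NA` with a warning.
#'
#' @param mp A fitted `metaprotein`.
#' @param table The isotope-group tibble.
#' @return A symmetric correlation matrix with unit diagonal, one row/column
#'   per member feature.
#' @export
peptide_correlations <- function(mp, table) {
  ids <- mp$members$feature_id
  if (length(ids) < 2) stop_dimension("need at least 2 member peptides")
  X <- intensity_matrix(table)[, ids, drop = FALSE]
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  W <- (!is.na(X)) * 1
  overlap <- crossprod(W)
  if (any(overlap[upper.tri(overlap)] < 3)) {
    warning("some peptide pairs share fewer than 3 samples; correlations set to NA")
    r[overlap < 3] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Fit all metaprotein factors
#'
#' Seeds one factor per protein with at least two identified isotope groups
#' (see [seed_factors()]) and fits each independently with
#' [fit_metaprotein()]; a feature may belong to several metaproteins.
#' Per-factor failures are downgraded to skipped factors with a summary
#' warning.
#'
#' @param table An isotope-group tibble.
#' @param hp A [factor_hyperparams()].
#' @return An object of class `metaprotein_fit` with the list of fitted
#'   factors, the samples-by-factors score tibble (each column standardized
#'   to mean 0, variance 1), composition metrics, and skipped-factor names.
#' @export
fit_metaproteins <- function(table, hp = factor_hyperparams()) {
  seeds <- seed_factors(table)
  fits <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(seeds))) {
    pid <- seeds$protein_id[i]
    res <- tryCatch(fit_metaprotein(table, pid, hp = hp),
                    metapqtl_degenerate_factor_error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, pid)
    } else {
      fits[[length(fits) + 1L]] <- res
    }
  }
  if (length(skipped) > 0) {
    warning(sprintf("%d factor(s) skipped: %s", length(skipped),
                    paste(skipped, collapse = ", ")))
  }
  if (length(fits) == 0) {
    abort_class("no metaprotein factor could be fitted", "metapqtl_degenerate_factor_error")
  }
  nm <- make.unique(purrr::map_chr(fits, "name"))
  scores <- tibble::as_tibble(stats::setNames(
    as.data.frame(purrr::map(fits, "score")), nm))
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = names(fits[[1]]$score)), scores)
  composition <- dplyr::bind_rows(lapply(fits, composition_metrics, table = table))
  composition$factor <- nm
  names(fits) <- nm
  structure(list(factors = fits, scores = scores, composition = composition,
                 hp = hp, skipped = skipped, seeds = seeds),
            class = "metaprotein_fit")
}

#' @export
print.metaprotein_fit <- function(x, ...) {
  cat(sprintf("<metaprotein_fit> %d factors (%d skipped), %d samples\n",
              length(x$factors), length(x$skipped), nrow(x$scores)))
  invisible(x)
}

#' Tidy a metaprotein fit into a membership table
#'
#' @param x A `metaprotein_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (factor, member feature): loading,
#'   inclusion probability, seed flag.
#' @export
tidy.metaprotein_fit <- function(x, ...) {
  purrr::map_dfr(names(x$factors), function(nm) {
    dplyr::mutate(x$factors[[nm]]$members, factor = nm, .before = 1)
  })
}

#' One-row summary of a metaprotein fit
#'
#' @param x A `metaprotein_fit`.
#' @param ... Unused.
#' @return A tibble with factor counts, convergence, and mean composition.
#' @export
glance.metaprotein_fit <- function(x, ...) {
  tibble::tibble(
    n_factors = length(x$factors),
    n_skipped = length(x$skipped),
    n_samples = nrow(x$scores),
    n_converged = sum(vapply(x$factors, `[[`, logical(1), "converged")),
    mean_coverage_pct = mean(x$composition$coverage_pct),
    mean_signature_pct = mean(x$composition$signature_pct)
  )
}

#' Serialize a metaprotein fit to a directory
#'
#' Writes `scores.tsv` (samples x metaproteins), `membership.tsv`,
#' `composition.tsv`, and `fit_meta.yaml` (hyperparameters, seed,
#' convergence).
#'
#' @param fit A `metaprotein_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metaprotein_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_with_header(fit$scores, file.path(dir, "scores.tsv"), "\t")
  write_with_header(tidy.metaprotein_fit(fit), file.path(dir, "membership.tsv"), "\t")
  write_with_header(fit$composition, file.path(dir, "composition.tsv"), "\t")
  meta <- c(unclass(fit$hp),
            list(n_factors = length(fit$factors), skipped = as.list(fit$skipped),
                 converged = sum(vapply(fit$factors, `[[`, logical(1), "converged"))))
  yaml::write_yaml(meta, file.path(dir, "fit_meta.yaml"))
  invisible(dir)
}
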