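# Independent reference implementations used as oracles. These are written
# deliberately as naive loops / explicit formulas so they share no code with
# the package internals they check.

# Explicit normal-equations least squares: beta, se, t, two-sided p for one
# coefficient, from (X'X)^{-1} X'y and the t distribution.
ols_oracle <- function(X, y, col) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- unname(beta[col] / se[col])
  list(beta = unname(beta[col]), se = unname(se[col]), t = tval,
       p = 2 * pt(abs(tval), df, lower.tail = FALSE))
}

# Naive coordinate-ascent fit of the one-factor spike-and-slab model on a
# complete-data matrix, written with scalar loops. Same model, independent
# code path.
ref_cavi <- function(X, pi_j, tau = 1, n_iter = 300) {
  n <- nrow(X); J <- ncol(X)
  mu <- colMeans(X)
  psi <- apply(X, 2, var)
  a <- scale(prcomp(X)$x[, 1])[, 1]
  s <- rep(0.1, n)
  m <- rep(0, J); v <- rep(tau, J); p <- pi_j
  for (it in 1:n_iter) {
    for (j in 1:J) {
      xt <- X[, j] - mu[j]
      v[j] <- 1 / (sum(a^2 + s) / psi[j] + 1 / tau)
      m[j] <- v[j] * sum(a * xt) / psi[j]
      lo <- qlogis(pi_j[j]) + 0.5 * log(v[j] / tau) + m[j]^2 / (2 * v[j])
      p[j] <- plogis(lo)
    }
    for (j in 1:J) {
      mu[j] <- mean(X[, j] - p[j] * m[j] * a)
      xt <- X[, j] - mu[j]
      psi[j] <- max(mean(xt^2 - 2 * p[j] * m[j] * a * xt +
                           p[j] * (m[j]^2 + v[j]) * (a^2 + s)), 1e-10)
    }
    for (i in 1:n) {
      prec <- 1 + sum(p * (m^2 + v) / psi)
      s[i] <- 1 / prec
      a[i] <- s[i] * sum(p * m * (X[i, ] - mu) / psi)
    }
  }
  list(p = p, m = m, a = a, mu = mu, psi = psi)
}

# Hand-coded Newton-Raphson logistic regression on the exact gradients.
logit_oracle <- function(X, y, n_iter = 50) {
  beta <- rep(0, ncol(X))
  for (it in 1:n_iter) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- t(X) %*% (y - p)
    hess <- t(X) %*% (X * (p * (1 - p)))
    beta <- beta + solve(hess, grad)
  }
  drop(beta)
}

# A tiny complete isotope-group tibble built directly (no generator), with a
# known shared signal.
toy_isotope <- function(signal, loadings, noise_sd = 0, protein = "CBG",
                        intercept = 18, seed = 1,
                        extra = NULL, extra_protein = "OTHER") {
  set.seed(seed)
  n <- length(signal)
  J <- length(loadings)
  X <- sapply(loadings, function(l) intercept + l * signal + rnorm(n, sd = noise_sd))
  ids <- sprintf("%s_p%d", protein, seq_len(J))
  prot <- rep(protein, J)
  if (!is.null(extra)) {
    X <- cbind(X, extra)
    ids <- c(ids, sprintf("%s_p%d", extra_protein, seq_len(ncol(extra))))
    prot <- c(prot, rep(extra_protein, ncol(extra)))
  }
  tab <- tibble::tibble(
    feature_id = ids, peptide_label = prot, protein_id = prot,
    monoisotopic_mz = 500 + seq_along(ids), charge_state = 2L,
    peak_centroid_times = replicate(length(ids), c(40, 41), simplify = FALSE),
    peak_time_scores = replicate(length(ids), c(0.9, 0.95), simplify = FALSE)
  )
  intens <- tibble::as_tibble(as.data.frame(t(X)))
  names(intens) <- sprintf("S%03d", seq_len(n))
  dplyr::bind_cols(tab, intens)
}

# Small cohort without simulation machinery.
toy_cohort <- function(allele_count, outcome = NULL, seed = 1) {
  set.seed(seed)
  n <- length(allele_count)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    genotype = c("TT", "CT", "CC")[allele_count + 1L],
    allele_count = as.integer(allele_count),
    sex = sample(c("male", "female"), n, replace = TRUE),
    race = sample(c("Caucasian", "African American"), n, replace = TRUE, prob = c(.78, .22)),
    outcome = if (is.null(outcome)) NA_character_ else outcome
  )
}
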