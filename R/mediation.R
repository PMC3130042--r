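# Nested-logistic mediation analysis: does the metaprotein score mediate the
# genotype-outcome association, or does the genotype act through a separate
# path (pleiotropy)?
#
# P-values come from likelihood-ratio tests of dropping the predictor, and
# 95% intervals from profile likelihood (Wald intervals are emitted
# alongside): with n ~ 41 and odds ratios as extreme as 0.03 the Wald
# approximation is unreliable and can disagree with the LRT about
# significance. Under (near-)separation the maximum-likelihood fit is flagged
# and a bias-reduced fit (Firth's Jeffreys-prior penalty) is reported
# alongside, never silently substituted.

# Newton-Raphson logistic regression with optional offset and optional Firth
# penalty. Returns coefficients, (penalized) log-likelihood and X'WX.
logistic_engine <- function(X, y, offset = NULL, firth = FALSE,
                            max_iter = 100, tol = 1e-10) {
  if (is.null(offset)) offset <- rep(0, length(y))
  beta <- rep(0, ncol(X))
  ll_of <- function(beta) {
    eta <- drop(X %*% beta) + offset
    # numerically stable log(1 + exp(eta))
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    if (firth) {
      p <- stats::plogis(eta)
      w <- pmax(p * (1 - p), 1e-12)
      ll <- ll + 0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
    }
    ll
  }
  ll_old <- ll_of(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    Xw <- X * sqrt(w)
    XtWX <- crossprod(Xw)
    adj <- 0
    if (firth) {
      # hat-matrix diagonal of the weighted design
      H <- Xw %*% solve(XtWX)
      h <- rowSums(H * Xw)
      adj <- h * (0.5 - p)
    }
    U <- drop(crossprod(X, y - p + adj))
    delta <- tryCatch(solve(XtWX, U), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {  # step-halving keeps the (penalized) likelihood non-decreasing
      cand <- beta + step * delta
      ll_new <- ll_of(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-8) { cand <- beta; ll_new <- ll_old; break }
    }
    moved <- max(abs(cand - beta))
    beta <- cand
    if (abs(ll_new - ll_old) < tol && moved < 1e-8) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta) + offset
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  XtWX <- crossprod(X * sqrt(w))
  list(beta = beta, loglik = ll_of(beta), XtWX = XtWX, converged = converged,
       fitted = p)
}

# Profile (penalized-)likelihood CI for one column of X by inverting the LRT:
# find beta0 on each side of the estimate where the profile deviance rises by
# qchisq(level, 1).
profile_ci <- function(X, y, col, ll_max, firth = FALSE, level = 0.95,
                       beta_hat, se_hat) {
  crit <- stats::qchisq(level, 1) / 2
  Xr <- X[, -col, drop = FALSE]
  xcol <- X[, col]
  g <- function(b0) {
    pl <- logistic_engine(Xr, y, offset = b0 * xcol, firth = firth)$loglik
    (ll_max - pl) - crit
  }
  step0 <- max(se_hat, 0.5)
  find_side <- function(dir) {
    lo <- beta_hat
    for (k in 1:40) {
      hi <- beta_hat + dir * step0 * 2^(k / 2)
      val <- g(hi)
      if (is.finite(val) && val > 0) {
        r <- tryCatch(stats::uniroot(g, sort(c(lo, hi)), tol = 1e-6)$root,
                      error = function(e) NA_real_)
        return(r)
      }
      lo <- hi
    }
    dir * Inf  # profile never crosses: open-ended interval (separation)
  }
  c(find_side(-1), find_side(1))
}

encode_outcome <- function(v, event = "SVR") {
  if (is.numeric(v)) {
    if (!all(stats::na.omit(v) %in% 0:1)) stop_schema("numeric outcome must be 0/1")
    return(as.integer(v))
  }
  as.integer(as.character(v) == event)
}

#' Logistic regression of a binary outcome on one predictor of interest
#'
#' Maximum-likelihood logistic regression with the predictor's p-value from
#' the likelihood-ratio test of dropping it, 95% CI by profile likelihood
#' (Wald CI reported alongside), and odds ratio `exp(beta)`. If the fit shows
#' (near-)separation the ML row is flagged `converged = FALSE` and a second,
#' clearly labelled bias-reduced (Firth) row is appended.
#'
#' @param data Tibble holding the outcome, predictor, and covariates.
#' @param outcome Name of the binary outcome column (`"SVR"`/`"NR"` strings
#'   or 0/1; `event` names the success level).
#' @param predictor Name of the predictor of interest.
#' @param covariates Covariate column names (default sex and race).
#' @param event Outcome level coded 1 (default `"SVR"`).
#' @param ci Compute profile-likelihood intervals (default `TRUE`); with
#'   `FALSE` the profile columns are `NA` (the Wald columns remain), which is
#'   faster in large simulations that only need p-values.
#' @return A tibble (one row per method: `"ml"`, plus `"firth"` under
#'   separation): `predictor`, `method`, `beta`, `se`, `odds_ratio`,
#'   `conf.low`/`conf.high` (profile), `wald.low`/`wald.high`, `p_value`
#'   (LRT), `n_used`, `converged`, `covariates`.
#' @export
logistic_fit <- function(data, outcome, predictor, covariates = c("sex", "race"),
                         event = "SVR", ci = TRUE) {
  cols <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  d <- data[cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  y <- encode_outcome(d[[outcome]], event)
  if (length(unique(y)) < 2) {
    abort_class("outcome has a single class in the analysis sample",
                "metapqtl_invalid_input_error")
  }
  for (cv in covariates) if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  if (is.logical(d[[predictor]])) d[[predictor]] <- as.numeric(d[[predictor]])
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  if (nrow(X) <= ncol(X) + 1) {
    abort_class("too few complete samples for the logistic design",
                "metapqtl_invalid_input_error")
  }
  check_design(X)
  col <- 2L  # predictor immediately after intercept

  one_fit <- function(firth) {
    full <- logistic_engine(X, y, firth = firth)
    red <- logistic_engine(X[, -col, drop = FALSE], y, firth = firth)
    beta <- unname(full$beta[col])
    se <- unname(sqrt(diag(solve(full$XtWX)))[col])
    lrt <- 2 * (full$loglik - red$loglik)
    p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
    bounds <- if (ci) {
      profile_ci(X, y, col, full$loglik, firth = firth,
                 beta_hat = beta, se_hat = se)
    } else {
      c(NA_real_, NA_real_)
    }
    tibble::tibble(
      predictor = predictor, method = if (firth) "firth" else "ml",
      beta = beta, se = se, odds_ratio = exp(beta),
      conf.low = exp(bounds[1]), conf.high = exp(bounds[2]),
      wald.low = exp(beta - 1.96 * se), wald.high = exp(beta + 1.96 * se),
      p_value = p, n_used = nrow(X),
      converged = full$converged, covariates = paste(covariates, collapse = ","))
  }

  ml <- one_fit(firth = FALSE)
  separated <- !ml$converged || abs(ml$beta) > 15 || ml$se > 10 ||
    (ci && any(!is.finite(c(ml$conf.low, ml$conf.high))))
  if (separated) {
    ml$converged <- FALSE
    return(dplyr::bind_rows(ml, one_fit(firth = TRUE)))
  }
  ml
}

#' Nested-logistic mediation analysis
#'
#' Fits the three models of the attenuation comparison on one common sample:
#' outcome ~ mediator + covariates (`m_only`), outcome ~ 1{non-CC} +
#' covariates (`g_only`), and the joint model with both (`joint_g`,
#' `joint_m` rows report each term's LRT within the joint fit). Verdict:
#' `"independent"` when both marginal fits are significant, the mediator's
#' joint p >= 0.05 and the genotype's joint p < 0.05 (the genotype acts on
#' outcome through a separate path); `"mediates"` when the genotype is the
#' one attenuated instead; otherwise `"ambiguous"`.
#'
#' @param data Tibble with the outcome, `allele_count`, the mediator column,
#'   and covariates; rows with any missing value among these are dropped so
#'   all fits share one sample.
#' @param outcome,covariates,event As in [logistic_fit()].
#' @param mediator Name of the mediator column (a metaprotein score).
#' @param genotype Name of the allele-count column; enters all models as the
#'   recessive indicator `1{allele_count < 2}`, so odds ratios below 1 mean
#'   the non-CC group has lower odds of the event.
#' @param alpha Significance level for the verdict (default 0.05).
#' @param ci Passed to [logistic_fit()]; `FALSE` skips profile intervals.
#' @return An object of class `mediation_result`: `fits` (tibble of the four
#'   model rows) and `verdict`. `tidy()` returns the fits.
#' @export
mediation_analysis <- function(data, outcome, genotype = "allele_count",
                               mediator, covariates = c("sex", "race"),
                               event = "SVR", alpha = 0.05, ci = TRUE) {
  cols <- c(outcome, genotype, mediator, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  d <- data[cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$..non_cc <- as.numeric(d[[genotype]] < 2)

  m_only <- logistic_fit(d, outcome, mediator, covariates, event, ci = ci)
  g_only <- logistic_fit(d, outcome, "..non_cc", covariates, event, ci = ci)
  joint_g <- logistic_fit(d, outcome, "..non_cc", c(mediator, covariates), event, ci = ci)
  joint_m <- logistic_fit(d, outcome, mediator, c("..non_cc", covariates), event, ci = ci)

  label <- function(tbl, model) dplyr::mutate(tbl, model = model, .before = 1)
  fits <- dplyr::bind_rows(label(m_only, "m_only"), label(g_only, "g_only"),
                           label(joint_g, "joint_g"), label(joint_m, "joint_m"))
  fits$predictor[fits$predictor == "..non_cc"] <- "non_CC"

  p_of <- function(model) fits$p_value[fits$model == model][1]  # ml row first
  marginals_sig <- p_of("m_only") < alpha && p_of("g_only") < alpha
  verdict <- if (marginals_sig && p_of("joint_m") >= alpha && p_of("joint_g") < alpha) {
    "independent"
  } else if (marginals_sig && p_of("joint_g") >= alpha && p_of("joint_m") < alpha) {
    "mediates"
  } else {
    "ambiguous"
  }
  structure(list(fits = fits, verdict = verdict, alpha = alpha,
                 mediator = mediator, n_used = nrow(d)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> mediator %s, n = %d, verdict: %s\n",
              x$mediator, x$n_used, x$verdict))
  print(x$fits[c("model", "predictor", "method", "odds_ratio",
                 "conf.low", "conf.high", "p_value")])
  invisible(x)
}

#' @export
tidy.mediation_result <- function(x, ...) x$fits

#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(verdict = x$verdict, mediator = x$mediator,
                 n_used = x$n_used, alpha = x$alpha)
}

#' Write a mediation result as TSV
#'
#' One row per fit plus a `# verdict:` header line.
#'
#' @param result A `mediation_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mediation <- function(result, path) {
  write_with_header(result$fits, path, "\t",
                    c(sprintf("verdict: %s", result$verdict),
                      sprintf("mediator: %s", result$mediator)))
}
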