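#' Specify a single-factor measurement model
#'
#' @param name Factor label.
#' @param indicators Character vector of indicator column names (>= 2, or a
#'   single indicator used as a fixed-loading passthrough).
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(name, indicators) {
  stop_if_not(length(indicators) >= 1, "need at least one indicator")
  structure(list(name = name, indicators = indicators,
                 identification = "unit latent variance"),
            class = "factor_spec")
}

#' Fit a one-factor confirmatory model by maximum likelihood
#'
#' Maximum-likelihood one-factor solution with the latent variance fixed at
#' 1, fitted on pairwise-complete correlations; factor scores are computed by
#' the regression (Thomson) method, with missing indicator values mean-imputed
#' (zero on the standardized scale) for scoring only. The sign convention
#' fixes the first indicator's loading to be nonnegative. A Heywood case
#' (uniqueness reaching the 1e-4 lower bound) is flagged with a warning and
#' status `"heywood_clamped"` rather than an error.
#'
#' A single-indicator spec degenerates to a passthrough with loading fixed at
#' one.
#'
#' @param data Data frame holding the indicators (standardized internally).
#' @param spec A [factor_spec()].
#' @return An object of class `factor_solution`: `loadings`, `uniquenesses`,
#'   `scores`, `loglik`, `srmr`, `status`, `n`.
#' @export
fit_single_factor <- function(data, spec) {
  ind <- spec$indicators
  stop_if_not(all(ind %in% names(data)),
              "spec indicators missing from data")
  X <- as.matrix(data[, ind, drop = FALSE])
  stop_if_not(!any(colSums(!is.na(X)) == 0), "fully-missing indicator column")
  X <- scale(X)

  if (length(ind) == 1L) {
    scores <- as.vector(X)
    return(structure(list(
      loadings = stats::setNames(1, ind), uniquenesses = stats::setNames(0, ind),
      scores = scores, loglik = NA_real_, srmr = 0, status = "passthrough",
      n = sum(!is.na(X))), class = "factor_solution"))
  }

  n_pair <- crossprod(!is.na(X))
  stop_if_not(min(n_pair) >= 50,
              "pairwise-complete n < 50 for at least one indicator pair")
  R <- stats::cor(X, use = "pairwise.complete.obs")
  n_obs <- min(n_pair)

  lower <- 1e-4
  if (length(ind) == 2L) {
    # two indicators: identified only under an equal-loading constraint,
    # giving the closed form lambda = sqrt(r12)
    r12 <- R[1, 2]
    lam <- rep(sqrt(max(r12, 0)), 2)
    uniq <- pmax(1 - lam^2, lower)
  } else {
    fa <- stats::factanal(covmat = R, factors = 1, n.obs = n_obs,
                          rotation = "none", control = list(lower = lower))
    lam <- as.vector(fa$loadings)
    uniq <- fa$uniquenesses
  }
  status <- "ok"
  if (any(uniq <= lower * (1 + 1e-6))) {
    warning("Heywood case: uniqueness clamped at 1e-4")
    status <- "heywood_clamped"
  }
  if (lam[1] < 0) lam <- -lam

  # Thomson regression scores from the fitted structure; NA -> 0 (mean).
  X0 <- X; X0[is.na(X0)] <- 0
  w <- solve(R, lam)
  scores <- as.vector(X0 %*% w)

  implied <- tcrossprod(lam) + diag(uniq)
  p <- length(ind)
  srmr <- sqrt(sum((R - implied)[lower.tri(R, diag = TRUE)]^2) /
                 (p * (p + 1) / 2))
  S <- R
  loglik <- -0.5 * n_obs *
    (log(det(implied)) + sum(diag(solve(implied, S))) - log(det(S)) - p)

  structure(list(loadings = stats::setNames(lam, ind),
                 uniquenesses = stats::setNames(as.vector(uniq), ind),
                 scores = scores, loglik = loglik, srmr = srmr,
                 status = status, n = n_obs),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("One-factor ML solution (latent variance fixed at 1)\n")
  print(round(rbind(loading = x$loadings, uniqueness = x$uniquenesses), 3))
  cat(sprintf("SRMR %.4f | status %s | n %d\n", x$srmr, x$status, x$n))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")`, kept as a named
#' operation so every analysis battery corrects through the same door.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (empty allowed).
#' @return Vector of q-values, monotone in p-rank and capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stop_if_not(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Standardized multiple regression with covariate adjustment
#'
#' OLS of a standardized outcome on standardized predictors and covariates.
#' When `family_id` is supplied, one twin per family is selected at random
#' under a fixed seed to avoid family clustering. Heteroskedasticity-robust
#' (HC1) standard errors are available via `robust = TRUE`. BH q-values are
#' computed across the predictor terms.
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param predictors Character vector of focal predictor columns.
#' @param covariates Character vector of covariate columns (may be empty).
#' @param family_id Optional column naming the family/cluster id.
#' @param robust Use HC1 robust standard errors.
#' @param seed Seed for the one-per-family subsample.
#' @return A `regression_result` data frame: one row per model term
#'   (`term`, `beta`, `se`, `t`, `p`, `q`, `predictor` flag), with
#'   attributes `n` and `r2`.
#' @export
regress_standardized <- function(data, outcome, predictors,
                                 covariates = character(),
                                 family_id = NULL, robust = FALSE,
                                 seed = 1) {
  vars <- c(outcome, predictors, covariates)
  stop_if_not(all(vars %in% names(data)), "model columns missing from data")
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  if (!is.null(family_id)) {
    d <- one_per_family(d, family_id, seed = seed)
  }
  for (v in vars) {
    if (is.numeric(d[[v]]) && length(unique(d[[v]])) > 2) d[[v]] <- zstd(d[[v]])
  }
  X <- stats::model.matrix(
    stats::reformulate(c(predictors, covariates)), data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient model matrix; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(d[[outcome]] ~ X - 1)
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  vc <- if (robust) hc1_vcov(fit, X) else stats::vcov(fit)
  se <- sqrt(diag(vc))
  tval <- beta / se
  df <- fit$df.residual
  p <- 2 * stats::pt(-abs(tval), df)
  res <- data.frame(term = colnames(X), beta = unname(beta), se = unname(se),
                    t = unname(tval), p = unname(p),
                    predictor = colnames(X) %in% predictors,
                    stringsAsFactors = FALSE)
  res$q <- NA_real_
  res$q[res$predictor] <- bh_adjust(res$p[res$predictor])
  attr(res, "n") <- nrow(d)
  attr(res, "r2") <- summary(fit)$r.squared
  class(res) <- c("regression_result", "data.frame")
  res
}

# HC1 heteroskedasticity-robust covariance for an lm fitted on matrix X.
hc1_vcov <- function(fit, X) {
  u <- stats::residuals(fit)
  n <- length(u); k <- ncol(X)
  XtXi <- solve(crossprod(X))
  meat <- crossprod(X * u)
  (n / (n - k)) * XtXi %*% meat %*% XtXi
}

# Select one twin per family under a fixed seed.
one_per_family <- function(d, family_id, seed = 1) {
  with_seed(derive_seed(seed, "subsample"), {
    idx <- seq_len(nrow(d))
    keep <- unlist(lapply(split(idx, d[[family_id]]), function(i) {
      if (length(i) == 1) i else sample(i, 1)
    }), use.names = FALSE)
    d[sort(keep), , drop = FALSE]
  })
}
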