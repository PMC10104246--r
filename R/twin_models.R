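# Classical twin analysis: intraclass correlations, Falconer estimates, and
# maximum-likelihood ACE models (univariate, common pathway, Cholesky) fitted
# by full-information normal-theory ML on pair vectors grouped by zygosity.

#' Arrange a twin cohort into per-zygosity pair matrices
#'
#' @param cohort A `twin_cohort` long data frame.
#' @param traits Trait names to extract (column order is preserved).
#' @param age,rater Optional filters.
#' @return List with `mz` and `dz` matrices (columns: twin-1 traits then
#'   twin-2 traits) and the trait names.
#' @export
twin_pair_matrix <- function(cohort, traits, age = NULL, rater = NULL) {
  d <- as.data.frame(cohort)
  if (!is.null(age)) d <- d[d$age %in% age, , drop = FALSE]
  if (!is.null(rater)) d <- d[d$rater %in% rater, , drop = FALSE]
  d <- d[d$trait %in% traits, , drop = FALSE]
  stop_if_not(nrow(d) > 0, "no rows left after filtering")
  key <- paste(d$family_id, d$trait, d$twin)
  stop_if_not(!anyDuplicated(key),
              "multiple rows per (family, trait, twin); filter by age/rater")
  fams <- sort(unique(d$family_id))
  p <- length(traits)
  arr <- array(NA_real_, c(length(fams), p, 2))
  for (j in seq_len(p)) {
    for (w in 1:2) {
      sub <- d[d$trait == traits[j] & d$twin == w, , drop = FALSE]
      arr[match(sub$family_id, fams), j, w] <- sub$value
    }
  }
  zyg <- d$zygosity[match(fams, d$family_id)]
  W <- cbind(arr[, , 1, drop = TRUE], arr[, , 2, drop = TRUE])
  W <- matrix(W, nrow = length(fams)) # guard p = 1 dimension dropping
  ok <- stats::complete.cases(W)
  list(mz = W[ok & zyg == "MZ", , drop = FALSE],
       dz = W[ok & zyg == "DZ", , drop = FALSE],
       traits = traits)
}

#' Twin intraclass correlations by zygosity
#'
#' Pearson correlation on double-entered pairs (each pair contributes both
#' orderings), computed separately for MZ and DZ groups, with Fisher-z
#' confidence intervals based on the number of pairs.
#'
#' @param cohort A `twin_cohort`.
#' @param trait Single trait name.
#' @param age,rater Optional filters.
#' @param conf Confidence level.
#' @return Object of class `twin_correlations`: `r_mz`, `r_dz`, pair counts
#'   and CIs.
#' @export
intraclass_correlations <- function(cohort, trait, age = NULL, rater = NULL,
                                    conf = 0.95) {
  pm <- twin_pair_matrix(cohort, trait, age = age, rater = rater)
  icc <- function(W) {
    n <- nrow(W)
    stop_if_not(n >= 30, "fewer than 30 complete pairs in a zygosity group")
    x <- c(W[, 1], W[, 2]); y <- c(W[, 2], W[, 1])
    stop_if_not(stats::sd(x) > 0, "zero variance in trait values")
    r <- stats::cor(x, y)
    zcrit <- stats::qnorm(1 - (1 - conf) / 2)
    zr <- atanh(max(min(r, 0.999999), -0.999999))
    ci <- tanh(zr + c(-1, 1) * zcrit / sqrt(n - 3))
    list(r = r, n = n, ci = ci)
  }
  mz <- icc(pm$mz); dz <- icc(pm$dz)
  structure(list(trait = trait, r_mz = mz$r, r_dz = dz$r,
                 n_mz = mz$n, n_dz = dz$n,
                 ci_mz = mz$ci, ci_dz = dz$ci, conf = conf),
            class = "twin_correlations")
}

#' @export
print.twin_correlations <- function(x, ...) {
  cat(sprintf("Intraclass correlations for '%s'\n", x$trait))
  cat(sprintf("  rMZ = %.3f [%.3f, %.3f] (n = %d pairs)\n",
              x$r_mz, x$ci_mz[1], x$ci_mz[2], x$n_mz))
  cat(sprintf("  rDZ = %.3f [%.3f, %.3f] (n = %d pairs)\n",
              x$r_dz, x$ci_dz[1], x$ci_dz[2], x$n_dz))
  invisible(x)
}

#' Falconer variance-component estimates
#'
#' The classical moment estimates: heritability as double the MZ-DZ
#' intraclass-correlation difference, `A = 2(rMZ - rDZ)`, shared environment
#' `C = rMZ - A`, nonshared environment `E = 1 - rMZ`. Components are
#' truncated to \[0, 1\] with the truncation flagged (not an error).
#'
#' @param r A [intraclass_correlations()] result.
#' @return Object of class `variance_components` with fields `A`, `C`, `E`,
#'   `truncated`, `source = "falconer"`.
#' @export
falconer_estimates <- function(r) {
  A <- 2 * (r$r_mz - r$r_dz)
  C <- r$r_mz - A
  E <- 1 - r$r_mz
  raw <- c(A = A, C = C, E = E)
  tr <- pmin(pmax(raw, 0), 1)
  structure(list(A = tr[["A"]], C = tr[["C"]], E = tr[["E"]],
                 raw = raw, truncated = any(raw != tr),
                 source = "falconer", trait = r$trait),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (%s): A = %.3f, C = %.3f, E = %.3f%s\n",
              x$source, x$A, x$C, x$E,
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

# ---- ML ACE fitting ------------------------------------------------------

# Expected twin-pair covariance from component matrices.
ace_sigma <- function(A, C, E, rA) {
  T_ <- A + C + E
  ct <- rA * A + C
  rbind(cbind(T_, ct), cbind(ct, T_))
}

# Component matrices implied by a parameter vector for each model kind.
ace_components <- function(par, kind, p) {
  if (kind == "univariate") {
    list(A = matrix(par[1]^2, 1, 1), C = matrix(par[2]^2, 1, 1),
         E = matrix(par[3]^2, 1, 1))
  } else if (kind == "cholesky") {
    m <- p * (p + 1) / 2
    X <- lower_tri_from_vec(par[1:m], p)
    Y <- lower_tri_from_vec(par[m + 1:m], p)
    Z <- lower_tri_from_vec(par[2 * m + 1:m], p)
    list(A = tcrossprod(X), C = tcrossprod(Y), E = tcrossprod(Z),
         X = X, Y = Y, Z = Z)
  } else if (kind == "common_pathway") {
    # latent direction normalized to unit latent variance for identification
    ace <- par[1:3] / sqrt(sum(par[1:3]^2))
    f <- par[3 + seq_len(p)]
    as_ <- par[3 + p + seq_len(p)]
    cs <- par[3 + 2 * p + seq_len(p)]
    es <- par[3 + 3 * p + seq_len(p)]
    ff <- tcrossprod(f)
    list(A = ace[1]^2 * ff + diag(as_^2, p),
         C = ace[2]^2 * ff + diag(cs^2, p),
         E = ace[3]^2 * ff + diag(es^2, p),
         latent = ace^2, loadings = f,
         specific = cbind(a2 = as_^2, c2 = cs^2, e2 = es^2))
  } else stop("unknown model kind: ", kind, call. = FALSE)
}

ace_neg2ll <- function(par, kind, p, stats_) {
  comp <- ace_components(par, kind, p)
  val <- 0
  for (g in c("mz", "dz")) {
    n <- stats_[[g]]$n
    if (n == 0) next
    S <- stats_[[g]]$S
    Sg <- ace_sigma(comp$A, comp$C, comp$E, if (g == "mz") 1 else 0.5)
    dec <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(dec)) return(1e10)
    logdet <- 2 * sum(log(diag(dec)))
    val <- val + n * (2 * p * log(2 * pi) + logdet +
                        sum(chol2inv(dec) * S))
  }
  val
}

# Method-of-moments starting components from the observed covariances.
ace_start_components <- function(stats_, p) {
  Smz <- stats_$mz$S; Sdz <- stats_$dz$S
  Tm <- (Smz[1:p, 1:p] + Smz[p + 1:p, p + 1:p] +
           Sdz[1:p, 1:p] + Sdz[p + 1:p, p + 1:p]) / 4
  CTmz <- (Smz[1:p, p + 1:p] + t(Smz[1:p, p + 1:p])) / 2
  CTdz <- (Sdz[1:p, p + 1:p] + t(Sdz[1:p, p + 1:p])) / 2
  A <- psd_clip(as.matrix(2 * (CTmz - CTdz)), 1e-4)
  C <- psd_clip(as.matrix(2 * CTdz - CTmz), 1e-4)
  E <- psd_clip(as.matrix(Tm - A - C), 1e-4)
  list(A = A, C = C, E = E)
}

#' Fit an ACE model by maximum likelihood
#'
#' Full-information normal-theory ML over twin-pair vectors grouped by
#' zygosity, with expected covariance `[[T, A+C], [A+C, T]]` for MZ and
#' `[[T, 0.5A+C], [0.5A+C, T]]` for DZ pairs (block form for multivariate
#' models). Optimization is over unconstrained Cholesky/path parameters, so
#' A, C and E are positive semi-definite by construction; five seeded starts
#' (method-of-moments plus jitters) guard against local optima. Traits are
#' standardized before fitting, so components are proportions of variance.
#'
#' Model kinds:
#' \describe{
#'   \item{`univariate`}{one trait; parameters a, c, e.}
#'   \item{`cholesky`}{p traits; lower-triangular factors X, Y, Z with
#'     `A = XX'` etc.}
#'   \item{`common_pathway`}{p indicators of one latent factor with unit
#'     latent variance; parameters: latent a/c/e (normalized), indicator
#'     loadings, and indicator-specific a/c/e paths.}
#' }
#'
#' @param cohort A `twin_cohort`.
#' @param traits Trait name(s); order matters for `cholesky`.
#' @param kind One of `"univariate"`, `"common_pathway"`, `"cholesky"`.
#' @param age,rater Optional filters passed to [twin_pair_matrix()].
#' @param n_starts Number of optimization starts.
#' @param seed Seed for start jitter.
#' @param compute_se Compute SEs from the numerical Hessian.
#' @return An object of class `ace_fit`.
#' @export
fit_ace <- function(cohort, traits, kind = c("univariate", "common_pathway",
                                             "cholesky"),
                    age = NULL, rater = NULL, n_starts = 5, seed = 1,
                    compute_se = FALSE) {
  kind <- match.arg(kind)
  p <- length(traits)
  if (kind == "univariate") stop_if_not(p == 1, "univariate needs one trait")
  if (kind == "cholesky") stop_if_not(p >= 2, "cholesky needs >= 2 traits")
  pm <- twin_pair_matrix(cohort, traits, age = age, rater = rater)
  stop_if_not(nrow(pm$mz) >= 20 && nrow(pm$dz) >= 20,
              "need at least 20 complete pairs per zygosity group")

  # standardize each trait over all observations (both twins, both groups)
  W <- rbind(pm$mz, pm$dz)
  mu <- colMeans(W); sdv <- apply(W, 2, stats::sd)
  scl <- function(M) sweep(sweep(M, 2, mu, "-"), 2, sdv, "/")
  mz <- scl(pm$mz); dz <- scl(pm$dz)
  mlcov <- function(M) {
    Mc <- sweep(M, 2, colMeans(M), "-")
    crossprod(Mc) / nrow(M)
  }
  stats_ <- list(mz = list(S = mlcov(mz), n = nrow(mz)),
                 dz = list(S = mlcov(dz), n = nrow(dz)))

  sc <- ace_start_components(stats_, p)
  base_par <- switch(kind,
    univariate = sqrt(pmax(c(sc$A[1, 1], sc$C[1, 1], sc$E[1, 1]), 0.05)),
    cholesky = c(t(chol(psd_clip(sc$A, 1e-3)))[lower.tri(sc$A, diag = TRUE)],
                 t(chol(psd_clip(sc$C, 1e-3)))[lower.tri(sc$C, diag = TRUE)],
                 t(chol(psd_clip(sc$E, 1e-3)))[lower.tri(sc$E, diag = TRUE)]),
    common_pathway = {
      Rw <- stats::cov2cor((stats_$mz$S[1:p, 1:p] + stats_$dz$S[1:p, 1:p]) / 2)
      f0 <- vapply(seq_len(p), function(j) {
        sqrt(max(mean(Rw[j, -j]), 0.15))
      }, numeric(1))
      c(0.7, 0.4, 0.6, f0, rep(0.35, p), rep(0.25, p), rep(0.5, p))
    })

  with_seed(derive_seed(seed, "fitstarts"), {
    best <- NULL
    for (s in seq_len(n_starts)) {
      par0 <- if (s == 1) base_par else
        base_par * stats::runif(length(base_par), 0.6, 1.4) +
          stats::rnorm(length(base_par), sd = 0.02)
      obj <- function(v) ace_neg2ll(v, kind, p, stats_)
      opt <- tryCatch(
        stats::optim(par0, obj, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
    }
    stop_if_not(!is.null(best), "all optimization starts failed")
    comp <- ace_components(best$par, kind, p)
    T_ <- comp$A + comp$C + comp$E
    std <- list(A = comp$A / sqrt(tcrossprod(diag(T_))),
                C = comp$C / sqrt(tcrossprod(diag(T_))),
                E = comp$E / sqrt(tcrossprod(diag(T_))))

    se <- NULL
    if (compute_se) {
      H <- tryCatch(stats::optimHess(best$par,
                                     function(v) ace_neg2ll(v, kind, p,
                                                            stats_)),
                    error = function(e) NULL)
      if (!is.null(H)) {
        cv <- tryCatch(2 * solve(H), error = function(e) NULL)
        if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
      }
    }

    boundary <- switch(kind,
      univariate = any(abs(best$par) < 1e-3),
      common_pathway = any(abs(best$par[1:3] / sqrt(sum(best$par[1:3]^2)))
                           < 1e-3),
      cholesky = any(abs(diag(comp$X)) < 1e-3))

    structure(list(
      kind = kind, traits = pm$traits, par = best$par, par_se = se,
      A = comp$A, C = comp$C, E = comp$E, std = std,
      latent = if (kind == "common_pathway")
        stats::setNames(comp$latent, c("a2", "c2", "e2")),
      loadings = if (kind == "common_pathway") comp$loadings,
      specific = if (kind == "common_pathway") comp$specific,
      X = comp$X, Y = comp$Y, Z = comp$Z,
      minus2ll = best$value,
      sigma_mz = ace_sigma(comp$A, comp$C, comp$E, 1),
      sigma_dz = ace_sigma(comp$A, comp$C, comp$E, 0.5),
      n_mz = stats_$mz$n, n_dz = stats_$dz$n,
      convergence = best$convergence == 0,
      boundary = boundary),
      class = "ace_fit")
  })
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("ACE %s model: %s | -2lnL = %.2f | %s\n", x$kind,
              paste(x$traits, collapse = ", "), x$minus2ll,
              if (x$convergence) "converged" else "NOT converged"))
  if (x$kind == "univariate") {
    cat(sprintf("  A = %.3f, C = %.3f, E = %.3f\n",
                x$std$A[1, 1], x$std$C[1, 1], x$std$E[1, 1]))
  } else if (x$kind == "common_pathway") {
    cat(sprintf("  latent: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
                x$latent[1], x$latent[2], x$latent[3]))
  } else {
    cat("  standardized A diagonal:",
        paste(round(diag(x$std$A), 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Genetic variance shares of achievement from a trivariate Cholesky fit
#'
#' For a Cholesky fit over the ordered triple (cognitive, noncognitive,
#' achievement), reports the proportions of achievement's total variance
#' attributable to genetics shared with cognitive skills (squared first
#' genetic path), to noncognitive genetics beyond cognitive (squared second
#' path), and to achievement-specific genetics (squared third path). The
#' three shares sum to achievement's heritability.
#'
#' @param fit An [fit_ace()] result with `kind = "cholesky"` over exactly
#'   three traits, achievement entered last.
#' @return Object of class `variance_shares`.
#' @export
variance_shares_from_cholesky <- function(fit) {
  stop_if_not(inherits(fit, "ace_fit") && fit$kind == "cholesky",
              "fit must be a Cholesky ace_fit")
  stop_if_not(length(fit$traits) == 3,
              "variance shares require a trivariate fit (achievement last)")
  v3 <- (fit$A + fit$C + fit$E)[3, 3]
  X <- fit$X
  shares <- c(share_cog = X[3, 1]^2, share_noncog_independent = X[3, 2]^2,
              share_achievement_specific = X[3, 3]^2) / v3
  structure(list(share_cog = shares[[1]],
                 share_noncog_independent = shares[[2]],
                 share_achievement_specific = shares[[3]],
                 total_h2 = sum(shares), traits = fit$traits),
            class = "variance_shares")
}

#' @export
print.variance_shares <- function(x, ...) {
  cat("Achievement genetic variance shares (trivariate Cholesky)\n")
  cat(sprintf("  cognitive-shared        %.3f\n", x$share_cog))
  cat(sprintf("  noncognitive-independent %.3f\n", x$share_noncog_independent))
  cat(sprintf("  achievement-specific     %.3f\n",
              x$share_achievement_specific))
  cat(sprintf("  total heritability       %.3f\n", x$total_h2))
  invisible(x)
}
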