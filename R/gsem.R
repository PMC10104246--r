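# Genomic structural equation model: a two-factor (Cog/NonCog) measurement
# model fitted to the LDSC genetic covariance matrix by diagonally weighted
# least squares, the per-SNP subtraction step that turns it into factor-level
# association statistics, and factor-level genetic correlations with
# external traits.

#' Declare a two-factor Cog/NonCog path model
#'
#' All traits load on the Cog factor; only the traits named in `noncog` load
#' on the NonCog factor (educational attainment and the socioeconomic
#' indicators in the default architecture). Factor variances are fixed at 1
#' for identification; the factor covariance is fixed at 0 in the default
#' subtraction parameterization or freely estimated in the oblique variant;
#' residual variances are free (or fixed to 0), residual covariances fixed
#' at 0.
#'
#' @param traits Trait labels (order must match the genetic covariance).
#' @param noncog Traits loading on NonCog.
#' @param residuals `"free"` or `"zero"`.
#' @param factor_cov `"zero"` (subtraction default) or `"free"`.
#' @return Object of class `path_model`.
#' @export
path_model <- function(traits = c("CP", "SD", "ME", "TM", "RT",
                                  "EA", "IN", "DE"),
                       noncog = c("EA", "IN", "DE"),
                       residuals = c("free", "zero"),
                       factor_cov = c("zero", "free")) {
  residuals <- match.arg(residuals)
  factor_cov <- match.arg(factor_cov)
  stop_if_not(all(noncog %in% traits), "noncog traits must be among traits")
  stop_if_not(length(setdiff(traits, noncog)) >= 1,
              "at least one trait must load on Cog only (identification)")
  structure(list(traits = traits, noncog = noncog,
                 residuals = residuals, factor_cov = factor_cov),
            class = "path_model")
}

# Free-parameter layout for a path model.
pm_layout <- function(model) {
  k <- length(model$traits)
  noncog_idx <- match(model$noncog, model$traits)
  n_res <- if (model$residuals == "free") k else 0
  n_fc <- if (model$factor_cov == "free") 1 else 0
  list(k = k, noncog_idx = noncog_idx,
       n_par = k + length(noncog_idx) + n_res + n_fc,
       idx_cog = seq_len(k),
       idx_noncog = k + seq_along(noncog_idx),
       idx_res = if (n_res) k + length(noncog_idx) + seq_len(k) else integer(),
       idx_fc = if (n_fc) k + length(noncog_idx) + n_res + 1 else integer())
}

# Implied genetic covariance for a parameter vector.
pm_implied <- function(theta, model, layout) {
  k <- layout$k
  Lc <- theta[layout$idx_cog]
  Ln <- numeric(k)
  Ln[layout$noncog_idx] <- theta[layout$idx_noncog]
  psi <- if (length(layout$idx_res)) theta[layout$idx_res] else numeric(k)
  fc <- if (length(layout$idx_fc)) theta[layout$idx_fc] else 0
  Lam <- cbind(cog = Lc, noncog = Ln)
  Phi <- matrix(c(1, fc, fc, 1), 2, 2)
  Lam %*% Phi %*% t(Lam) + diag(psi, k)
}

#' Fit the factor model to a genetic covariance matrix by DWLS
#'
#' Minimizes the diagonally weighted least squares discrepancy
#' `F = (s - sigma(theta))' D^-1 (s - sigma(theta))` with `s = vech(S)` and
#' `D = diag(V)`; standard errors use the full sandwich
#' `(J'D^-1 J)^-1 J'D^-1 V D^-1 J (J'D^-1 J)^-1` with `J` the Jacobian of the
#' implied vech at the solution, so the off-diagonal sampling covariance in
#' `V` is honoured even though only the diagonal enters the weighting.
#' Multi-start (seeded) optimization; identification is checked by Jacobian
#' column rank at the start values.
#'
#' @param gc A [build_genetic_covariance()] result.
#' @param model A [path_model()].
#' @param n_starts Optimization starts.
#' @param seed Seed for start jitter.
#' @return Object of class `path_model_fit`: `estimates` (named vector),
#'   `se`, `loadings` (k x 2), `residuals`, `factor_cov`, `implied_S`,
#'   `discrepancy`, `srmr`, `converged`.
#' @export
fit_path_model <- function(gc, model, n_starts = 5, seed = 1) {
  stop_if_not(identical(model$traits, gc$traits),
              "model traits must match the genetic covariance traits")
  layout <- pm_layout(model)
  s <- vech(gc$S)
  d <- pmax(diag(gc$V), 1e-12)
  k <- layout$k

  objective <- function(theta) {
    r <- s - vech(pm_implied(theta, model, layout))
    sum(r^2 / d)
  }

  # analytic-flavoured start: project loadings off the first Cog-only trait
  anchor <- setdiff(seq_len(k), layout$noncog_idx)[1]
  va <- max(gc$S[anchor, anchor], 0.01)
  Lc0 <- gc$S[, anchor] / sqrt(va)
  Lc0[anchor] <- sqrt(va)
  res0 <- pmax(diag(gc$S) - Lc0^2, 0.02)
  Ln0 <- sqrt(pmax(diag(gc$S)[layout$noncog_idx] -
                     Lc0[layout$noncog_idx]^2, 0.01))
  base <- c(Lc0, Ln0,
            if (length(layout$idx_res)) res0,
            if (length(layout$idx_fc)) 0)

  J0 <- num_jacobian(function(th) vech(pm_implied(th, model, layout)), base)
  stop_if_not(qr(J0)$rank == layout$n_par,
              "model not identified: implied-moment Jacobian is rank-deficient")

  with_seed(derive_seed(seed, "fitstarts"), {
    best <- NULL
    for (sidx in seq_len(n_starts)) {
      th0 <- if (sidx == 1) base else
        base * stats::runif(length(base), 0.7, 1.3) +
          stats::rnorm(length(base), sd = 0.02)
      opt <- tryCatch(
        stats::optim(th0, objective, method = "BFGS",
                     control = list(maxit = 2000, reltol = 1e-14)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value - 1e-12) best <- opt
    }
    stop_if_not(!is.null(best), "all optimization starts failed")
    theta <- best$par

    # Gauss-Newton polish: quadratic convergence near the optimum, which
    # matters for exact-fit inputs where BFGS stalls around 1e-6.
    fval <- best$value
    for (it in 1:20) {
      r <- s - vech(pm_implied(theta, model, layout))
      Jg <- num_jacobian(function(th) vech(pm_implied(th, model, layout)),
                         theta)
      step <- tryCatch(solve(crossprod(Jg, Jg / d), crossprod(Jg, r / d)),
                       error = function(e) NULL)
      if (is.null(step)) break
      cand <- theta + as.vector(step)
      fc <- objective(cand)
      if (!is.finite(fc) || fc > fval + 1e-12) break
      theta <- cand
      improved <- fval - fc
      fval <- fc
      if (improved < 1e-16) break
    }
    best$value <- fval

    # sign convention: first trait loads positively on Cog, first NonCog
    # trait loads positively on NonCog
    if (theta[layout$idx_cog[1]] < 0)
      theta[layout$idx_cog] <- -theta[layout$idx_cog]
    if (theta[layout$idx_noncog[1]] < 0)
      theta[layout$idx_noncog] <- -theta[layout$idx_noncog]

    J <- num_jacobian(function(th) vech(pm_implied(th, model, layout)), theta)
    W <- 1 / d
    bread <- solve(crossprod(J, J * W))
    meat <- crossprod(J * W, gc$V %*% (J * W))
    cov_theta <- bread %*% meat %*% bread
    se <- sqrt(pmax(diag(cov_theta), 0))

    implied <- pm_implied(theta, model, layout)
    dimnames(implied) <- dimnames(gc$S)
    Ds <- diag(1 / sqrt(pmax(diag(gc$S), 1e-8)))
    resid_cor <- Ds %*% (gc$S - implied) %*% Ds
    srmr <- sqrt(mean(resid_cor[lower.tri(resid_cor, diag = TRUE)]^2))

    nm <- c(paste0("cog_", model$traits),
            paste0("noncog_", model$traits[layout$noncog_idx]),
            if (length(layout$idx_res)) paste0("res_", model$traits),
            if (length(layout$idx_fc)) "factor_cov")
    names(theta) <- nm; names(se) <- nm

    Ln <- numeric(k); Ln[layout$noncog_idx] <- theta[layout$idx_noncog]
    loadings <- cbind(cog = theta[layout$idx_cog], noncog = Ln)
    rownames(loadings) <- model$traits

    structure(list(
      model = model, estimates = theta, se = se, vcov = cov_theta,
      loadings = loadings,
      residuals = if (length(layout$idx_res))
        stats::setNames(theta[layout$idx_res], model$traits)
      else stats::setNames(rep(0, k), model$traits),
      factor_cov = if (length(layout$idx_fc))
        unname(theta[layout$idx_fc]) else 0,
      implied_S = implied, discrepancy = best$value, srmr = srmr,
      converged = best$convergence == 0,
      traits = model$traits, layout = layout),
      class = "path_model_fit")
  })
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("Two-factor genomic SEM fit (DWLS): F = %.6g, SRMR = %.4f%s\n",
              x$discrepancy, x$srmr,
              if (x$converged) "" else " [NOT converged]"))
  print(round(x$loadings, 4))
  if (x$model$factor_cov == "free")
    cat(sprintf("factor covariance = %.4f\n", x$factor_cov))
  invisible(x)
}

#' Per-SNP Cog and NonCog effects (GWAS-by-subtraction step)
#'
#' For each SNP, expands the fitted measurement model with a row for the SNP
#' (variance `2p(1-p)` from the allele frequency, SNP-trait genetic
#' covariances `Z sqrt(2p(1-p)/N)` from the marginal summary statistics) and
#' solves, with measurement parameters held fixed, the two free regressions
#' of the latent factors on the SNP by weighted least squares. This two-stage
#' step has a closed form, so no per-SNP optimization is needed. The
#' returned effects are reported on the standardized-genotype scale with
#' effective sample sizes `1/(A^-1)_kk` where `A = Lambda' diag(N) Lambda`.
#'
#' SNPs with near-zero leverage on a factor (e.g. when the NonCog loadings
#' collapse to zero because the educational-attainment input duplicates the
#' cognitive input) get effects computed through a pseudoinverse, which
#' drives them to zero rather than blowing up.
#'
#' @param gc A [build_genetic_covariance()] result (used for trait order).
#' @param set The harmonized [sumstats_set()] with `snp_info` MAFs.
#' @param model A [path_model()] or an already fitted `path_model_fit`.
#' @return A `snp_effects` data frame: `SNP, A1, A2, beta_cog, se_cog,
#'   z_cog, beta_noncog, se_noncog, z_noncog`, with attribute `n_eff`.
#' @export
gwas_by_subtraction <- function(gc, set, model) {
  fit <- if (inherits(model, "path_model_fit")) model
  else fit_path_model(gc, model)
  stop_if_not(!is.null(set$snp_info) && "maf" %in% names(set$snp_info),
              "set$snp_info with maf is required for the SNP step")
  traits <- fit$traits
  tabs <- set$tables[traits]
  snp <- tabs[[1]]$SNP
  ok <- Reduce(`&`, lapply(tabs, function(tb) tb$SNP %in% snp))
  for (tb in tabs) stop_if_not(identical(tb$SNP, snp),
                               "sumstats must be harmonized (same SNP order)")
  info <- set$snp_info[match(snp, set$snp_info$snp), , drop = FALSE]
  dropped <- sum(is.na(info$maf))
  if (dropped > 0) message(dropped, " SNPs without MAF skipped")
  keep <- !is.na(info$maf)

  Zm <- vapply(tabs, function(tb) tb$Z, numeric(length(snp)))[keep, ,
                                                             drop = FALSE]
  Nv <- vapply(tabs, function(tb) mean(tb$N), numeric(1))
  Lam <- fit$loadings # k x 2
  A <- crossprod(Lam, Lam * Nv) # Lambda' diag(N) Lambda, 2x2
  Ainv <- pinv_sym(A, rtol = 1e-8)
  # standardized-scale effects: beta_std = A^-1 Lambda' (sqrt(N) z)
  P <- Ainv %*% t(Lam * sqrt(Nv)) # 2 x k
  B <- Zm %*% t(P)                # M x 2
  n_eff <- ifelse(diag(Ainv) > 0, 1 / diag(Ainv), Inf)
  se_std <- sqrt(pmax(diag(Ainv), 0))
  zc <- if (se_std[1] > 0) B[, 1] / se_std[1] else rep(0, nrow(B))
  zn <- if (se_std[2] > 0) B[, 2] / se_std[2] else rep(0, nrow(B))

  out <- data.frame(
    SNP = snp[keep], A1 = tabs[[1]]$A1[keep], A2 = tabs[[1]]$A2[keep],
    maf = info$maf[keep],
    beta_cog = B[, 1], se_cog = se_std[1], z_cog = zc,
    beta_noncog = B[, 2], se_noncog = se_std[2], z_noncog = zn,
    stringsAsFactors = FALSE
  )
  attr(out, "n_eff") <- stats::setNames(n_eff, c("cog", "noncog"))
  attr(out, "fit") <- fit
  class(out) <- c("snp_effects", "data.frame")
  out
}

#' Write per-factor association statistics in sumstats form
#'
#' @param effects A [gwas_by_subtraction()] result.
#' @param dir Output directory; writes `cog.sumstats.tsv` and
#'   `noncog.sumstats.tsv` with columns SNP A1 A2 BETA SE Z N_effective.
#' @export
write_snp_effects <- function(effects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_eff <- attr(effects, "n_eff")
  for (f in c("cog", "noncog")) {
    tb <- data.frame(SNP = effects$SNP, A1 = effects$A1, A2 = effects$A2,
                     BETA = effects[[paste0("beta_", f)]],
                     SE = effects[[paste0("se_", f)]],
                     Z = effects[[paste0("z_", f)]],
                     N_effective = round(n_eff[[f]], 2))
    utils::write.table(tb, file.path(dir, paste0(f, ".sumstats.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Factor-level sumstats table from per-SNP effects
#'
#' Converts one factor's column of a [gwas_by_subtraction()] result into the
#' standard `SNP A1 A2 Z N` slice used by LDSC and LDpred.
#'
#' @param effects A `snp_effects` data frame.
#' @param factor `"cog"` or `"noncog"`.
#' @return Data frame with columns SNP, A1, A2, Z, N.
#' @export
factor_sumstats <- function(effects, factor = c("cog", "noncog")) {
  factor <- match.arg(factor)
  n_eff <- attr(effects, "n_eff")[[factor]]
  data.frame(SNP = effects$SNP, A1 = effects$A1, A2 = effects$A2,
             Z = effects[[paste0("z_", factor)]],
             N = if (is.finite(n_eff)) n_eff else 1,
             stringsAsFactors = FALSE)
}

#' Genetic correlation of the latent factors with an external trait
#'
#' Computes bivariate LDSC genetic covariances between the external trait
#' and every indicator trait, then solves the measurement model for the
#' factor-level covariances: `cov(T, trait_i) = lambda_cog_i cov(T, Cog) +
#' lambda_noncog_i cov(T, NonCog)` by least squares over the indicators.
#' Factor variances are fixed at 1, so `rg = cov / sqrt(h2_T)`.
#'
#' @param fit A `path_model_fit`.
#' @param set The harmonized indicator [sumstats_set()].
#' @param external Data frame `SNP A1 A2 Z N` for the external trait,
#'   harmonized to the same SNP universe.
#' @param ld LD scores.
#' @param n_blocks Jackknife blocks.
#' @return Named vector `c(rg_cog, rg_noncog)` with attributes `h2_external`
#'   and `factor_cov` (the solved covariances).
#' @export
factor_rg_with_external <- function(fit, set, external, ld, n_blocks = 50) {
  uh <- ldsc_univariate(external, ld, n_blocks)
  stop_if_not(uh$h2 > 0, "external trait heritability is nonpositive")
  g <- vapply(fit$traits, function(tr) {
    ldsc_bivariate(external, set$tables[[tr]], ld, n_blocks)$gcov
  }, numeric(1))
  Lam <- fit$loadings
  phi <- as.vector(pinv_sym(crossprod(Lam)) %*% crossprod(Lam, g))
  rg <- phi / sqrt(uh$h2)
  out <- stats::setNames(rg, c("rg_cog", "rg_noncog"))
  attr(out, "h2_external") <- uh$h2
  attr(out, "factor_cov") <- stats::setNames(phi, c("cog", "noncog"))
  out
}
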