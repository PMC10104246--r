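# LD score regression: univariate heritability, cross-trait genetic
# covariance, and assembly of the (S, V) matrices consumed by the genomic
# structural equation model. Standard errors come from a delete-one-block
# jackknife over contiguous SNP blocks.

# Weighted regression of y on x with intercept; returns c(intercept, slope).
wls_fit <- function(y, x, w) {
  X <- cbind(1, x)
  XtW <- t(X * w)
  as.vector(solve(XtW %*% X, XtW %*% y))
}

# Core LDSC engine shared by the univariate and bivariate paths: fits the
# full-sample weighted regression and the delete-one-block estimates with
# weights held fixed (two-pass heteroskedasticity weights from a first
# unweighted pass).
ldsc_core <- function(y, l, n_blocks, scale_n, M, weight_n) {
  m <- length(y)
  stop_if_not(m >= 200, "need at least 200 SNPs for LD score regression")
  stop_if_not(stats::sd(l) > 0, "degenerate LD score variance")
  blocks <- split(seq_len(m), cut(seq_len(m), n_blocks, labels = FALSE))

  # pass 1: unweighted slope -> provisional h2/gcov for the weights
  c1 <- wls_fit(y, l, rep(1, m))
  est1 <- min(max(c1[2] * M / scale_n, 0), 1)
  w <- 1 / (1 + weight_n * est1 * l / M)^2

  cf <- wls_fit(y, l, w)
  full <- c(intercept = cf[1], est = cf[2] * M / scale_n)

  loo <- matrix(NA_real_, n_blocks, 2)
  for (b in seq_len(n_blocks)) {
    idx <- setdiff(seq_len(m), blocks[[b]])
    cb <- wls_fit(y[idx], l[idx], w[idx])
    loo[b, ] <- c(cb[1], cb[2] * M / scale_n)
  }
  pseudo_mean <- colMeans(loo)
  se <- sqrt((n_blocks - 1) / n_blocks *
               colSums(sweep(loo, 2, pseudo_mean, "-")^2))
  list(full = full, loo = loo, se = c(intercept_se = se[1], est_se = se[2]),
       weights = w, blocks = blocks)
}

#' Univariate LD score regression
#'
#' Regresses per-SNP chi-square statistics on LD scores under the model
#' `E[chi2_j] = intercept + N h2 l_j / M`, with two-pass heteroskedasticity
#' weights `1 / (1 + N h2 l/M)^2` and delete-one-block jackknife standard
#' errors over `n_blocks` contiguous blocks. The slope is rescaled by `M/N`
#' to the heritability scale.
#'
#' @param trait Data frame slice with columns `SNP, A1, A2, Z, N`.
#' @param ld LD-score table with columns `SNP` and `L2` (as written by
#'   [write_ld_scores()]), or an `ld_reference`.
#' @param n_blocks Number of jackknife blocks.
#' @param M LD-score denominator (defaults to the number of merged SNPs).
#' @return Object of class `ldsc_estimate` with `h2`, `h2_se`, `intercept`,
#'   `intercept_se`, `mean_chi2`, `n_blocks`, and the per-block leave-one-out
#'   estimates in `jackknife`.
#' @export
ldsc_univariate <- function(trait, ld, n_blocks = 50, M = NULL) {
  tab <- merge_ld(trait, ld)
  M <- M %||% nrow(tab)
  N <- mean(tab$N)
  core <- ldsc_core(tab$Z^2, tab$L2, n_blocks, scale_n = N, M = M,
                    weight_n = N)
  structure(list(h2 = core$full[["est"]], h2_se = core$se[["est_se"]],
                 intercept = core$full[["intercept"]],
                 intercept_se = core$se[["intercept_se"]],
                 mean_chi2 = mean(tab$Z^2), n_blocks = n_blocks,
                 jackknife = core$loo, weights = core$weights,
                 blocks = core$blocks, y = tab$Z^2, l = tab$L2,
                 n = N, M = M, kind = "h2"),
            class = "ldsc_estimate")
}

#' Cross-trait (bivariate) LD score regression
#'
#' Regresses `Z_A * Z_B` on LD scores: `E[Z_A Z_B] = intercept +
#' sqrt(N_A N_B) rho_g l_j / M`. With non-overlapping cohorts the intercept
#' is approximately zero; with complete overlap it approaches the phenotypic
#' correlation. The genetic correlation `rho_g / sqrt(h2_A h2_B)` is
#' computed from internally estimated univariate heritabilities and is
#' flagged undefined when either is nonpositive.
#'
#' @param trait_a,trait_b Harmonized sumstats slices (`SNP A1 A2 Z N`).
#' @inheritParams ldsc_univariate
#' @return Object of class `ldsc_estimate` with `gcov`, `gcov_se`,
#'   `intercept`, `rg` (possibly `NA` with `rg_defined = FALSE`).
#' @export
ldsc_bivariate <- function(trait_a, trait_b, ld, n_blocks = 50, M = NULL) {
  ta <- merge_ld(trait_a, ld)
  tb <- merge_ld(trait_b, ld)
  stop_if_not(identical(ta$SNP, tb$SNP),
              "traits must be harmonized to the same SNP universe")
  M <- M %||% nrow(ta)
  Na <- mean(ta$N); Nb <- mean(tb$N)
  ua <- ldsc_univariate(trait_a, ld, n_blocks, M)
  ub <- ldsc_univariate(trait_b, ld, n_blocks, M)
  core <- ldsc_core(ta$Z * tb$Z, ta$L2, n_blocks, scale_n = sqrt(Na * Nb),
                    M = M, weight_n = sqrt(Na * Nb))
  gcov <- core$full[["est"]]
  defined <- ua$h2 > 0 && ub$h2 > 0
  rg <- if (defined) gcov / sqrt(ua$h2 * ub$h2) else NA_real_
  structure(list(gcov = gcov, gcov_se = core$se[["est_se"]],
                 intercept = core$full[["intercept"]],
                 intercept_se = core$se[["intercept_se"]],
                 rg = rg, rg_defined = defined,
                 h2_a = ua$h2, h2_b = ub$h2,
                 mean_z1z2 = mean(ta$Z * tb$Z),
                 n_blocks = n_blocks, jackknife = core$loo,
                 weights = core$weights, blocks = core$blocks,
                 y = ta$Z * tb$Z, l = ta$L2, scale_n = sqrt(Na * Nb),
                 M = M, kind = "gcov"),
            class = "ldsc_estimate")
}

#' @export
print.ldsc_estimate <- function(x, ...) {
  if (x$kind == "h2") {
    cat(sprintf("LDSC h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), mean chi2 = %.3f\n",
                x$h2, x$h2_se, x$intercept, x$intercept_se, x$mean_chi2))
  } else {
    cat(sprintf("LDSC genetic covariance = %.4f (SE %.4f), intercept = %.4f, rg = %s\n",
                x$gcov, x$gcov_se, x$intercept,
                if (x$rg_defined) sprintf("%.3f", x$rg) else "undefined"))
  }
  invisible(x)
}

merge_ld <- function(trait, ld) {
  ldt <- if (inherits(ld, "ld_reference")) {
    data.frame(SNP = ld$snp_info$snp, L2 = ld$ldscores,
               stringsAsFactors = FALSE)
  } else {
    stop_if_not(all(c("SNP", "L2") %in% names(ld)),
                "ld table needs SNP and L2 columns")
    ld[, c("SNP", "L2")]
  }
  tab <- merge(trait, ldt, by = "SNP", sort = FALSE)
  stop_if_not(nrow(tab) == nrow(trait),
              "LD scores missing for some SNPs")
  tab[order(match(tab$SNP, trait$SNP)), , drop = FALSE]
}

#' Assemble the genetic covariance matrix S and its sampling covariance V
#'
#' Runs univariate LDSC for every trait (diagonal of S) and bivariate LDSC
#' for every pair (off-diagonals), then estimates the sampling covariance of
#' `vech(S)` by a cross-entry delete-one-block jackknife using the same
#' contiguous blocks for every entry. S is smoothed to the nearest positive
#' semi-definite matrix by eigenvalue clipping at 1e-6 when needed (flagged),
#' and likewise V.
#'
#' @param set A harmonized [sumstats_set()] with >= 2 traits.
#' @param ld LD scores (`ld_reference` or CHR/SNP/BP/L2 table).
#' @param n_blocks Jackknife blocks.
#' @param M LD-score denominator (defaults to the SNP count).
#' @return Object of class `genetic_covariance`: `S`, `V`, `traits`,
#'   `smoothed_S`, `smoothed_V`, `univariate` (list of ldsc_estimates).
#' @export
build_genetic_covariance <- function(set, ld, n_blocks = 50, M = NULL) {
  k <- length(set$traits)
  stop_if_not(k >= 2, "need at least 2 traits")
  traits <- set$traits
  uni <- stats::setNames(lapply(traits, function(tr) {
    ldsc_univariate(set$tables[[tr]], ld, n_blocks, M)
  }), traits)
  for (tr in traits) {
    stop_if_not(is.finite(uni[[tr]]$h2),
                sprintf("univariate LDSC failed for trait %s", tr))
  }

  S <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  nb <- n_blocks
  loo_entries <- list() # per vech entry: per-block leave-one-out estimates
  vn <- vech_names(traits)
  pos <- 0
  for (j in seq_len(k)) {
    for (i in j:k) {
      pos <- pos + 1
      if (i == j) {
        S[i, j] <- uni[[i]]$h2
        loo_entries[[pos]] <- uni[[i]]$jackknife[, 2]
      } else {
        bi <- ldsc_bivariate(set$tables[[traits[i]]], set$tables[[traits[j]]],
                             ld, n_blocks, M)
        S[i, j] <- S[j, i] <- bi$gcov
        loo_entries[[pos]] <- bi$jackknife[, 2]
      }
    }
  }
  L <- do.call(cbind, loo_entries) # n_blocks x n_vech
  colnames(L) <- vn
  center <- colMeans(L)
  V <- (nb - 1) / nb * crossprod(sweep(L, 2, center, "-"))

  Ssm <- psd_clip(S, 1e-6)
  Vsm <- psd_clip(V, 1e-6)
  dimnames(Ssm) <- list(traits, traits)
  dimnames(Vsm) <- list(vn, vn)
  structure(list(S = unname_attr(Ssm), V = unname_attr(Vsm),
                 traits = traits,
                 smoothed_S = attr(Ssm, "smoothed"),
                 smoothed_V = attr(Vsm, "smoothed"),
                 vech_names = vn, univariate = uni,
                 n_blocks = nb, M = uni[[1]]$M),
            class = "genetic_covariance")
}

unname_attr <- function(x) { attr(x, "smoothed") <- NULL; x }

#' @export
print.genetic_covariance <- function(x, ...) {
  cat(sprintf("Genetic covariance: %d traits, %d jackknife blocks%s\n",
              length(x$traits), x$n_blocks,
              if (x$smoothed_S) " [S smoothed]" else ""))
  print(round(x$S, 4))
  invisible(x)
}
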