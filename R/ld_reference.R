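#' Build a block-diagonal LD reference
#'
#' Constructs the haplotype correlation structure used by every downstream
#' stage: `n_blocks` contiguous blocks with zero correlation across blocks.
#' Within a block, haplotypes are sampled by Gaussian-copula thresholding of
#' a latent AR(1) process with correlation `rho_b^|i-k|` between SNPs `i`
#' and `k`; the AR(1) parameter is graded across blocks from 0 up to the
#' configured `ld_decay`, emulating variable recombination intensity along
#' the genome (a single-block reference uses `ld_decay` directly). Because
#' thresholding attenuates correlation, the reference stores
#' two matrices per block: the latent Gaussian matrix (`R_latent`, used for
#' sampling) and the exact allele-scale haplotype correlation it implies
#' (`R`, computed analytically via the Plackett identity
#' \eqn{\partial \Phi_2 / \partial \rho = \phi_2} with Gauss-Legendre
#' quadrature). LD scores are computed exactly from the allele-scale matrix
#' as \eqn{\ell_j = \sum_k r_{jk}^2} within the block (self-term included,
#' so \eqn{\ell_j \ge 1}); these are the scores that describe the realized
#' genotype LD and feed LD score regression and LDpred.
#'
#' Per-SNP minor-allele frequencies are drawn uniformly from the configured
#' range, seeded from the configuration, and stored with the SNP metadata so
#' that all cohorts simulate from identical frequencies.
#'
#' @param config A [sim_config()].
#' @return An object of class `ld_reference`: block index list, per-block
#'   allele-scale correlation matrices `R`, latent matrices `R_latent` and
#'   their Cholesky factors, exact LD scores, and a `snp_info` data frame
#'   (`snp`, `block`, `bp`, `a1`, `a2`, `maf`).
#' @export
build_ld_reference <- function(config) {
  M <- config$n_snps
  B <- config$n_blocks
  rho <- config$ld_decay
  stop_if_not(rho < 1, "ld_decay (rho) must be < 1")
  bs <- M %/% B
  blocks <- split(seq_len(M), rep(seq_len(B), each = bs))
  names(blocks) <- NULL

  # LD strength is graded across blocks from 0 (no LD) up to ld_decay,
  # emulating variable recombination intensity along the genome; the no-LD
  # blocks anchor l = 1 and give the LD-score regression its leverage.
  # A single-block reference uses ld_decay itself.
  rho_b <- if (B == 1) rho else rho * (seq_len(B) - 1) / (B - 1)
  dist <- abs(outer(seq_len(bs), seq_len(bs), "-"))

  maf <- with_seed(derive_seed(config$seed, "ld"),
                   stats::runif(M, config$maf_range[1], config$maf_range[2]))

  R <- vector("list", B)
  R_latent <- vector("list", B)
  chol_list <- vector("list", B)
  ldscores <- numeric(M)
  for (b in seq_len(B)) {
    idx <- blocks[[b]]
    Rl <- rho_b[b]^dist
    R_latent[[b]] <- Rl
    chol_list[[b]] <- chol(Rl)
    Rg <- allele_scale_correlation(Rl, maf[idx])
    R[[b]] <- Rg
    ldscores[idx] <- rowSums(Rg^2)
  }

  snp_info <- data.frame(
    snp = sprintf("rs%05d", seq_len(M)),
    block = rep(seq_len(B), each = bs),
    bp = seq_len(M),
    a1 = "A", a2 = "G",
    maf = maf,
    stringsAsFactors = FALSE
  )
  structure(list(blocks = blocks, R = R,
                 R_latent = R_latent,
                 chol = chol_list,
                 ldscores = ldscores, snp_info = snp_info,
                 rho = rho, rho_blocks = rho_b),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("LD reference: %d SNPs in %d blocks (latent AR(1) rho = %.2f)\n",
              nrow(x$snp_info), length(x$blocks), x$rho))
  cat(sprintf("  mean allele-scale LD score %.3f (range %.3f-%.3f)\n",
              mean(x$ldscores), min(x$ldscores), max(x$ldscores)))
  invisible(x)
}

# Gauss-Legendre nodes and weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

#' Exact allele-scale correlation implied by Gaussian-copula thresholding
#'
#' For binary allele indicators generated as `1(Z < qnorm(maf))` with latent
#' correlation matrix `R_latent`, the allele covariance between SNPs j and k
#' is \eqn{\Phi_2(t_j, t_k; \rho_{jk}) - p_j p_k}, evaluated through the
#' Plackett identity as \eqn{\int_0^{\rho} \phi_2(t_j, t_k; r)\, dr} with
#' fixed Gauss-Legendre quadrature (machine-level accuracy for the smooth
#' integrand).
#'
#' @param R_latent Latent Gaussian correlation matrix.
#' @param maf Allele frequencies (thresholds `qnorm(maf)`).
#' @param n_nodes Quadrature nodes.
#' @return The allele-scale correlation matrix (unit diagonal).
#' @export
allele_scale_correlation <- function(R_latent, maf, n_nodes = 24) {
  bs <- length(maf)
  stop_if_not(nrow(R_latent) == bs, "R_latent does not match maf length")
  t_ <- stats::qnorm(maf)
  gl <- gauss_legendre(n_nodes)
  u <- (gl$nodes + 1) / 2
  w <- gl$weights / 2
  T1 <- matrix(t_, bs, bs)
  T2 <- t(T1)
  covg <- matrix(0, bs, bs)
  for (m in seq_along(u)) {
    Rm <- R_latent * u[m]
    om <- 1 - Rm^2
    dens <- exp(-(T1^2 - 2 * Rm * T1 * T2 + T2^2) / (2 * om)) /
      (2 * pi * sqrt(om))
    covg <- covg + w[m] * R_latent * dens
  }
  sdv <- sqrt(maf * (1 - maf))
  Rg <- covg / tcrossprod(sdv)
  diag(Rg) <- 1
  Rg
}

# Draw n_hap haplotypes (0/1 alleles, rows = haplotypes) under the reference
# LD via Gaussian-copula thresholding: latent MVN per block, allele "a1"
# carried where the latent value falls below qnorm(maf).
sample_haplotypes <- function(n_hap, ld) {
  maf <- ld$snp_info$maf
  M <- length(maf)
  H <- matrix(0L, n_hap, M)
  thr <- stats::qnorm(maf)
  for (b in seq_along(ld$blocks)) {
    idx <- ld$blocks[[b]]
    Z <- matrix(stats::rnorm(n_hap * length(idx)), n_hap) %*% ld$chol[[b]]
    # column-major rep makes the threshold constant within each column
    H[, idx] <- (Z < rep(thr[idx], each = n_hap)) + 0L
  }
  H
}
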