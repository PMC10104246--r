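#' Simulate multivariate twin-pair phenotypes from ACE covariance matrices
#'
#' The engine behind all twin simulations. Given additive-genetic (`A`),
#' shared-environment (`C`) and nonshared-environment (`E`) covariance
#' matrices over `p` traits, twin-pair vectors are drawn from the implied
#' multivariate normal: cross-twin genetic correlation 1 for MZ and 0.5 for
#' DZ pairs, shared environment correlated 1 in both, nonshared environment
#' uncorrelated.
#'
#' @param n_mz,n_dz Numbers of MZ and DZ pairs.
#' @param A,C,E Symmetric p x p covariance matrices (or scalars for a single
#'   trait).
#' @param trait_names Trait labels (length p).
#' @param seed RNG seed.
#' @param age,rater Labels attached to every row of the output.
#' @param standardize Standardize values within trait before returning
#'   (default TRUE; the generating matrices are then interpreted as
#'   correlation-scale components).
#' @return A `twin_cohort` data frame in long form: `family_id`, `zygosity`,
#'   `twin` (1 or 2), `age`, `rater`, `trait`, `value`.
#' @export
simulate_twin_multivariate <- function(n_mz, n_dz, A, C, E,
                                       trait_names = NULL, seed = 1,
                                       age = NA, rater = "none",
                                       standardize = TRUE) {
  A <- as.matrix(A); C <- as.matrix(C); E <- as.matrix(E)
  p <- nrow(A)
  trait_names <- trait_names %||% paste0("trait", seq_len(p))
  T_ <- A + C + E
  sigma <- function(rA) {
    ct <- rA * A + C
    rbind(cbind(T_, ct), cbind(ct, T_))
  }
  draw <- function(n, S) {
    if (n == 0) return(matrix(numeric(0), 0, 2 * p))
    L <- chol(psd_clip(S, floor = 1e-10))
    matrix(stats::rnorm(n * 2 * p), n) %*% L
  }
  with_seed(seed, {
    Ymz <- draw(n_mz, sigma(1))
    Ydz <- draw(n_dz, sigma(0.5))
    n <- n_mz + n_dz
    fam <- sprintf("F%05d", seq_len(n))
    zyg <- c(rep("MZ", n_mz), rep("DZ", n_dz))
    Y <- rbind(Ymz, Ydz) # columns 1..p = twin 1, p+1..2p = twin 2
    out <- data.frame(
      family_id = rep(fam, times = 2 * p),
      zygosity = rep(zyg, times = 2 * p),
      twin = rep(rep(c(1L, 2L), each = p), each = n),
      age = age, rater = rater,
      trait = rep(rep(trait_names, 2), each = n),
      value = as.vector(Y),
      stringsAsFactors = FALSE
    )
    if (standardize) {
      out$value <- stats::ave(out$value, out$trait, FUN = zstd)
    }
    class(out) <- c("twin_cohort", "data.frame")
    out
  })
}

#' Simulate the full twin phenotype cohort
#'
#' For every (domain, rater, age) cell of the ACE configuration, draws a
#' latent factor per twin with the cell's latent a2/c2/e2 decomposition and
#' builds indicators as `loading * latent + residual`, where each
#' indicator's residual variance has its own A/C/E split. Values are
#' standardized within (age, rater, trait).
#'
#' Indicator-level implied components (latent variance fixed at 1, equal
#' loadings f): `A_ind = a2 * f f' + diag(res_a2 * (1 - f^2))`, and likewise
#' for C and E, so the data are exactly the common-pathway model's implied
#' distribution.
#'
#' @param config A [sim_config()]; uses `ace_config`, `n_families`,
#'   `prop_mz` and the master seed.
#' @return A `twin_cohort` data frame in long form; indicator traits are
#'   named `<domain>.<k>`.
#' @export
simulate_twin_phenotypes <- function(config) {
  ac <- config$ace_config
  stop_if_not(all(abs(ac$a2 + ac$c2 + ac$e2 - 1) < 1e-8),
              "a2 + c2 + e2 must equal 1 in every ace_config row")
  n_mz <- round(config$prop_mz * config$n_families)
  n_dz <- config$n_families - n_mz
  base_seed <- derive_seed(config$seed, "twins")
  out <- vector("list", nrow(ac))
  for (i in seq_len(nrow(ac))) {
    row <- ac[i, ]
    k <- row$n_indicators
    f <- rep(row$loading, k)
    res <- 1 - f^2
    ACEi <- function(lat, spl) lat * tcrossprod(f) + diag(spl * res, k)
    A <- ACEi(row$a2, row$res_a2)
    C <- ACEi(row$c2, row$res_c2)
    E <- ACEi(row$e2, row$res_e2)
    out[[i]] <- simulate_twin_multivariate(
      n_mz, n_dz, A, C, E,
      trait_names = paste(row$domain, seq_len(k), sep = "."),
      seed = (base_seed + i * 131) %% 2147483629,
      age = row$age, rater = row$rater)
  }
  res <- do.call(rbind, out)
  class(res) <- c("twin_cohort", "data.frame")
  res
}

#' ACE component matrices for a trivariate Cholesky generating model
#'
#' Builds 3 x 3 A, C and E matrices for an ordered triple
#' (cognitive, noncognitive, achievement) in which achievement's genetic
#' variance decomposes into a component shared with cognitive skills
#' (`share_cog`), a component shared with noncognitive skills beyond
#' cognitive (`share_noncog`), and an achievement-specific component
#' (`share_specific`), as squared standardized paths of a genetic Cholesky.
#'
#' @param share_cog,share_noncog,share_specific Target genetic variance
#'   shares of achievement (sum = achievement heritability).
#' @param h2_cog,h2_noncog Heritabilities of the first two traits.
#' @param c2 Length-3 shared-environment variances per trait.
#' @param rg_cog_noncog Genetic correlation between cognitive and
#'   noncognitive traits.
#' @return List with matrices `A`, `C`, `E` and the generating `shares`.
#' @export
trivariate_ace_matrices <- function(share_cog = 0.30, share_noncog = 0.12,
                                    share_specific = 0.20,
                                    h2_cog = 0.50, h2_noncog = 0.55,
                                    c2 = c(0.20, 0.15, 0.15),
                                    rg_cog_noncog = 0.30) {
  h2_ach <- share_cog + share_noncog + share_specific
  stop_if_not(h2_ach <= 1, "achievement shares must sum to at most 1")
  # Genetic Cholesky X: achievement paths fixed by the target shares.
  x11 <- sqrt(h2_cog)
  x21 <- rg_cog_noncog * sqrt(h2_cog * h2_noncog) / x11
  x22 <- sqrt(h2_noncog - x21^2)
  X <- rbind(c(x11, 0, 0),
             c(x21, x22, 0),
             c(sqrt(share_cog), sqrt(share_noncog), sqrt(share_specific)))
  A <- tcrossprod(X)
  # Modest shared-environment overlap; diagonal fixed at c2.
  Y <- rbind(c(sqrt(c2[1]), 0, 0),
             c(0.5 * sqrt(c2[1] * c2[2]) / sqrt(c2[1]),
               NA, 0),
             c(0.4 * sqrt(c2[1] * c2[3]) / sqrt(c2[1]), 0.1, NA))
  Y[2, 2] <- sqrt(c2[2] - Y[2, 1]^2)
  Y[3, 3] <- sqrt(max(c2[3] - Y[3, 1]^2 - Y[3, 2]^2, 1e-6))
  C <- tcrossprod(Y)
  e2 <- 1 - diag(A) - diag(C)
  stop_if_not(all(e2 > 0.02), "variance budget exceeded: A + C >= 1 for a trait")
  # Small nonshared-environment overlap mirroring rater/measurement links.
  Z <- diag(sqrt(e2))
  Z[3, 1] <- 0.1 * sqrt(e2[1]); Z[3, 3] <- sqrt(max(e2[3] - Z[3, 1]^2, 1e-6))
  E <- tcrossprod(Z)
  T_ <- A + C + E
  # Rescale to unit total variance per trait (keeps shares exact ratios).
  D <- diag(1 / sqrt(diag(T_)))
  list(A = D %*% A %*% D, C = D %*% C %*% D, E = D %*% E %*% D,
       shares = c(share_cog = share_cog, share_noncog = share_noncog,
                  share_specific = share_specific) / diag(T_)[3])
}
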