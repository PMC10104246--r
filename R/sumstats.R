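#' Construct a harmonized summary-statistics set
#'
#' @param tables Named list of per-trait data frames with columns
#'   `SNP`, `A1`, `A2`, `Z`, `N`.
#' @param snp_info Optional SNP metadata (needs `snp` and `maf` columns) used
#'   by the per-SNP factor-effect step.
#' @param trait_meta Optional per-trait metadata data frame.
#' @return An object of class `sumstats_set`.
#' @export
sumstats_set <- function(tables, snp_info = NULL, trait_meta = NULL) {
  stop_if_not(length(tables) >= 1 && !is.null(names(tables)),
              "tables must be a named list")
  need <- c("SNP", "A1", "A2", "Z", "N")
  for (nm in names(tables)) {
    stop_if_not(all(need %in% names(tables[[nm]])),
                sprintf("trait '%s' lacks required columns SNP A1 A2 Z N", nm))
    stop_if_not(all(is.finite(tables[[nm]]$Z)),
                sprintf("trait '%s' has non-finite Z statistics", nm))
  }
  structure(list(tables = tables, snp_info = snp_info,
                 trait_meta = trait_meta,
                 traits = names(tables)),
            class = "sumstats_set")
}

#' @export
print.sumstats_set <- function(x, ...) {
  cat(sprintf("Summary-statistics set: %d traits (%s), %d SNPs\n",
              length(x$traits), paste(x$traits, collapse = ", "),
              nrow(x$tables[[1]])))
  invisible(x)
}

#' Simulate discovery-cohort GWAS summary statistics
#'
#' For each of the architecture's traits, simulates an independent unrelated
#' discovery cohort of `n_discovery` individuals under the LD reference,
#' builds the phenotype as
#' `cog_loading * G_cog + noncog_loading * G_noncog + residual genetic +
#' environmental noise`, and computes marginal per-SNP association
#' z-statistics. True per-SNP effects are shared with the family panel (see
#' [true_effects()]). With `overlap > 0` a fraction of each cohort is shared
#' across traits and trait-specific environments are correlated `env_cor` on
#' the shared individuals, which induces nonzero cross-trait LDSC intercepts.
#'
#' @param config A [sim_config()].
#' @param ld The matching [build_ld_reference()].
#' @param overlap Fraction of the cohort shared between traits (defaults to
#'   the configuration's `sample_overlap`).
#' @param env_cor Environmental correlation between traits among shared
#'   individuals.
#' @return A [sumstats_set()] whose `trait_meta` records the generating
#'   loadings and heritabilities.
#' @export
simulate_discovery_sumstats <- function(config, ld,
                                        overlap = config$sample_overlap,
                                        env_cor = 0) {
  arch <- config$architecture
  N <- config$n_discovery
  M <- config$n_snps
  if (N < 500)
    warning("n_discovery < 500: per-SNP z-statistics will be unstable")
  eff <- true_effects(config)
  n_shared <- round(overlap * N)

  with_seed(derive_seed(config$seed, "sumstats"), {
    shared <- NULL
    if (n_shared > 0) {
      Xs <- sample_haplotypes(2L * n_shared, ld)
      Gsh <- Xs[seq_len(n_shared), , drop = FALSE] +
        Xs[n_shared + seq_len(n_shared), , drop = FALSE]
      shared <- list(X = col_standardize(Gsh),
                     e = stats::rnorm(n_shared))
    }
    tables <- list()
    for (i in seq_along(arch$trait_names)) {
      tr <- arch$trait_names[i]
      n_unique <- N - n_shared
      Xu <- NULL
      if (n_unique > 0) {
        H <- sample_haplotypes(2L * n_unique, ld)
        Gu <- H[seq_len(n_unique), , drop = FALSE] +
          H[n_unique + seq_len(n_unique), , drop = FALSE]
        Xu <- col_standardize(Gu)
        rm(H, Gu)
      }
      X <- if (is.null(shared)) Xu else rbind(shared$X, Xu)
      rm(Xu)

      gc_ <- zstd(as.vector(X %*% eff$u_cog))
      gn <- zstd(as.vector(X %*% eff$u_noncog))
      gr <- zstd(as.vector(X %*% eff$u_resid[, tr]))
      e <- stats::rnorm(N)
      if (!is.null(shared) && env_cor > 0) {
        e[seq_len(n_shared)] <- sqrt(env_cor) * shared$e +
          sqrt(1 - env_cor) * e[seq_len(n_shared)]
      }
      h2 <- arch$h2[[tr]]
      y <- arch$cog_loadings[[tr]] * gc_ + arch$noncog_loadings[[tr]] * gn +
        sqrt(arch$residual_h2[[tr]]) * gr + sqrt(max(0, 1 - h2)) * zstd(e)
      y <- zstd(y)

      r <- as.vector(crossprod(X, y)) / (N - 1)
      r <- pmin(pmax(r, -0.999999), 0.999999)
      z <- r * sqrt((N - 2) / (1 - r^2))
      tables[[tr]] <- data.frame(SNP = ld$snp_info$snp,
                                 A1 = ld$snp_info$a1, A2 = ld$snp_info$a2,
                                 Z = z, N = N, stringsAsFactors = FALSE)
      rm(X); gc(FALSE)
    }
    trait_meta <- data.frame(trait = arch$trait_names,
                             cog_loading = as.numeric(arch$cog_loadings),
                             noncog_loading = as.numeric(arch$noncog_loadings),
                             residual_h2 = as.numeric(arch$residual_h2),
                             h2 = as.numeric(arch$h2),
                             n = N, stringsAsFactors = FALSE)
    sumstats_set(tables, snp_info = ld$snp_info, trait_meta = trait_meta)
  })
}

ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize raw per-trait summary statistics
#'
#' Intersects SNP sets across traits, aligns alleles to the first trait's
#' orientation (flipping the sign of Z when A1/A2 are swapped), and drops
#' strand-ambiguous (A/T, C/G) SNPs and allele mismatches. Drop counts are
#' recorded in the returned object's `log`.
#'
#' @param tables Named list of data frames with columns `SNP, A1, A2, Z, N`.
#' @param snp_info Optional SNP metadata passed through to the result.
#' @return A [sumstats_set()] restricted to the harmonized SNP universe, with
#'   attribute-like `log` entry describing drops.
#' @export
harmonize_sumstats <- function(tables, snp_info = NULL) {
  stop_if_not(length(tables) >= 1, "need at least one trait table")
  ref <- tables[[1]]
  drop_log <- list()

  amb <- ambiguous_pair(ref$A1, ref$A2)
  drop_log$ambiguous_reference <- sum(amb)
  ref <- ref[!amb, , drop = FALSE]

  universe <- ref$SNP
  for (nm in names(tables)[-1]) {
    universe <- intersect(universe, tables[[nm]]$SNP)
  }
  stop_if_not(length(universe) > 0, "empty SNP intersection across traits")

  ref <- ref[match(universe, ref$SNP), , drop = FALSE]
  out <- list()
  out[[names(tables)[1]]] <- ref
  n_flip <- 0L; n_mismatch <- 0L
  keep <- rep(TRUE, length(universe))
  for (nm in names(tables)[-1]) {
    tb <- tables[[nm]]
    tb <- tb[match(universe, tb$SNP), , drop = FALSE]
    same <- tb$A1 == ref$A1 & tb$A2 == ref$A2
    swap <- tb$A1 == ref$A2 & tb$A2 == ref$A1
    tb$Z[swap] <- -tb$Z[swap]
    tb$A1[swap] <- ref$A1[swap]; tb$A2[swap] <- ref$A2[swap]
    n_flip <- n_flip + sum(swap)
    bad <- !(same | swap)
    n_mismatch <- n_mismatch + sum(bad)
    keep <- keep & !bad
    out[[nm]] <- tb
  }
  if (!all(keep)) out <- lapply(out, function(tb) tb[keep, , drop = FALSE])
  drop_log$allele_mismatch <- n_mismatch
  drop_log$flipped <- n_flip
  if (!is.null(snp_info)) {
    snp_info <- snp_info[match(out[[1]]$SNP, snp_info$snp), , drop = FALSE]
  }
  res <- sumstats_set(out, snp_info = snp_info)
  res$log <- drop_log
  res
}
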