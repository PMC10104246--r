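#' LDpred weights under the infinitesimal prior
#'
#' Computes LD-aware shrinkage weights assuming every SNP contributes to the
#' trait: per LD block, `w = (R + lambda I)^-1 beta_std` with
#' `lambda = M / (N h2)` and `beta_std = Z / sqrt(N)` the marginal effects on
#' the standardized-genotype scale. Blocks are processed independently
#' (LDpred windows coincide with the simulator's LD blocks). With identity
#' LD this reduces to the closed form `beta_std / (1 + lambda)`.
#'
#' @param sumstats Data frame slice `SNP A1 A2 Z N` aligned to the
#'   reference's SNP universe.
#' @param ld An [build_ld_reference()] reference.
#' @param h2 Trait heritability plugged into the shrinkage (must be in
#'   (0, 1]); by convention the package's own LDSC estimate.
#' @param n Sample size (defaults to the sumstats' mean N).
#' @return A `pgs_weights` data frame `SNP, A1, WEIGHT` (standardized-genotype
#'   scale) with provenance attributes `h2`, `n`, `lambda`.
#' @export
ldpred_inf_weights <- function(sumstats, ld, h2, n = NULL) {
  stop_if_not(h2 > 0 && h2 <= 1, "h2 must lie in (0, 1]")
  idx <- match(ld$snp_info$snp, sumstats$SNP)
  stop_if_not(!anyNA(idx), "sumstats missing SNPs present in the LD reference")
  ss <- sumstats[idx, , drop = FALSE]
  n <- n %||% mean(ss$N)
  M <- nrow(ld$snp_info)
  lambda <- M / (n * h2)
  beta_std <- ss$Z / sqrt(ss$N)
  w <- numeric(M)
  for (b in seq_along(ld$blocks)) {
    bi <- ld$blocks[[b]]
    R <- ld$R[[b]]
    w[bi] <- solve(R + diag(lambda, nrow(R)), beta_std[bi])
  }
  out <- data.frame(SNP = ld$snp_info$snp, A1 = ss$A1, WEIGHT = w,
                    stringsAsFactors = FALSE)
  attr(out, "h2") <- h2; attr(out, "n") <- n; attr(out, "lambda") <- lambda
  class(out) <- c("pgs_weights", "data.frame")
  out
}

#' Score individuals with PGS weights
#'
#' Computes per-individual polygenic scores as the weighted sum of
#' standardized genotypes (per-SNP standardization uses founder means and
#' SDs, matching the standardized-genotype scale of the weights). Alleles
#' are aligned to the panel: a weight whose A1 matches the panel's A2 has
#' its sign flipped; other mismatches are dropped and counted. Scores are
#' standardized to mean 0, variance 1 among the founders, so MZ co-twins
#' share identical scores by construction.
#'
#' @param panel A [simulate_genotype_panel()] result.
#' @param weights A `pgs_weights` data frame (or list of them, one per
#'   score).
#' @param names Score column name(s) in the output.
#' @return A `scored_cohort` data frame: `id`, `family_id`, `role`,
#'   `zygosity`, plus one column per score.
#' @export
score_individuals <- function(panel, weights, names = "pgs") {
  if (inherits(weights, "pgs_weights")) weights <- list(weights)
  stop_if_not(length(weights) == length(names),
              "one name per weight set required")
  info <- panel$snp_info
  founders <- panel$meta$role %in% c("parent1", "parent2")
  mu <- colMeans(panel$geno[founders, , drop = FALSE])
  sdv <- sqrt(pmax(colMeans(panel$geno[founders, , drop = FALSE]^2) - mu^2,
                   1e-12))
  out <- panel$meta[, c("id", "family_id", "role", "zygosity")]
  for (i in seq_along(weights)) {
    w <- weights[[i]]
    m <- match(info$snp, w$SNP)
    stop_if_not(!all(is.na(m)), "no overlapping SNPs between panel and weights")
    wv <- numeric(nrow(info))
    ok <- !is.na(m)
    a1 <- w$A1[m[ok]]
    sign <- ifelse(a1 == info$a1[ok], 1,
                   ifelse(a1 == info$a2[ok], -1, NA))
    if (anyNA(sign)) {
      message(sum(is.na(sign)), " SNPs dropped for allele mismatch")
      sign[is.na(sign)] <- 0
    }
    wv[ok] <- w$WEIGHT[m[ok]] * sign
    raw <- as.vector(sweep(sweep(panel$geno, 2, mu, "-"), 2, sdv, "/") %*% wv)
    s <- stats::sd(raw[founders])
    out[[names[i]]] <- if (s > 0) (raw - mean(raw[founders])) / s else raw
  }
  class(out) <- c("scored_cohort", "data.frame")
  out
}

#' Build a scored analysis cohort from panel, phenotypes and PGS columns
#'
#' Joins per-individual scores onto the long phenotype table.
#'
#' @param scores A [score_individuals()] result (or any data frame with an
#'   `id` column and score columns).
#' @param phenotypes A `cohort_phenotypes` data frame.
#' @return The phenotype table with score columns appended.
#' @export
scored_cohort <- function(scores, phenotypes) {
  sc_cols <- setdiff(names(scores), c("id", "family_id", "role", "zygosity"))
  m <- match(phenotypes$id, scores$id)
  stop_if_not(!anyNA(m), "phenotype ids missing from the scored panel")
  out <- phenotypes
  for (cl in sc_cols) out[[cl]] <- scores[[cl]][m]
  class(out) <- c("scored_cohort", "data.frame")
  out
}
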