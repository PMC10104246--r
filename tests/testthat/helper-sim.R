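# Shared fixture builders: everything is generated in code at test time.

tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_snps = 400L, n_blocks = 8L,
               n_discovery = 1500L, n_families = 400L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# A scored cohort built from the simulator's true genetic values, i.e. a
# perfect-weight polygenic score: isolates the regression estimators from
# finite-sample PGS attenuation.
true_score_cohort <- function(panel, phenotypes) {
  sc <- panel$meta[, c("id", "family_id", "role", "zygosity")]
  f <- panel$meta$role %in% c("parent1", "parent2")
  sc$pgs_cog <- (panel$g_cog - mean(panel$g_cog[f])) / sd(panel$g_cog[f])
  sc$pgs_noncog <- (panel$g_noncog - mean(panel$g_noncog[f])) /
    sd(panel$g_noncog[f])
  class(sc) <- c("scored_cohort", "data.frame")
  scored_cohort(sc, phenotypes)
}

# Minimal ld_reference-shaped object for closed-form LDpred checks.
manual_ld <- function(R_blocks, maf) {
  M <- length(maf)
  sizes <- vapply(R_blocks, nrow, integer(1))
  stopifnot(sum(sizes) == M)
  ends <- cumsum(sizes)
  blocks <- Map(function(s, e) seq.int(s, e), ends - sizes + 1, ends)
  structure(list(blocks = blocks, R = R_blocks,
                 R_latent = R_blocks,
                 chol = lapply(R_blocks, function(R)
                   tryCatch(chol(R), error = function(e) NULL)),
                 ldscores = unlist(lapply(R_blocks,
                                          function(R) rowSums(R^2))),
                 snp_info = data.frame(
                   snp = sprintf("rs%05d", seq_len(M)),
                   block = rep(seq_along(sizes), sizes),
                   bp = seq_len(M), a1 = "A", a2 = "G", maf = maf,
                   stringsAsFactors = FALSE),
                 rho = NA_real_),
            class = "ld_reference")
}

# Genetic covariance object assembled from a known S (for exact-fit tests).
manual_gc <- function(S, traits, v_diag = 1e-6) {
  nv <- length(vech(S))
  structure(list(S = S, V = diag(v_diag, nv), traits = traits,
                 smoothed_S = FALSE, smoothed_V = FALSE,
                 vech_names = noncogdev:::vech_names(traits),
                 n_blocks = 50, M = nrow(S) * 100),
            class = "genetic_covariance")
}

vech <- noncogdev:::vech
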