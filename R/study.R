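#' Run the in-memory polygenic-score study for one configuration
#'
#' Convenience wrapper chaining the genomic stages without file output:
#' discovery sumstats, genetic covariance, two-factor model fit, per-SNP
#' factor effects, LDpred-infinitesimal weights (shrinkage heritability from
#' the package's own LDSC estimate of each factor), family-panel scoring,
#' developmental outcomes, and the per-age PGS regression profile.
#'
#' @param config A [sim_config()].
#' @param n_blocks Jackknife blocks for LDSC.
#' @return List with `profile` (per-age PGS betas), `cohort` (scored
#'   phenotypes), `panel`, `effects`, `fit`, `gc`, `weights`.
#' @export
pgs_study <- function(config, n_blocks = 50) {
  ld <- build_ld_reference(config)
  set <- simulate_discovery_sumstats(config, ld)
  gc_ <- build_genetic_covariance(set, ld, n_blocks)
  model <- path_model(traits = gc_$traits,
                      noncog = intersect(c("EA", "IN", "DE"), gc_$traits))
  fit <- fit_path_model(gc_, model)
  effects <- gwas_by_subtraction(gc_, set, fit)
  weights <- list()
  for (f in c("cog", "noncog")) {
    fs <- factor_sumstats(effects, f)
    h2f <- min(max(ldsc_univariate(fs, ld, n_blocks)$h2, 0.05), 1)
    weights[[f]] <- ldpred_inf_weights(fs, ld, h2 = h2f)
  }
  panel <- simulate_genotype_panel(config, ld)
  pheno <- simulate_developmental_outcomes(panel, config)
  scores <- score_individuals(panel, list(weights$cog, weights$noncog),
                              names = c("pgs_cog", "pgs_noncog"))
  cohort <- scored_cohort(scores, pheno)
  profile <- pgs_developmental_profile(cohort, seed = config$seed)
  list(profile = profile, cohort = cohort, panel = panel,
       effects = effects, fit = fit, gc = gc_, weights = weights,
       ld = ld)
}
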