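test_that("a noise-free S is fitted exactly", {
  arch <- factor_architecture()
  Lam <- cbind(arch$cog_loadings, arch$noncog_loadings)
  S <- Lam %*% t(Lam) + diag(arch$residual_h2)
  dimnames(S) <- list(arch$trait_names, arch$trait_names)
  fit <- fit_path_model(manual_gc(S, arch$trait_names), path_model())
  expect_lt(max(abs(fit$loadings - Lam)), 1e-6)
  expect_lt(fit$discrepancy, 1e-8)
  expect_lt(max(abs(fit$implied_S - S)), 1e-8)
  # fixed constraints reproduced exactly
  expect_equal(unname(fit$loadings[1:5, "noncog"]), rep(0, 5))
})

test_that("subtraction orthogonality holds in the default model", {
  # factor covariance fixed at zero: implied Cog-NonCog covariance is 0
  m <- path_model()
  layout <- noncogdev:::pm_layout(m)
  expect_length(layout$idx_fc, 0)
  # and the oblique variant frees it
  mo <- path_model(factor_cov = "free")
  expect_length(noncogdev:::pm_layout(mo)$idx_fc, 1)
})

test_that("an unidentified model is rejected", {
  # every trait on both factors with free factor covariance: not identified
  expect_error(
    fit_path_model(
      manual_gc(diag(8) * 0.3, path_model()$traits),
      path_model(noncog = path_model()$traits, factor_cov = "free")),
    "identif")
})

test_that("duplicated cognitive input drives the NonCog side to zero", {
  # architecture with no noncognitive genetics at all; EA duplicates CP
  arch <- factor_architecture(noncog_loadings = rep(0, 8))
  cfg <- sim_config(seed = 37, n_snps = 1000L, n_blocks = 20L,
                    n_discovery = 4000L, architecture = arch)
  ldr <- build_ld_reference(cfg)
  set <- simulate_discovery_sumstats(cfg, ldr)
  set$tables$EA <- set$tables$CP
  set$tables$IN <- set$tables$CP
  set$tables$DE <- set$tables$CP
  gcv <- build_genetic_covariance(set, ldr, 20)
  fit <- fit_path_model(gcv, path_model())
  # NonCog variance contribution collapses relative to Cog
  expect_lt(sum(fit$loadings[, "noncog"]^2) /
              sum(fit$loadings[, "cog"]^2), 0.10)
  eff <- gwas_by_subtraction(gcv, set, fit)
  # NonCog statistics are null-calibrated noise; Cog carries the signal
  expect_lt(mean(eff$z_noncog^2), 1.4)
  expect_gt(mean(eff$z_cog^2), mean(eff$z_noncog^2) + 0.5)
})

test_that("per-SNP factor effects recover the generating architecture", {
  cfg <- sim_config(seed = 41, n_snps = 1500L, n_blocks = 30L,
                    n_discovery = 6000L)
  ldr <- build_ld_reference(cfg)
  set <- simulate_discovery_sumstats(cfg, ldr)
  gcv <- build_genetic_covariance(set, ldr, 30)
  fit <- fit_path_model(gcv, path_model())
  # loadings recovered (up to factor sign, fixed positive by convention)
  expect_lt(max(abs(fit$loadings[, "cog"] -
                      cfg$architecture$cog_loadings)), 0.25)
  eff <- gwas_by_subtraction(gcv, set, fit)
  tru <- true_effects(cfg)
  expect_gt(cor(eff$beta_cog, tru$u_cog), 0.4)
  expect_gt(cor(eff$beta_noncog, tru$u_noncog), 0.3)
  # effective N is larger for the better-measured Cog factor
  n_eff <- attr(eff, "n_eff")
  expect_gt(n_eff[["cog"]], n_eff[["noncog"]])
})

test_that("null SNP factor statistics are calibrated", {
  # fully null traits scored against a fixed measurement model: the per-SNP
  # factor z-statistics must reject at the nominal 5% rate
  arch0 <- factor_architecture(cog_loadings = rep(0, 8),
                               noncog_loadings = rep(0, 8),
                               residual_h2 = rep(0, 8))
  cfg <- sim_config(seed = 43, n_snps = 1000L, n_blocks = 20L,
                    n_discovery = 4000L, ld_decay = 0,
                    architecture = arch0)
  ldr <- build_ld_reference(cfg)
  set <- simulate_discovery_sumstats(cfg, ldr)
  ref <- factor_architecture() # measurement model held at reference values
  fit <- structure(list(traits = ref$trait_names,
                        loadings = cbind(cog = as.numeric(ref$cog_loadings),
                                         noncog = as.numeric(
                                           ref$noncog_loadings))),
                   class = "path_model_fit")
  rownames(fit$loadings) <- ref$trait_names
  eff <- gwas_by_subtraction(manual_gc(diag(0.3, 8), ref$trait_names),
                             set, fit)
  for (zcol in c("z_cog", "z_noncog")) {
    rej <- mean(abs(eff[[zcol]]) > 1.96)
    expect_gt(rej, 0.02)
    expect_lt(rej, 0.085)
  }
})

test_that("factor-level genetic correlations order external traits correctly", {
  cfg <- sim_config(seed = 47, n_snps = 1500L, n_blocks = 30L,
                    n_discovery = 6000L)
  ldr <- build_ld_reference(cfg)
  set <- simulate_discovery_sumstats(cfg, ldr)
  gcv <- build_genetic_covariance(set, ldr, 30)
  fit <- fit_path_model(gcv, path_model())
  # external trait = the EA indicator itself: loads on both, stronger NonCog
  rg_ea <- factor_rg_with_external(fit, set, set$tables$EA, ldr, 30)
  expect_gt(rg_ea[["rg_noncog"]], rg_ea[["rg_cog"]] - 0.2)
  expect_gt(rg_ea[["rg_cog"]], 0.2)
  # a pure-cognitive external trait correlates more with Cog
  rg_cp <- factor_rg_with_external(fit, set, set$tables$CP, ldr, 30)
  expect_gt(rg_cp[["rg_cog"]], 0.7)
  expect_lt(abs(rg_cp[["rg_noncog"]]), 0.35)
  # a heritability-free external trait is rejected
  null_tab <- set$tables$CP
  null_tab$Z <- 0
  expect_error(factor_rg_with_external(fit, set, null_tab, ldr, 30),
               "nonpositive")
})
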