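fam_cfg <- tiny_config(seed = 61, n_snps = 300L, n_blocks = 6L,
                       n_families = 1200L)
fam_ld <- build_ld_reference(fam_cfg)
fam_panel <- simulate_genotype_panel(fam_cfg, fam_ld)
fam_pheno <- simulate_developmental_outcomes(fam_panel, fam_cfg)
fam_cohort <- true_score_cohort(fam_panel, fam_pheno)

test_that("the within/between decomposition is exact arithmetic", {
  dec <- decompose_within_between(fam_cohort)
  # reconstruction and zero-sum identities, machine precision
  expect_equal(dec$pgs_cog_mean + dec$pgs_cog_dev, dec$pgs_cog,
               tolerance = 1e-12)
  sums <- tapply(dec$pgs_noncog_dev, dec$family_id, sum)
  expect_lt(max(abs(sums)), 1e-12)
  # hand case
  d2 <- dec[1:2, ]
  d2$pgs_cog <- c(1.0, 0.2)
  d2$family_id <- "FX"
  r <- decompose_within_between(
    within(d2, zygosity <- "DZ"), pgs = "pgs_cog")
  expect_equal(unique(r$pgs_cog_mean), 0.6)
  expect_equal(sort(r$pgs_cog_dev), c(-0.4, 0.4))
  # orthogonality between family means and deviations
  expect_lt(abs(cor(dec$pgs_cog_mean, dec$pgs_cog_dev)), 0.06)
})

test_that("families without two DZ twins are excluded and counted", {
  dec0 <- decompose_within_between(fam_cohort)
  one_twin <- fam_cohort[!(fam_cohort$family_id ==
                             fam_cohort$family_id[fam_cohort$role ==
                                                    "twin2"][1] &
                             fam_cohort$role == "twin2"), ]
  # drop twin2 of the first DZ family entirely
  dz_fams <- unique(fam_cohort$family_id[fam_cohort$zygosity == "DZ"])
  drop_fam <- dz_fams[1]
  sub <- fam_cohort[!(fam_cohort$family_id == drop_fam &
                        fam_cohort$role == "twin2"), ]
  dec <- decompose_within_between(sub)
  expect_equal(attr(dec, "n_excluded"), 1)
  expect_false(drop_fam %in% dec$family_id)
  expect_equal(nrow(dec0) - nrow(dec), 2)
})

test_that("without passive rGE the between and within effects coincide", {
  cfg0 <- tiny_config(seed = 63, n_snps = 300L, n_blocks = 6L,
                      n_families = 1500L,
                      rge_config = rge_config(
                        lambda_active = rep(0, 4), gamma_passive = 0))
  ld0 <- build_ld_reference(cfg0)
  p0 <- simulate_genotype_panel(cfg0, ld0)
  coh0 <- true_score_cohort(p0, simulate_developmental_outcomes(p0, cfg0))
  dec0 <- decompose_within_between(coh0)
  wb <- fit_within_between_model(coh0, dec0, age = 7)
  dif <- abs(wb$beta[["pgs_noncog_mean"]] - wb$beta[["pgs_noncog_dev"]])
  expect_lt(dif, 2 * sqrt(wb$se[["pgs_noncog_mean"]]^2 +
                            wb$se[["pgs_noncog_dev"]]^2))
  # and the population-level regression agrees with both
  pr <- pgs_regression(coh0, age = 7)
  b_pop <- pr$beta[pr$term == "pgs_noncog"]
  expect_lt(abs(b_pop - wb$beta[["pgs_noncog_dev"]]), 0.1)
})

test_that("passive rGE inflates the between effect, not the within effect", {
  wb <- local({
    dec <- decompose_within_between(fam_cohort)
    fit_within_between_model(fam_cohort, dec, age = 7)
  })
  # default scenario: gamma_passive = 0.5, direct noncog effect 0.10
  expect_gt(wb$beta[["pgs_noncog_mean"]],
            wb$beta[["pgs_noncog_dev"]] + 0.05)
  expect_lt(abs(wb$beta[["pgs_noncog_dev"]] - 0.10),
            2 * wb$se[["pgs_noncog_dev"]])
})

test_that("the G x SES model finds construction-level effects", {
  gx <- gxe_model(fam_cohort, age = 16)
  tb <- gx$terms
  # SES loads on achievement through the family environment
  expect_gt(tb$beta[tb$term == "ses"], 0)
  expect_lt(tb$p[tb$term == "ses"], 0.05)
  expect_true(all(tb$q[tb$interaction] >= tb$p[tb$interaction] - 1e-12))
  sl <- slopes_by_ses(gx, "pgs_noncog")
  expect_equal(nrow(sl), 4)
  expect_true(all(is.finite(sl$slope)))
})

test_that("an injected PGS-by-SES interaction is recovered", {
  cfgx <- tiny_config(seed = 67, n_snps = 300L, n_blocks = 6L,
                      n_families = 2000L,
                      rge_config = rge_config(gxe_noncog = 0.1))
  ldx <- build_ld_reference(cfgx)
  px <- simulate_genotype_panel(cfgx, ldx)
  cohx <- true_score_cohort(px, simulate_developmental_outcomes(px, cfgx))
  gx <- gxe_model(cohx, age = 16)
  tb <- gx$terms
  nm <- tb$term %in% c("pgs_noncog:ses", "ses:pgs_noncog")
  expect_lt(abs(tb$beta[nm] - 0.1), 2 * tb$se[nm])
  expect_gt(tb$beta[nm], 0.02)
})
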