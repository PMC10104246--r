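ld_cfg <- sim_config(seed = 17, n_snps = 1200L, n_blocks = 24L,
                     n_discovery = 4000L)
ld_ref <- build_ld_reference(ld_cfg)

test_that("null statistics independent of LD give zero heritability", {
  z <- noncogdev:::with_seed(5, rnorm(1200))
  tab <- data.frame(SNP = ld_ref$snp_info$snp, A1 = "A", A2 = "G",
                    Z = z, N = 5000, stringsAsFactors = FALSE)
  u <- ldsc_univariate(tab, ld_ref, 24)
  expect_lt(abs(u$h2), 2 * u$h2_se)
  expect_lt(abs(u$intercept - 1), 2 * u$intercept_se + 0.05)
})

test_that("jackknife SEs equal a brute-force leave-one-block recomputation", {
  z <- noncogdev:::with_seed(6, rnorm(1200) * sqrt(1 + ld_ref$ldscores))
  tab <- data.frame(SNP = ld_ref$snp_info$snp, A1 = "A", A2 = "G",
                    Z = z, N = 3000, stringsAsFactors = FALSE)
  u <- ldsc_univariate(tab, ld_ref, 20)
  # independent oracle: plain weighted lm per deleted block
  y <- z^2
  l <- ld_ref$ldscores
  w <- u$weights
  blocks <- split(seq_along(y), cut(seq_along(y), 20, labels = FALSE))
  loo <- t(vapply(blocks, function(b) {
    fit <- stats::lm(y[-b] ~ l[-b], weights = w[-b])
    c(coef(fit)[1], coef(fit)[2] * u$M / u$n)
  }, numeric(2)))
  se_or <- sqrt((20 - 1) / 20 * colSums(sweep(loo, 2, colMeans(loo), "-")^2))
  expect_equal(u$intercept_se, unname(se_or[1]), tolerance = 1e-10)
  expect_equal(u$h2_se, unname(se_or[2]), tolerance = 1e-10)
})

test_that("full-sample LDSC estimates are invariant to SNP ordering", {
  z <- noncogdev:::with_seed(7, rnorm(1200) * sqrt(1 + ld_ref$ldscores))
  tab <- data.frame(SNP = ld_ref$snp_info$snp, A1 = "A", A2 = "G",
                    Z = z, N = 3000, stringsAsFactors = FALSE)
  u1 <- ldsc_univariate(tab, ld_ref, 12)
  perm <- noncogdev:::with_seed(8, sample(nrow(tab)))
  u2 <- ldsc_univariate(tab[perm, ], ld_ref, 12)
  expect_equal(u1$h2, u2$h2, tolerance = 1e-10)
  expect_equal(u1$intercept, u2$intercept, tolerance = 1e-10)
})

test_that("a trait paired with itself has genetic correlation one", {
  arch <- factor_architecture(trait_names = c("Ta", "Tb"),
                              cog_loadings = c(sqrt(0.4), sqrt(0.3)),
                              noncog_loadings = c(0, 0),
                              residual_h2 = c(0, 0))
  cfg <- sim_config(seed = 19, n_snps = 1200L, n_blocks = 24L,
                    n_discovery = 5000L, architecture = arch)
  set <- simulate_discovery_sumstats(cfg, build_ld_reference(cfg))
  bi <- ldsc_bivariate(set$tables$Ta, set$tables$Ta,
                       build_ld_reference(cfg), 24)
  expect_true(bi$rg_defined)
  expect_lt(abs(bi$rg - 1), 0.02)
})

test_that("sample overlap with correlated environments inflates the intercept", {
  arch0 <- factor_architecture(trait_names = c("Ua", "Ub"),
                               cog_loadings = c(0, 0),
                               noncog_loadings = c(0, 0),
                               residual_h2 = c(0, 0))
  cfg <- sim_config(seed = 23, n_snps = 600L, n_blocks = 12L,
                    n_discovery = 3000L, architecture = arch0)
  ldr <- build_ld_reference(cfg)
  over <- simulate_discovery_sumstats(cfg, ldr, overlap = 1, env_cor = 0.5)
  bo <- ldsc_bivariate(over$tables$Ua, over$tables$Ub, ldr, 12)
  # complete overlap: intercept ~ phenotypic correlation (= env_cor here)
  expect_lt(abs(bo$intercept - 0.5), 0.15)
  apart <- simulate_discovery_sumstats(cfg, ldr, overlap = 0)
  ba <- ldsc_bivariate(apart$tables$Ua, apart$tables$Ub, ldr, 12)
  expect_lt(abs(ba$intercept), 2 * ba$intercept_se + 0.02)
})

test_that("the genetic covariance assembly is coherent", {
  arch <- factor_architecture(
    trait_names = c("P", "Q", "R"),
    cog_loadings = c(sqrt(0.4), sqrt(0.3), sqrt(0.2)),
    noncog_loadings = c(0, 0, 0), residual_h2 = c(0, 0.05, 0.1))
  cfg <- sim_config(seed = 29, n_snps = 1500L, n_blocks = 30L,
                    n_discovery = 5000L, architecture = arch)
  ldr <- build_ld_reference(cfg)
  set <- simulate_discovery_sumstats(cfg, ldr)
  gcv <- build_genetic_covariance(set, ldr, 25)
  expect_equal(gcv$S, t(gcv$S))
  expect_equal(gcv$V, t(gcv$V))
  expect_gt(min(eigen(gcv$V, only.values = TRUE)$values), 0)
  # diagonal entries match the univariate estimates used to build them
  if (!gcv$smoothed_S) {
    expect_equal(unname(diag(gcv$S)),
                 unname(vapply(gcv$univariate, function(u) u$h2,
                               numeric(1))),
                 tolerance = 1e-10)
  }
  # truth within ~2 jackknife SE for each h2
  for (i in 1:3) {
    expect_lt(abs(gcv$S[i, i] - arch$h2[i]),
              3 * gcv$univariate[[i]]$h2_se)
  }
})

test_that("duplicated traits leave S rank-deficient but never crash", {
  arch <- factor_architecture(trait_names = c("Xa", "Xb"),
                              cog_loadings = c(sqrt(0.4), sqrt(0.4)),
                              noncog_loadings = c(0, 0),
                              residual_h2 = c(0, 0))
  cfg <- sim_config(seed = 31, n_snps = 600L, n_blocks = 12L,
                    n_discovery = 2000L, architecture = arch)
  ldr <- build_ld_reference(cfg)
  set <- simulate_discovery_sumstats(cfg, ldr)
  set$tables$Xb <- set$tables$Xa # exact duplicate
  set$tables$Xc <- set$tables$Xa
  set$traits <- c("Xa", "Xb", "Xc")
  gcv <- build_genetic_covariance(set, ldr, 12)
  expect_s3_class(gcv, "genetic_covariance")
  expect_gt(min(eigen(gcv$V, only.values = TRUE)$values), 0)
})
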