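test_that("Falconer estimates follow the algebraic identities", {
  mk <- function(rmz, rdz) {
    structure(list(trait = "y", r_mz = rmz, r_dz = rdz,
                   n_mz = 500, n_dz = 500,
                   ci_mz = c(NA, NA), ci_dz = c(NA, NA), conf = 0.95),
              class = "twin_correlations")
  }
  f1 <- falconer_estimates(mk(0.8, 0.5))
  expect_equal(c(f1$A, f1$C, f1$E), c(0.6, 0.2, 0.2), tolerance = 1e-12)
  expect_false(f1$truncated)

  f2 <- falconer_estimates(mk(0.5, 0.5))
  expect_equal(c(f2$A, f2$C, f2$E), c(0, 0.5, 0.5), tolerance = 1e-12)

  # negative C truncated to zero and flagged
  f3 <- falconer_estimates(mk(0.4, 0.1))
  expect_equal(c(f3$A, f3$C, f3$E), c(0.6, 0, 0.6), tolerance = 1e-12)
  expect_true(f3$truncated)
  expect_equal(unname(f3$raw["C"]), -0.2, tolerance = 1e-12)
})

test_that("intraclass correlation limits behave as expected", {
  tc <- simulate_twin_multivariate(200, 200, 0.5, 0.2, 0.3, "y", seed = 8)
  # duplicate twin 1 into twin 2 -> r = 1
  dup <- tc
  v1 <- dup$value[dup$twin == 1]
  dup$value[dup$twin == 2] <- v1
  expect_gt(intraclass_correlations(dup, "y")$r_mz, 0.999)
  # independent values -> r near 0
  ind <- tc
  ind$value <- noncogdev:::with_seed(1, rnorm(nrow(ind)))
  ic <- intraclass_correlations(ind, "y")
  expect_lt(abs(ic$r_mz), 2 / sqrt(ic$n_mz))
  expect_lt(abs(ic$r_dz), 2 / sqrt(ic$n_dz))
})

test_that("univariate ML recovery agrees with Falconer within sampling error", {
  tc <- simulate_twin_multivariate(2000, 2000, 0.5, 0.2, 0.3, "y", seed = 21)
  fit <- fit_ace(tc, "y", "univariate")
  expect_true(fit$convergence)
  expect_lt(abs(fit$std$A[1, 1] - 0.5), 0.08)
  expect_lt(abs(fit$std$C[1, 1] - 0.2), 0.08)
  expect_lt(abs(fit$std$E[1, 1] - 0.3), 0.04)
  falc <- falconer_estimates(intraclass_correlations(tc, "y"))
  expect_lt(abs(fit$std$A[1, 1] - falc$A), 0.06)
  # standardized components sum to the phenotypic variance
  expect_equal(fit$std$A[1, 1] + fit$std$C[1, 1] + fit$std$E[1, 1], 1,
               tolerance = 1e-3)
})

test_that("data generated without shared environment fit C near zero", {
  tc <- simulate_twin_multivariate(1500, 1500, 0.5, 0, 0.5, "y", seed = 22)
  fit <- fit_ace(tc, "y", "univariate")
  expect_lt(fit$std$C[1, 1], 0.05)
  falc <- falconer_estimates(intraclass_correlations(tc, "y"))
  expect_lt(abs(fit$std$A[1, 1] - falc$A), 0.07)
})

test_that("the likelihood is lowest near the generating parameters", {
  # -2lnL at truth beats clearly perturbed parameters, on average
  truth <- c(sqrt(0.5), sqrt(0.2), sqrt(0.3))
  wrong <- c(sqrt(0.1), sqrt(0.6), sqrt(0.3))
  diffs <- vapply(1:5, function(i) {
    tc <- simulate_twin_multivariate(400, 400, 0.5, 0.2, 0.3, "y",
                                     seed = 30 + i, standardize = FALSE)
    pm <- twin_pair_matrix(tc, "y")
    mlcov <- function(M) {
      Mc <- sweep(M, 2, colMeans(M), "-"); crossprod(Mc) / nrow(M)
    }
    st <- list(mz = list(S = mlcov(pm$mz), n = nrow(pm$mz)),
               dz = list(S = mlcov(pm$dz), n = nrow(pm$dz)))
    noncogdev:::ace_neg2ll(wrong, "univariate", 1, st) -
      noncogdev:::ace_neg2ll(truth, "univariate", 1, st)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("common pathway model recovers latent structure", {
  f <- rep(0.7, 4); res <- 1 - f^2
  mk <- function(lat, spl) lat * tcrossprod(f) + diag(spl * res, 4)
  A <- mk(0.8, 0.25); C <- mk(0.1, 0.10); E <- mk(0.1, 0.65)
  tc <- simulate_twin_multivariate(1500, 1500, A, C, E, paste0("x", 1:4),
                                   seed = 41)
  fit <- fit_ace(tc, paste0("x", 1:4), "common_pathway")
  expect_true(fit$convergence)
  expect_lt(abs(fit$latent[["a2"]] - 0.8), 0.08)
  expect_lt(max(abs(abs(fit$loadings) - 0.7)), 0.05)
})

test_that("trivariate Cholesky shares are recovered and internally consistent", {
  tr <- trivariate_ace_matrices(0.30, 0.12, 0.20)
  tc <- simulate_twin_multivariate(1200, 2400, tr$A, tr$C, tr$E,
                                   c("cog", "noncog", "ach"), seed = 42)
  fit <- fit_ace(tc, c("cog", "noncog", "ach"), "cholesky")
  sh <- variance_shares_from_cholesky(fit)
  expect_lt(abs(sh$share_cog - 0.30), 0.07)
  expect_lt(abs(sh$share_noncog_independent - 0.12), 0.07)
  expect_lt(abs(sh$share_achievement_specific - 0.20), 0.07)
  # Cholesky identity: shares sum to achievement heritability
  h2_ach <- fit$std$A[3, 3]
  expect_equal(sh$share_cog + sh$share_noncog_independent +
                 sh$share_achievement_specific, h2_ach, tolerance = 1e-6)
  # implied pair covariances are PSD
  expect_gt(min(eigen(fit$sigma_mz, only.values = TRUE)$values), 0)
  expect_gt(min(eigen(fit$sigma_dz, only.values = TRUE)$values), 0)
  # MZ cross-twin covariance dominates DZ when A is nonzero
  expect_gt(fit$sigma_mz[1, 4], fit$sigma_dz[1, 4])
})

test_that("a duplicated noncognitive trait contributes no independent genetics", {
  tr <- trivariate_ace_matrices(0.30, 0.12, 0.20)
  tc <- simulate_twin_multivariate(1000, 2000, tr$A, tr$C, tr$E,
                                   c("cog", "noncog", "ach"), seed = 43)
  # overwrite noncog with a copy of cog (plus tiny jitter for invertibility)
  v_cog <- tc$value[tc$trait == "cog"]
  tc$value[tc$trait == "noncog"] <-
    v_cog + noncogdev:::with_seed(2, rnorm(length(v_cog), sd = 0.02))
  fit <- fit_ace(tc, c("cog", "noncog", "ach"), "cholesky")
  sh <- variance_shares_from_cholesky(fit)
  expect_lt(sh$share_noncog_independent, 0.03)
})

test_that("total achievement heritability is invariant to entry order", {
  tr <- trivariate_ace_matrices(0.30, 0.12, 0.20)
  tc <- simulate_twin_multivariate(1000, 2000, tr$A, tr$C, tr$E,
                                   c("cog", "noncog", "ach"), seed = 44)
  f1 <- fit_ace(tc, c("cog", "noncog", "ach"), "cholesky")
  f2 <- fit_ace(tc, c("noncog", "cog", "ach"), "cholesky")
  expect_equal(f1$std$A[3, 3], f2$std$A[3, 3], tolerance = 0.01)
})
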