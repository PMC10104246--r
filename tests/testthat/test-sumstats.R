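test_that("a null architecture yields null GWAS statistics", {
  arch0 <- factor_architecture(trait_names = c("A1t", "B1t"),
                               cog_loadings = c(0, 0),
                               noncog_loadings = c(0, 0),
                               residual_h2 = c(0, 0))
  cfg <- tiny_config(seed = 3, architecture = arch0, n_discovery = 2000L)
  ld <- build_ld_reference(cfg)
  set <- simulate_discovery_sumstats(cfg, ld)
  chi2 <- set$tables$A1t$Z^2
  expect_lt(abs(mean(chi2) - 1), 3 * sqrt(2 / length(chi2)) + 0.05)
})

test_that("single-factor truth gives a genetic correlation near one", {
  arch1 <- factor_architecture(
    trait_names = c("EAx", "CPx"),
    cog_loadings = c(sqrt(0.35), sqrt(0.30)),
    noncog_loadings = c(0, 0), residual_h2 = c(0, 0))
  cfg <- sim_config(seed = 5, n_snps = 1500L, n_blocks = 30L,
                    n_discovery = 6000L, architecture = arch1)
  ld <- build_ld_reference(cfg)
  set <- simulate_discovery_sumstats(cfg, ld)
  bi <- ldsc_bivariate(set$tables$EAx, set$tables$CPx, ld, 30)
  expect_true(bi$rg_defined)
  expect_lt(abs(bi$rg - 1), 0.25)
})

test_that("sumstats generation is deterministic and records N", {
  cfg <- tiny_config(seed = 9, n_discovery = 1000L)
  ld <- build_ld_reference(cfg)
  s1 <- simulate_discovery_sumstats(cfg, ld)
  s2 <- simulate_discovery_sumstats(cfg, ld)
  expect_identical(s1$tables$EA$Z, s2$tables$EA$Z)
  expect_true(all(s1$tables$CP$N == 1000))
  expect_warning(
    simulate_discovery_sumstats(tiny_config(n_discovery = 400L), ld),
    "unstable")
})

test_that("harmonization flips swapped alleles and drops ambiguous SNPs", {
  ref <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4"),
                    A1 = c("A", "A", "A", "A"),
                    A2 = c("G", "G", "T", "G"),
                    Z = c(1, -2, 0.5, 3), N = 1000,
                    stringsAsFactors = FALSE)
  other <- ref
  other$A1 <- c("G", "A", "A", "A")
  other$A2 <- c("A", "G", "T", "G")
  other$Z <- c(1.7, 0.3, 1, -1)
  h <- harmonize_sumstats(list(t1 = ref, t2 = other))
  # rs3 is strand-ambiguous (A/T) and must be gone
  expect_false("rs3" %in% h$tables$t1$SNP)
  expect_equal(h$log$ambiguous_reference, 1)
  # rs1 was A1/A2-swapped in t2: sign flipped, alleles aligned
  z1 <- h$tables$t2$Z[h$tables$t2$SNP == "rs1"]
  expect_equal(z1, -1.7)
  expect_equal(h$tables$t2$A1[h$tables$t2$SNP == "rs1"], "A")
  expect_equal(h$log$flipped, 1)
})

test_that("harmonizing identical tables changes nothing", {
  tb <- data.frame(SNP = paste0("rs", 1:5), A1 = "A", A2 = "G",
                   Z = rnorm(5), N = 500, stringsAsFactors = FALSE)
  h <- harmonize_sumstats(list(a = tb, b = tb))
  expect_equal(h$tables$a$Z, tb$Z)
  expect_equal(h$tables$b$Z, tb$Z)
  expect_equal(h$log$allele_mismatch, 0)
  expect_equal(h$log$flipped, 0)
})

test_that("allele mismatches are dropped with a count", {
  ref <- data.frame(SNP = c("rs1", "rs2"), A1 = "A", A2 = "G",
                    Z = c(1, 2), N = 100, stringsAsFactors = FALSE)
  bad <- ref
  bad$A1 <- c("C", "A"); bad$A2 <- c("G", "G")
  h <- harmonize_sumstats(list(a = ref, b = bad))
  expect_equal(nrow(h$tables$a), 1)
  expect_equal(h$log$allele_mismatch, 1)
  expect_error(harmonize_sumstats(list(
    a = data.frame(SNP = "rs1", A1 = "A", A2 = "G", Z = 1, N = 10),
    b = data.frame(SNP = "rs9", A1 = "A", A2 = "G", Z = 1, N = 10))),
    "empty")
})
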