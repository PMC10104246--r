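test_that("identity-LD weights match the scalar closed form", {
  # beta_std = 0.12, M = 100, N = 1000, h2 = 0.5 -> lambda = 0.2,
  # w = 0.12 / 1.2 = 0.10 exactly
  M <- 100
  ld <- manual_ld(rep(list(diag(5)), 20), maf = rep(0.3, M))
  ss <- data.frame(SNP = ld$snp_info$snp, A1 = "A", A2 = "G",
                   Z = 0.12 * sqrt(1000), N = 1000,
                   stringsAsFactors = FALSE)
  w <- ldpred_inf_weights(ss, ld, h2 = 0.5)
  expect_equal(attr(w, "lambda"), 0.2, tolerance = 1e-12)
  expect_equal(w$WEIGHT, rep(0.1, M), tolerance = 1e-12)
})

test_that("perfect-LD duplicated SNPs get the 2x2 closed form", {
  # R = [[1, 1], [1, 1]] (eps off perfect for solvability), each beta = b:
  # w = b / (lambda + 2)
  b <- 0.08; N <- 2000; h2 <- 0.4
  R2 <- matrix(c(1, 1, 1, 1), 2)
  ld <- manual_ld(list(R2), maf = c(0.25, 0.25))
  ss <- data.frame(SNP = ld$snp_info$snp, A1 = "A", A2 = "G",
                   Z = b * sqrt(N), N = N, stringsAsFactors = FALSE)
  lambda <- 2 / (N * h2)
  w <- ldpred_inf_weights(ss, ld, h2 = h2)
  expect_equal(w$WEIGHT, rep(b / (lambda + 2), 2), tolerance = 1e-10)
})

test_that("block solves agree with a dense whole-genome solve", {
  cfg <- sim_config(seed = 51, n_snps = 60L, n_blocks = 4L, ld_decay = 0.85)
  ld <- build_ld_reference(cfg)
  ss <- data.frame(SNP = ld$snp_info$snp, A1 = "A", A2 = "G",
                   Z = noncogdev:::with_seed(4, rnorm(60)), N = 5000,
                   stringsAsFactors = FALSE)
  w <- ldpred_inf_weights(ss, ld, h2 = 0.3)
  # brute force: one dense block-diagonal system
  Rfull <- matrix(0, 60, 60)
  for (b in 1:4) Rfull[ld$blocks[[b]], ld$blocks[[b]]] <- ld$R[[b]]
  lambda <- 60 / (5000 * 0.3)
  w_dense <- solve(Rfull + diag(lambda, 60), ss$Z / sqrt(ss$N))
  expect_equal(w$WEIGHT, w_dense, tolerance = 1e-10)
})

test_that("degenerate weight inputs behave as specified", {
  ld <- manual_ld(list(diag(3)), maf = rep(0.2, 3))
  ss <- data.frame(SNP = ld$snp_info$snp, A1 = "A", A2 = "G",
                   Z = 0, N = 100, stringsAsFactors = FALSE)
  expect_equal(ldpred_inf_weights(ss, ld, h2 = 0.5)$WEIGHT, rep(0, 3))
  expect_error(ldpred_inf_weights(ss, ld, h2 = 0), "h2")
  expect_error(ldpred_inf_weights(ss, ld, h2 = 1.5), "h2")
})

pgs_cfg <- tiny_config(seed = 53, n_families = 800L)
pgs_ld <- build_ld_reference(pgs_cfg)
pgs_panel <- simulate_genotype_panel(pgs_cfg, pgs_ld)

test_that("scoring respects MZ duplication and allele orientation", {
  wtab <- data.frame(SNP = pgs_ld$snp_info$snp, A1 = "A",
                     WEIGHT = noncogdev:::with_seed(9, rnorm(400, sd = 0.05)),
                     stringsAsFactors = FALSE)
  class(wtab) <- c("pgs_weights", "data.frame")
  sc <- score_individuals(pgs_panel, wtab, names = "pgs")
  mz <- pgs_panel$zygosity == "MZ"
  s1 <- sc$pgs[sc$role == "twin1"][mz]
  s2 <- sc$pgs[sc$role == "twin2"][mz]
  expect_equal(s1, s2, tolerance = 1e-12)
  # founders standardized
  f <- sc$role %in% c("parent1", "parent2")
  expect_equal(mean(sc$pgs[f]), 0, tolerance = 1e-12)
  expect_equal(sd(sc$pgs[f]), 1, tolerance = 1e-12)
  # flipping the scored allele negates the score
  wflip <- wtab
  wflip$A1 <- "G"
  sflip <- score_individuals(pgs_panel, wflip, names = "pgs")
  expect_equal(sflip$pgs, -sc$pgs, tolerance = 1e-10)
  # zero weights give zero scores
  w0 <- wtab; w0$WEIGHT <- 0
  expect_equal(score_individuals(pgs_panel, w0, names = "pgs")$pgs,
               rep(0, nrow(sc)), tolerance = 1e-12)
})

test_that("DZ co-twin scores correlate near one half", {
  wtab <- data.frame(SNP = pgs_ld$snp_info$snp, A1 = "A",
                     WEIGHT = noncogdev:::with_seed(10, rnorm(400, sd = 0.05)),
                     stringsAsFactors = FALSE)
  class(wtab) <- c("pgs_weights", "data.frame")
  sc <- score_individuals(pgs_panel, wtab, names = "pgs")
  dz <- pgs_panel$zygosity == "DZ"
  r <- cor(sc$pgs[sc$role == "twin1"][dz], sc$pgs[sc$role == "twin2"][dz])
  expect_lt(abs(r - 0.5), 0.08)
})
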