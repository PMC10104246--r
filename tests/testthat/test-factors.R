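make_indicators <- function(n, loadings, seed = 1) {
  noncogdev:::with_seed(seed, {
    f <- rnorm(n)
    out <- vapply(loadings, function(l) l * f + sqrt(1 - l^2) * rnorm(n),
                  numeric(n))
    colnames(out) <- paste0("x", seq_along(loadings))
    as.data.frame(out)
  })
}

test_that("a saturated two-indicator factor drives loadings to one", {
  d <- make_indicators(2000, c(0.999, 0.999), seed = 2)
  sol <- fit_single_factor(d, factor_spec("f", c("x1", "x2")))
  expect_true(all(sol$loadings > 0.98))
  expect_true(cor(sol$scores, d$x1) > 0.98)
})

test_that("known loadings are recovered at n = 5000", {
  d <- make_indicators(5000, c(0.8, 0.7, 0.6, 0.5), seed = 3)
  sol <- fit_single_factor(d, factor_spec("f", paste0("x", 1:4)))
  expect_lt(max(abs(sol$loadings - c(0.8, 0.7, 0.6, 0.5))), 0.05)
  expect_equal(unname(sol$uniquenesses), unname(1 - sol$loadings^2),
               tolerance = 0.02)
  expect_lt(sol$srmr, 0.05)
})

test_that("an uncorrelated indicator gets a near-zero loading", {
  d <- make_indicators(3000, c(0.8, 0.7, 0.6), seed = 4)
  d$x4 <- rnorm(3000)
  sol <- fit_single_factor(d, factor_spec("f", paste0("x", 1:4)))
  expect_lt(abs(sol$loadings[["x4"]]), 0.06)
})

test_that("CFA refitted on its own implied data reproduces loadings", {
  lam <- c(0.75, 0.65, 0.55, 0.45)
  d <- make_indicators(20000, lam, seed = 5)
  sol1 <- fit_single_factor(d, factor_spec("f", paste0("x", 1:4)))
  d2 <- make_indicators(20000, unname(sol1$loadings), seed = 6)
  sol2 <- fit_single_factor(d2, factor_spec("f", paste0("x", 1:4)))
  expect_lt(max(abs(sol1$loadings - sol2$loadings)), 0.03)
})

test_that("degenerate inputs are handled as specified", {
  # single indicator passes through with unit loading
  d <- data.frame(x1 = rnorm(100))
  sol <- fit_single_factor(d, factor_spec("f", "x1"))
  expect_equal(sol$status, "passthrough")
  expect_equal(unname(sol$loadings), 1)
  # too few rows
  expect_error(
    fit_single_factor(data.frame(x1 = rnorm(20), x2 = rnorm(20)),
                      factor_spec("f", c("x1", "x2"))),
    "pairwise")
})

test_that("standardized regression recovers generating effects", {
  noncogdev:::with_seed(11, {
    n <- 5000
    cog <- rnorm(n); noncog <- rnorm(n)
    y <- 0.46 * cog + 0.10 * noncog +
      sqrt(1 - 0.46^2 - 0.10^2) * rnorm(n)
    d <- data.frame(y = y, cog = cog, noncog = noncog, cov1 = rnorm(n))
    r <- regress_standardized(d, "y", c("cog", "noncog"), "cov1")
    b <- r$beta[match(c("cog", "noncog"), r$term)]
    se <- r$se[match(c("cog", "noncog"), r$term)]
    expect_lt(abs(b[1] - 0.46), 2 * se[1])
    expect_lt(abs(b[2] - 0.10), 2 * se[2])
    expect_true(all(r$q[r$predictor] >= r$p[r$predictor] - 1e-12))
  })
})

test_that("regression betas are invariant to affine input rescaling", {
  noncogdev:::with_seed(12, {
    n <- 800
    d <- data.frame(y = rnorm(n), x = rnorm(n), z = rnorm(n))
    d$y <- 0.3 * d$x + d$y
    r1 <- regress_standardized(d, "y", "x", "z")
    d2 <- d; d2$x <- 100 + 7 * d2$x; d2$y <- 3 * d2$y - 1
    r2 <- regress_standardized(d2, "y", "x", "z")
    expect_equal(r1$beta[r1$term == "x"], r2$beta[r2$term == "x"],
                 tolerance = 1e-10)
  })
})

test_that("identity outcome and collinearity behave as contracted", {
  d <- data.frame(y = rnorm(200))
  d$x <- d$y
  # base lm warns about the (intentional) perfect fit
  r <- suppressWarnings(regress_standardized(d, "y", "x"))
  expect_equal(r$beta[r$term == "x"], 1, tolerance = 1e-10)
  expect_equal(attr(r, "r2"), 1, tolerance = 1e-10)
  d$x2 <- d$x
  expect_error(regress_standardized(d, "y", c("x", "x2")), "collinear")
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.012), 0.012)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH controls the false discovery rate under the global null", {
  noncogdev:::with_seed(13, {
    any_rej <- vapply(1:500, function(i) {
      p <- runif(20)
      any(bh_adjust(p) <= 0.05)
    }, logical(1))
    # under the global null FDR = P(any rejection) <= alpha
    expect_lt(mean(any_rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 500) + 0.01)
  })
})

test_that("a Heywood case is clamped and flagged, not fatal", {
  # correlation pattern implying a loading above 1 for x1
  R <- rbind(c(1, 0.9, 0.5), c(0.9, 1, 0.2), c(0.5, 0.2, 1))
  noncogdev:::with_seed(14, {
    n <- 2000
    Z <- matrix(rnorm(n * 3), n)
    Z <- scale(qr.Q(qr(scale(Z, scale = FALSE)))) * sqrt(n / (n - 1))
    d <- as.data.frame(Z %*% chol(R))
    names(d) <- paste0("x", 1:3)
    expect_warning(sol <- fit_single_factor(d, factor_spec("f", names(d))),
                   "Heywood")
    expect_equal(sol$status, "heywood_clamped")
    expect_true(min(sol$uniquenesses) <= 1e-4 * (1 + 1e-6))
  })
})
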