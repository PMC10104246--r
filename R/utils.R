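# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded simulation stages
#' never disturb, or are disturbed by, surrounding code.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derivation; keeps results independent of the
# order in which pipeline stages are run. Always below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(
    ld = 11L, effects = 23L, panel = 37L, sumstats = 53L, twins = 71L,
    outcomes = 89L, subsample = 101L, fitstarts = 113L, pgs = 127L,
    covariates = 139L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483629)
}

# Standardize to mean 0, sd 1 (sd of 0 or NA maps to a zero vector).
zstd <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - m) / s
}

# Column-standardize a matrix; zero-variance columns become 0.
col_standardize <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(colMeans(X^2) - mu^2)
  sd[sd == 0 | !is.finite(sd)] <- Inf # maps the column to 0
  sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
}

# Half-vectorization (column-major lower triangle including diagonal).
vech <- function(S) S[lower.tri(S, diag = TRUE)]

# Names for vech entries given trait labels.
vech_names <- function(traits) {
  k <- length(traits)
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  paste(traits[idx[, 2]], traits[idx[, 1]], sep = ":")
}

# Inverse of vech for a symmetric matrix of order k.
unvech <- function(v, k) {
  S <- matrix(0, k, k)
  S[lower.tri(S, diag = TRUE)] <- v
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  S
}

# Project a symmetric matrix to the nearest PSD matrix by eigenvalue clipping.
# Returns the matrix plus an attribute saying whether clipping occurred.
psd_clip <- function(S, floor = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  clipped <- any(e$values < floor)
  if (clipped) {
    vals <- pmax(e$values, floor)
    S <- e$vectors %*% (vals * t(e$vectors))
    S <- (S + t(S)) / 2
  }
  attr(S, "smoothed") <- clipped
  S
}

# Moore-Penrose pseudoinverse (symmetric input), tolerance relative to the
# largest eigenvalue. Used where near-zero factor loadings make a normal
# matrix singular by design (e.g. the subtraction null).
pinv_sym <- function(A, rtol = 1e-10) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > rtol * max(abs(e$values), rtol)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  e$vectors[, keep, drop = FALSE] %*%
    ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
}

# Numeric Jacobian by central differences.
num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Lower-triangular matrix from a packed parameter vector.
lower_tri_from_vec <- function(v, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- v
  L
}

stop_if_not <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
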