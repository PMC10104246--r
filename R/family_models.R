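# Population-level, within/between-family, and gene-by-environment
# regression designs for Cog/NonCog polygenic scores.

default_covariates <- function() {
  c("sex", "age_dev", paste0("pc", 1:10), "chip", "batch")
}

#' Population-level PGS regression at one age
#'
#' Standardized multiple regression of an outcome on the Cog and NonCog PGS
#' jointly, adjusting for covariates, with one twin per family selected
#' under a fixed seed to avoid family clustering.
#'
#' @param cohort A `scored_cohort` (long, one row per individual per age).
#' @param outcome Outcome column (default `"achievement"`).
#' @param age Age to analyse.
#' @param pgs Names of the score columns.
#' @param covariates Covariate columns.
#' @param seed Subsampling seed.
#' @return A `regression_result` (see [regress_standardized()]).
#' @export
pgs_regression <- function(cohort, outcome = "achievement", age = NULL,
                           pgs = c("pgs_cog", "pgs_noncog"),
                           covariates = default_covariates(), seed = 1) {
  d <- as.data.frame(cohort)
  if (!is.null(age)) d <- d[d$age == age, , drop = FALSE]
  stop_if_not(nrow(d) > 0, "no rows at the requested age")
  regress_standardized(d, outcome, predictors = pgs,
                       covariates = covariates,
                       family_id = "family_id", seed = seed)
}

#' Developmental profile of PGS effects across ages
#'
#' Runs [pgs_regression()] at every age and applies a single BH correction
#' across the whole battery of PGS terms.
#'
#' @inheritParams pgs_regression
#' @param ages Ages to analyse (default: all present).
#' @return Data frame `age, term, beta, se, t, p, q, n`.
#' @export
pgs_developmental_profile <- function(cohort, outcome = "achievement",
                                      ages = NULL,
                                      pgs = c("pgs_cog", "pgs_noncog"),
                                      covariates = default_covariates(),
                                      seed = 1) {
  ages <- ages %||% sort(unique(cohort$age))
  rows <- lapply(ages, function(a) {
    full <- pgs_regression(cohort, outcome, a, pgs, covariates, seed)
    n <- attr(full, "n")
    r <- full[full$predictor, c("term", "beta", "se", "t", "p")]
    r$age <- a
    r$n <- n
    r
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[, c("age", "term", "beta", "se", "t", "p", "q", "n")]
}

#' Within/between family decomposition of DZ co-twin scores
#'
#' For DZ pairs with both twins scored, splits each twin's PGS into the
#' family mean and the deviation from it. Families without exactly two DZ
#' twins are excluded (and counted).
#'
#' @param cohort A `scored_cohort` restricted internally to DZ twins.
#' @param pgs Score columns to decompose.
#' @return A `family_decomposition` data frame with `<pgs>_mean` and
#'   `<pgs>_dev` columns per input score; attribute `n_excluded` counts
#'   dropped families.
#' @export
decompose_within_between <- function(cohort, pgs = c("pgs_cog", "pgs_noncog")) {
  d <- as.data.frame(cohort)
  d <- d[d$zygosity == "DZ", , drop = FALSE]
  stop_if_not(nrow(d) > 0, "no DZ twins in cohort")
  # one row per individual for the decomposition
  key <- !duplicated(d$id)
  ind <- d[key, c("id", "family_id", pgs), drop = FALSE]
  cnt <- table(ind$family_id)
  good <- names(cnt)[cnt == 2]
  n_excluded <- sum(cnt != 2)
  ind <- ind[ind$family_id %in% good, , drop = FALSE]
  for (p in pgs) {
    fm <- stats::ave(ind[[p]], ind$family_id, FUN = mean)
    ind[[paste0(p, "_mean")]] <- fm
    ind[[paste0(p, "_dev")]] <- ind[[p]] - fm
  }
  attr(ind, "n_excluded") <- n_excluded
  class(ind) <- c("family_decomposition", "data.frame")
  ind
}

#' Within/between family mixed model
#'
#' Random-intercept linear mixed model (fitted by ML through `lme4::lmer`)
#' of the outcome on the family-mean PGS (between-family effect, capturing
#' direct effects plus passive rGE and demography) and each twin's deviation
#' from the family mean (within-family effect, indexing direct genetic
#' effects), with covariates. DZ twins only; both twins enter, clustering
#' absorbed by the family intercept.
#'
#' @param cohort A `scored_cohort`.
#' @param decomposition A [decompose_within_between()] result.
#' @param outcome Outcome column.
#' @param age Age to analyse.
#' @param pgs Score columns used in the decomposition.
#' @param covariates Covariate columns.
#' @return Object of class `mixed_fit`: `beta` / `se` for the between and
#'   within terms, variance components, number of families.
#' @export
fit_within_between_model <- function(cohort, decomposition,
                                     outcome = "achievement", age = NULL,
                                     pgs = c("pgs_cog", "pgs_noncog"),
                                     covariates = default_covariates()) {
  d <- as.data.frame(cohort)
  if (!is.null(age)) d <- d[d$age == age, , drop = FALSE]
  d <- d[d$id %in% decomposition$id, , drop = FALSE]
  m <- match(d$id, decomposition$id)
  terms <- c()
  for (p in pgs) {
    d[[paste0(p, "_mean")]] <- decomposition[[paste0(p, "_mean")]][m]
    d[[paste0(p, "_dev")]] <- decomposition[[paste0(p, "_dev")]][m]
    terms <- c(terms, paste0(p, "_mean"), paste0(p, "_dev"))
  }
  d[[outcome]] <- zstd(d[[outcome]])
  fml <- stats::as.formula(paste(
    outcome, "~", paste(c(terms, covariates), collapse = " + "),
    "+ (1 | family_id)"))
  fit <- lme4::lmer(fml, data = d, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  fam_var <- vc$vcov[vc$grp == "family_id"]
  res_var <- vc$vcov[vc$grp == "Residual"]
  structure(list(beta = fe[terms], se = se[terms],
                 all_beta = fe, all_se = se,
                 family_var = fam_var, residual_var = res_var,
                 n_families = length(unique(d$family_id)),
                 n_obs = nrow(d), converged = TRUE),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Within/between family mixed model (%d families, %d obs)\n",
              x$n_families, x$n_obs))
  tab <- cbind(beta = x$beta, se = x$se)
  print(round(tab, 4))
  cat(sprintf("  family intercept var %.3f | residual var %.3f\n",
              x$family_var, x$residual_var))
  invisible(x)
}

#' Gene-by-SES interaction model
#'
#' Multiple regression of achievement on the Cog and NonCog PGS, SES, their
#' two-way interactions, covariates, and (optionally) predictor-by-covariate
#' interactions; one twin per family under a fixed seed. BH correction is
#' applied across the interaction terms.
#'
#' @param cohort A `scored_cohort`.
#' @param outcome Outcome column.
#' @param age Age to analyse.
#' @param ses SES column.
#' @param pgs Score columns.
#' @param covariates Covariate columns.
#' @param predictor_covariate_interactions Include PGS/SES-by-covariate
#'   interaction terms.
#' @param seed Subsampling seed.
#' @return Object of class `gxe_fit`: `terms` data frame (term, beta, se, t,
#'   p, q, interaction flag) plus `n`.
#' @export
gxe_model <- function(cohort, outcome = "achievement", age = NULL,
                      ses = "ses", pgs = c("pgs_cog", "pgs_noncog"),
                      covariates = default_covariates(),
                      predictor_covariate_interactions = TRUE, seed = 1) {
  d <- as.data.frame(cohort)
  if (!is.null(age)) d <- d[d$age == age, , drop = FALSE]
  stop_if_not(nrow(d) > 0, "no rows at the requested age")
  d <- one_per_family(d, "family_id", seed = seed)
  for (v in c(outcome, pgs, ses)) d[[v]] <- zstd(d[[v]])

  main <- c(pgs, ses)
  inter <- c(utils::combn(main, 2, FUN = paste, collapse = ":"))
  pci <- if (predictor_covariate_interactions)
    as.vector(outer(main, covariates, paste, sep = ":")) else character()
  fml <- stats::reformulate(c(main, covariates, inter, pci),
                            response = outcome)
  X <- stats::model.matrix(fml, data = d)
  stop_if_not(qr(X)$rank == ncol(X), "rank-deficient G x E model matrix")
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
                      t = sm[, 3], p = sm[, 4], stringsAsFactors = FALSE)
  is_int <- terms$term %in% gsub(":", ":", inter) |
    terms$term %in% vapply(strsplit(inter, ":"), function(v)
      paste(rev(v), collapse = ":"), character(1))
  terms$interaction <- is_int
  terms$q <- NA_real_
  terms$q[is_int] <- bh_adjust(terms$p[is_int])
  rownames(terms) <- NULL
  structure(list(terms = terms, n = nrow(d),
                 r2 = summary(fit)$r.squared,
                 interaction_terms = terms$term[is_int]),
            class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf("G x SES interaction model (n = %d, R2 = %.3f)\n", x$n, x$r2))
  print(x$terms[x$terms$interaction | x$terms$term %in%
                  c("pgs_cog", "pgs_noncog", "ses"),
                c("term", "beta", "se", "p", "q")], row.names = FALSE)
  invisible(x)
}

#' Simple slopes of PGS on achievement at SES quantiles
#'
#' Summarizes a fitted G x E model as the implied PGS slope at chosen SES
#' quantile points (standardized SES scale).
#'
#' @param fit A [gxe_model()] result.
#' @param pgs Score term.
#' @param ses SES term.
#' @param quantiles SES standard-score points at which to evaluate.
#' @return Data frame `ses_value, slope, se`.
#' @export
slopes_by_ses <- function(fit, pgs = "pgs_noncog", ses = "ses",
                          quantiles = c(-1.5, -0.5, 0.5, 1.5)) {
  tb <- fit$terms
  b_main <- tb$beta[tb$term == pgs]
  int_nm <- c(paste(pgs, ses, sep = ":"), paste(ses, pgs, sep = ":"))
  b_int <- tb$beta[tb$term %in% int_nm]
  se_main <- tb$se[tb$term == pgs]
  se_int <- tb$se[tb$term %in% int_nm]
  stop_if_not(length(b_main) == 1 && length(b_int) == 1,
              "terms not found in fit")
  data.frame(ses_value = quantiles,
             slope = b_main + b_int * quantiles,
             se = sqrt(se_main^2 + (quantiles * se_int)^2))
}
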