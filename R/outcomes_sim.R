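#' Simulate developmental achievement, SES and covariates with injectable rGE
#'
#' Builds the target-cohort phenotypes on top of a simulated family genotype
#' panel. A family environment `F = gamma_passive * midparent(G_noncog) + u`
#' carries passive gene-environment correlation; achievement at each age is
#' \deqn{y_t = b_{cog}(t) G_{cog} + (b_{noncog}(t) + \lambda_{active}(t))
#'       G_{noncog} + \kappa F + \epsilon_t}
#' with the residual variance chosen so the analytic variance budget sums to
#' one (an error is raised if the paths already exceed it), then values are
#' standardized within age. Observed SES is `ses_loading * F + noise`.
#' Cognitive and noncognitive phenotype measures, and covariates (sex, age
#' deviation, 10 ancestry-PC stand-ins, chip, batch) are generated
#' independently of the genetic values.
#'
#' @param panel A [simulate_genotype_panel()] result (parents and twins).
#' @param config The matching [sim_config()]; uses `rge_config` and `ages`.
#' @return A `cohort_phenotypes` data frame, one row per twin per age:
#'   `id`, `family_id`, `role`, `zygosity`, `age`, `achievement`,
#'   `cog_phen`, `noncog_phen`, `ses`, `sex`, `age_dev`, `pc1`-`pc10`,
#'   `chip`, `batch`, plus the true genetic values `g_cog`, `g_noncog`.
#' @export
simulate_developmental_outcomes <- function(panel, config) {
  rge <- config$rge_config
  ages <- config$ages
  stop_if_not(length(rge$b_cog) == length(ages),
              "rge paths and ages disagree in length")
  meta <- panel$meta
  is_twin <- meta$role %in% c("twin1", "twin2")
  stop_if_not(any(is_twin) && any(!is_twin),
              "panel must contain parents and offspring")
  fams <- unique(meta$family_id)
  F_ <- length(fams)

  p1 <- match(paste0(fams, "_P1"), meta$id)
  p2 <- match(paste0(fams, "_P2"), meta$id)
  midparent <- (panel$g_noncog[p1] + panel$g_noncog[p2]) / 2
  names(midparent) <- fams

  with_seed(derive_seed(config$seed, "outcomes"), {
    famenv <- rge$gamma_passive * midparent +
      sqrt(max(0, 1 - rge$gamma_passive^2 * 0.5)) * stats::rnorm(F_)
    ses <- zstd(rge$ses_loading * famenv +
                  sqrt(max(0, 1 - rge$ses_loading^2)) * stats::rnorm(F_))
    names(ses) <- fams

    twins <- meta[is_twin, , drop = FALSE]
    n <- nrow(twins)
    gcog <- panel$g_cog[twins$id]
    gnon <- panel$g_noncog[twins$id]
    fenv <- famenv[twins$family_id]
    ses_t <- ses[twins$family_id]

    # Covariates: independent of genetic values by construction.
    covs <- data.frame(
      sex = twins$sex,
      age_dev = stats::rnorm(n, sd = 0.3),
      chip = sample(0:1, n, TRUE),
      batch = sample(1:3, n, TRUE)
    )
    pcs <- matrix(stats::rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("pc", 1:10)))

    per_age <- vector("list", length(ages))
    for (t in seq_along(ages)) {
      b_c <- rge$b_cog[t]
      b_n <- rge$b_noncog[t] + rge$lambda_active[t]
      # analytic variance: cov(G_noncog, F) = gamma/2 under random mating
      var_f <- rge$gamma_passive^2 * 0.5 +
        max(0, 1 - rge$gamma_passive^2 * 0.5)
      signal_var <- b_c^2 + b_n^2 + rge$kappa_env^2 * var_f +
        2 * b_n * rge$kappa_env * rge$gamma_passive * 0.5 +
        (rge$gxe_cog^2 + rge$gxe_noncog^2) * 1.05
      stop_if_not(signal_var < 1,
                  "variance budget exceeded: rGE paths imply variance > 1")
      y <- b_c * gcog + b_n * gnon + rge$kappa_env * fenv +
        rge$gxe_cog * gcog * ses_t + rge$gxe_noncog * gnon * ses_t +
        sqrt(1 - signal_var) * stats::rnorm(n)
      per_age[[t]] <- data.frame(
        id = twins$id, family_id = twins$family_id, role = twins$role,
        zygosity = twins$zygosity, age = ages[t],
        achievement = zstd(y),
        cog_phen = zstd(0.7 * gcog + sqrt(1 - 0.49) * stats::rnorm(n)),
        noncog_phen = zstd(0.6 * gnon + 0.2 * fenv +
                             sqrt(0.6) * stats::rnorm(n)),
        ses = ses_t,
        covs, pcs,
        g_cog = gcog, g_noncog = gnon,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, per_age)
    rownames(out) <- NULL
    class(out) <- c("cohort_phenotypes", "data.frame")
    out
  })
}
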