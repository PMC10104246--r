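#' Two-factor Cog/NonCog genetic architecture for the discovery GWAS
#'
#' Describes how eight indicator traits load on two orthogonal latent genetic
#' factors: a cognitive factor (Cog) on which all traits may load, and a
#' noncognitive factor (NonCog) restricted to educational attainment and the
#' two socioeconomic indicators. Five cognitive-test traits (cognitive
#' performance `CP`, symbol digit `SD`, memory `ME`, trail making `TM`,
#' reaction time `RT`) load exclusively on Cog; educational attainment `EA`,
#' income `IN` and deprivation `DE` load on both factors.
#'
#' Per-trait SNP heritability is `cog_loadings^2 + noncog_loadings^2 +
#' residual_h2`; defaults give heritabilities in the 0.2-0.45 range typical
#' of biobank-scale behavioural GWAS.
#'
#' @param trait_names Labels for the eight indicator traits.
#' @param cog_loadings Loading of each trait on the Cog genetic factor.
#' @param noncog_loadings Loading on the NonCog factor; must be zero for the
#'   five cognitive traits.
#' @param residual_h2 Trait-specific genetic variance not shared with either
#'   factor.
#' @param n_causal Number of causal SNPs per factor; `NULL` means all SNPs
#'   (infinitesimal architecture).
#' @return An object of class `factor_architecture`.
#' @export
factor_architecture <- function(trait_names = c("CP", "SD", "ME", "TM", "RT",
                                                "EA", "IN", "DE"),
                                cog_loadings = c(0.60, 0.45, 0.40, 0.45, 0.35,
                                                 0.35, 0.20, 0.25),
                                noncog_loadings = c(0, 0, 0, 0, 0,
                                                    0.45, 0.40, 0.35),
                                residual_h2 = rep(0.05, 8),
                                n_causal = NULL) {
  k <- length(trait_names)
  stop_if_not(length(cog_loadings) == k && length(noncog_loadings) == k &&
                length(residual_h2) == k,
              "architecture vectors must all have one entry per trait")
  h2 <- cog_loadings^2 + noncog_loadings^2 + residual_h2
  stop_if_not(all(h2 <= 1 + 1e-12),
              "per-trait total genetic variance (cog^2 + noncog^2 + residual) must be <= 1")
  stop_if_not(all(residual_h2 >= 0), "residual_h2 must be nonnegative")
  structure(
    list(trait_names = trait_names,
         cog_loadings = stats::setNames(cog_loadings, trait_names),
         noncog_loadings = stats::setNames(noncog_loadings, trait_names),
         residual_h2 = stats::setNames(residual_h2, trait_names),
         h2 = stats::setNames(h2, trait_names),
         n_causal = n_causal),
    class = "factor_architecture")
}

#' Gene-environment correlation configuration
#'
#' Parameters of the generative model for developmental achievement. Each
#' child's achievement at age \eqn{t} is
#' \deqn{y_t = b_{cog}(t) G_{cog} + (b_{noncog}(t) + \lambda(t)) G_{noncog}
#'       + \kappa F + \epsilon_t,}
#' where \eqn{F = \gamma \cdot \mathrm{midparent}(G_{noncog}) + u} is a family
#' environment built from the parents' noncognitive genetic values (passive
#' rGE) and \eqn{\lambda(t)} is an age-indexed path from the child's own
#' noncognitive genetic value routed through the environment the child evokes
#' or selects (evocative/active rGE). Observed SES loads on the same family
#' environment.
#'
#' Defaults encode the study conditions: a flat cognitive path (0.24 at every
#' age), a constant direct noncognitive path of 0.10, and an active path
#' rising from 0 at age 7 to 0.12 at age 16, so the total child-side
#' noncognitive effect grows from 0.10 to 0.22 across ages while the
#' passive-rGE contribution through the family environment adds about
#' \eqn{\kappa\gamma/2 = 0.10} at the population level.
#'
#' @param b_cog,b_noncog Direct genetic paths per age (length must match the
#'   configured ages).
#' @param lambda_active Age-indexed active/evocative path from the child's
#'   own NonCog genetic value; monotone nondecreasing in the default scenario.
#' @param gamma_passive Weight of the mid-parent NonCog genetic value on the
#'   family environment.
#' @param kappa_env Path from family environment to achievement.
#' @param ses_loading Path from family environment to observed SES.
#' @param gxe_cog,gxe_noncog Coefficients of injected PGS-by-SES interactions
#'   (0 = no interaction, the default generative model).
#' @return An object of class `rge_config`.
#' @export
rge_config <- function(b_cog = c(0.24, 0.24, 0.24, 0.24),
                       b_noncog = c(0.10, 0.10, 0.10, 0.10),
                       lambda_active = c(0.00, 0.04, 0.08, 0.12),
                       gamma_passive = 0.5,
                       kappa_env = 0.4,
                       ses_loading = 0.7,
                       gxe_cog = 0,
                       gxe_noncog = 0) {
  stop_if_not(length(b_cog) == length(b_noncog) &&
                length(b_cog) == length(lambda_active),
              "b_cog, b_noncog and lambda_active must have equal length (one per age)")
  structure(
    list(b_cog = b_cog, b_noncog = b_noncog, lambda_active = lambda_active,
         gamma_passive = gamma_passive, kappa_env = kappa_env,
         ses_loading = ses_loading, gxe_cog = gxe_cog,
         gxe_noncog = gxe_noncog),
    class = "rge_config")
}

#' Default ACE configuration for the twin-phenotype simulator
#'
#' One row per (domain, rater, age) cell giving the latent factor's variance
#' decomposition and a simple measurement model (equal indicator loadings,
#' residual variance split over indicator-specific A/C/E). The
#' parent-reported education-specific noncognitive cell at age 9 is generated
#' with a latent heritability of 0.93, the strongest latent heritability the
#' simulator emulates; other cells use moderate values typical of cognitive
#' and achievement measures.
#'
#' @param ages Ages at which twin data are simulated.
#' @return A data frame with columns `domain`, `rater`, `age`, `a2`, `c2`,
#'   `e2`, `n_indicators`, `loading`, and the residual A/C/E split
#'   (`res_a2`, `res_c2`, `res_e2`, proportions of each indicator's residual
#'   variance).
#' @export
default_ace_config <- function(ages = c(7, 9, 12, 16)) {
  grid <- expand.grid(domain = c("g", "noncog_edu", "selfreg", "achievement"),
                      age = ages, stringsAsFactors = FALSE)
  grid$rater <- ifelse(grid$domain == "achievement", "teacher", "parent")
  comp <- list(
    g           = c(0.50, 0.20, 0.30),
    noncog_edu  = c(0.60, 0.20, 0.20),
    selfreg     = c(0.50, 0.25, 0.25),
    achievement = c(0.60, 0.20, 0.20)
  )
  m <- t(vapply(grid$domain, function(d) comp[[d]], numeric(3)))
  grid$a2 <- m[, 1]; grid$c2 <- m[, 2]; grid$e2 <- m[, 3]
  hot <- grid$domain == "noncog_edu" & grid$age == 9
  grid$a2[hot] <- 0.93; grid$c2[hot] <- 0.03; grid$e2[hot] <- 0.04
  grid$n_indicators <- ifelse(grid$domain == "achievement", 3L, 4L)
  grid$loading <- c(g = 0.75, noncog_edu = 0.70, selfreg = 0.65,
                    achievement = 0.80)[grid$domain]
  grid$res_a2 <- 0.25; grid$res_c2 <- 0.10; grid$res_e2 <- 0.65
  grid[, c("domain", "rater", "age", "a2", "c2", "e2", "n_indicators",
           "loading", "res_a2", "res_c2", "res_e2")]
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data engine. Defaults are the
#' desk-scale study conditions: 5000 SNPs in 50 LD blocks, a discovery GWAS
#' cohort of 10000 per trait, and 2000 twin families with a 1/3 MZ : 2/3 DZ
#' mix.
#'
#' @param seed Master seed; all stage seeds are derived from it
#'   deterministically.
#' @param n_snps Number of SNPs (`M` in the LD-score-regression denominator).
#' @param n_blocks Number of contiguous LD blocks; must divide `n_snps`.
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param ld_decay Maximum adjacent-SNP latent haplotype correlation (AR(1)
#'   parameter `rho`), in \[0, 1); blocks grade from no LD up to this value.
#' @param n_discovery GWAS discovery sample size per trait.
#' @param n_families Number of twin families in the target cohort.
#' @param prop_mz Proportion of MZ twin pairs.
#' @param architecture A [factor_architecture()].
#' @param ace_config Data frame as produced by [default_ace_config()].
#' @param rge_config An [rge_config()].
#' @param ages Age labels for the developmental waves.
#' @param sample_overlap Fraction of the discovery cohort shared between
#'   traits (0 = independent cohorts per trait, the default; 1 = a single
#'   shared cohort, which induces nonzero cross-trait LDSC intercepts).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_snps = 5000L,
                       n_blocks = 100L,
                       maf_range = c(0.05, 0.5),
                       ld_decay = 0.9,
                       n_discovery = 10000L,
                       n_families = 2000L,
                       prop_mz = 1 / 3,
                       architecture = factor_architecture(),
                       ace_config = default_ace_config(ages),
                       rge_config = noncogdev::rge_config(),
                       ages = c(7, 9, 12, 16),
                       sample_overlap = 0) {
  stop_if_not(n_snps %% n_blocks == 0,
              "n_snps must divide into n_blocks contiguous blocks")
  stop_if_not(maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2],
              "maf_range must lie within (0, 0.5]")
  stop_if_not(ld_decay >= 0 && ld_decay < 1, "ld_decay must be in [0, 1)")
  stop_if_not(prop_mz >= 0 && prop_mz <= 1, "prop_mz must be in [0, 1]")
  stop_if_not(length(rge_config$b_cog) == length(ages),
              "rge_config paths must have one entry per age")
  ok <- abs(ace_config$a2 + ace_config$c2 + ace_config$e2 - 1) < 1e-8
  stop_if_not(all(ok), "each ace_config row must satisfy a2 + c2 + e2 = 1")
  structure(
    list(seed = as.integer(seed), n_snps = as.integer(n_snps),
         n_blocks = as.integer(n_blocks), maf_range = maf_range,
         ld_decay = ld_decay, n_discovery = as.integer(n_discovery),
         n_families = as.integer(n_families), prop_mz = prop_mz,
         architecture = architecture, ace_config = ace_config,
         rge_config = rge_config, ages = ages,
         sample_overlap = sample_overlap),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  seed %d | M = %d SNPs in %d blocks (rho = %.2f, MAF %.2f-%.2f)\n",
              x$seed, x$n_snps, x$n_blocks, x$ld_decay,
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  discovery N = %d per trait | %d families (%.0f%% MZ)\n",
              x$n_discovery, x$n_families, 100 * x$prop_mz))
  cat(sprintf("  ages: %s\n", paste(x$ages, collapse = ", ")))
  invisible(x)
}

#' True per-SNP factor effects implied by a configuration
#'
#' Draws (deterministically, from the configuration's derived effects seed)
#' the per-SNP effect sizes of the Cog and NonCog genetic factors and the
#' eight trait-specific residual effect vectors, on the standardized-genotype
#' scale. Both the discovery-cohort simulator and the family-panel simulator
#' regenerate the identical draw, so ground truth is shared across cohorts.
#'
#' @param config A [sim_config()].
#' @return A list with `u_cog`, `u_noncog` (length-M vectors) and `u_resid`
#'   (M x traits matrix).
#' @export
true_effects <- function(config) {
  M <- config$n_snps
  arch <- config$architecture
  k <- length(arch$trait_names)
  nc <- arch$n_causal %||% M
  stop_if_not(nc >= 1 && nc <= M, "n_causal must be in [1, n_snps]")
  with_seed(derive_seed(config$seed, "effects"), {
    draw <- function() {
      u <- numeric(M)
      idx <- if (nc == M) seq_len(M) else sort(sample.int(M, nc))
      u[idx] <- stats::rnorm(nc, sd = sqrt(1 / nc))
      u
    }
    u_cog <- draw()
    u_noncog <- draw()
    u_resid <- vapply(seq_len(k), function(i) draw(), numeric(M))
    colnames(u_resid) <- arch$trait_names
    list(u_cog = u_cog, u_noncog = u_noncog, u_resid = u_resid)
  })
}
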