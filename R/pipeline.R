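# End-to-end orchestration of the synthetic study: simulate -> phenotypic ->
# twin -> genomic SEM -> PGS -> family -> G x E, with every intermediate
# written in the package's interchange dialects and a plain-text report.

#' Pipeline configuration
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory for the run.
#' @param stages Named logical vector toggling stages (`simulate`, `twin`,
#'   `ldsc`, `gsem`, `pgs`, `family`, `gxe`).
#' @param n_blocks Jackknife blocks for LDSC.
#' @param weights_dir Optional directory with pre-computed factor weights
#'   (`cog.weights.tsv`, `noncog.weights.tsv`) used when the `gsem` stage is
#'   toggled off.
#' @param write_genotypes Write the (large) PLINK-.raw-style dosage table.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = "noncogdev_run",
                            stages = c(simulate = TRUE, twin = TRUE,
                                       ldsc = TRUE, gsem = TRUE, pgs = TRUE,
                                       family = TRUE, gxe = TRUE),
                            n_blocks = 50, weights_dir = NULL,
                            write_genotypes = TRUE) {
  defaults <- c(simulate = TRUE, twin = TRUE, ldsc = TRUE, gsem = TRUE,
                pgs = TRUE, family = TRUE, gxe = TRUE)
  defaults[names(stages)] <- stages
  structure(list(sim = sim, out_dir = out_dir, stages = defaults,
                 n_blocks = n_blocks, weights_dir = weights_dir,
                 write_genotypes = write_genotypes),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys `out_dir`, `n_blocks`, `stages` (map of stage: true/false),
#' `write_genotypes`, and `sim` (any [sim_config()] argument; `rge` keys are
#' forwarded to [rge_config()]).
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$rge)) {
    sim_args$rge_config <- do.call(rge_config, sim_args$rge)
    sim_args$rge <- NULL
  }
  sim <- do.call(sim_config, sim_args)
  stages <- unlist(y$stages %||% list())
  pipeline_config(sim = sim, out_dir = y$out_dir %||% "noncogdev_run",
                  stages = if (length(stages)) stages else
                    c(simulate = TRUE),
                  n_blocks = y$n_blocks %||% 50,
                  weights_dir = y$weights_dir,
                  write_genotypes = y$write_genotypes %||% TRUE)
}

stage_msg <- function(report, stage, status, note = "") {
  report$status <- rbind(report$status,
                         data.frame(stage = stage, status = status,
                                    note = note, stringsAsFactors = FALSE))
  report
}

#' Run the full synthetic-study pipeline
#'
#' Executes the enabled stages in order, writing intermediates under the
#' configured output directory (`genotypes/`, `phenotypes/`, `sumstats/`,
#' `fits/`) and a plain-text `report.md`. All randomness flows from the
#' simulation configuration's seed, so re-running with an identical
#' configuration reproduces the outputs bit for bit. Stage warnings
#' (Heywood, smoothing, truncation, convergence) are collected into the
#' report.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report` with per-stage status, key estimate
#'   tables, ground-truth comparison tables and collected warnings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  out <- config$out_dir
  st <- config$stages
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(status = NULL, tables = list(), warnings = character(),
                 config = config)
  grab <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      report$warnings <<- c(report$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }, message = function(m) {
      report$warnings <<- c(report$warnings,
                            sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  }

  ld <- panel <- pheno <- twin <- set <- gc_ <- fit <- effects <- NULL
  weights <- scores <- cohort <- NULL

  # -- simulate ------------------------------------------------------------
  if (st[["simulate"]]) {
    ld <- grab(build_ld_reference(sim))
    panel <- grab(simulate_genotype_panel(sim, ld))
    pheno <- grab(simulate_developmental_outcomes(panel, sim))
    twin <- grab(simulate_twin_phenotypes(sim))
    dir.create(file.path(out, "genotypes"), showWarnings = FALSE)
    dir.create(file.path(out, "phenotypes"), showWarnings = FALSE)
    write_ld_scores(ld, file.path(out, "genotypes", "ldscores.tsv"))
    if (config$write_genotypes)
      write_genotype_raw(panel, file.path(out, "genotypes", "panel.raw"))
    write_phenotypes(pheno, file.path(out, "phenotypes", "cohort.csv"))
    write_phenotypes(twin, file.path(out, "phenotypes", "twins.csv"))
    report <- stage_msg(report, "simulate", "ok",
                        sprintf("%d SNPs, %d families", sim$n_snps,
                                sim$n_families))
  }

  # -- twin ----------------------------------------------------------------
  if (st[["twin"]]) {
    stop_if_not(!is.null(twin), "twin stage needs the simulate stage")
    ic <- grab(intraclass_correlations(twin, "achievement.1",
                                       age = sim$ages[1]))
    falc <- falconer_estimates(ic)
    uni <- grab(fit_ace(twin, "achievement.1", "univariate",
                        age = sim$ages[1]))
    cp_row <- sim$ace_config[sim$ace_config$domain == "noncog_edu" &
                               sim$ace_config$age == 9, ][1, ]
    cp <- grab(fit_ace(twin, paste0("noncog_edu.",
                                    seq_len(cp_row$n_indicators)),
                       "common_pathway", age = 9, rater = cp_row$rater))
    tri_truth <- trivariate_ace_matrices()
    tri_cohort <- simulate_twin_multivariate(
      round(sim$prop_mz * sim$n_families),
      sim$n_families - round(sim$prop_mz * sim$n_families),
      tri_truth$A, tri_truth$C, tri_truth$E,
      trait_names = c("cog", "noncog", "achievement"),
      seed = derive_seed(sim$seed, "twins") + 7L)
    tri <- grab(fit_ace(tri_cohort, c("cog", "noncog", "achievement"),
                        "cholesky"))
    shares <- variance_shares_from_cholesky(tri)
    twin_tab <- data.frame(
      model = c("intraclass", "intraclass", "falconer", "falconer",
                "falconer", "univariate_ml", "univariate_ml",
                "univariate_ml", "common_pathway", "cholesky", "cholesky",
                "cholesky"),
      parameter = c("rMZ", "rDZ", "A", "C", "E", "A", "C", "E",
                    "latent_a2", "share_cog", "share_noncog_independent",
                    "share_achievement_specific"),
      estimate = c(ic$r_mz, ic$r_dz, falc$A, falc$C, falc$E,
                   uni$std$A[1, 1], uni$std$C[1, 1], uni$std$E[1, 1],
                   cp$latent[["a2"]], shares$share_cog,
                   shares$share_noncog_independent,
                   shares$share_achievement_specific),
      truth = c(NA, NA, NA, NA, NA, 0.60, 0.20, 0.20, 0.93,
                tri_truth$shares[1], tri_truth$shares[2],
                tri_truth$shares[3]),
      stringsAsFactors = FALSE)
    report$tables$twin <- twin_tab
    dir.create(file.path(out, "fits"), showWarnings = FALSE)
    utils::write.csv(twin_tab, file.path(out, "fits", "twin_models.csv"),
                     row.names = FALSE, quote = FALSE)
    report <- stage_msg(report, "twin", "ok",
                        sprintf("%d MZ / %d DZ pairs", uni$n_mz, uni$n_dz))
  }

  # -- ldsc / gsem ---------------------------------------------------------
  if (st[["ldsc"]] || st[["gsem"]]) {
    stop_if_not(!is.null(ld), "ldsc stage needs the simulate stage")
    set <- grab(simulate_discovery_sumstats(sim, ld))
    write_sumstats(set, file.path(out, "sumstats"))
  }
  if (st[["ldsc"]]) {
    gc_ <- grab(build_genetic_covariance(set, ld, config$n_blocks))
    if (gc_$smoothed_S) report$warnings <- c(report$warnings,
                                             "S smoothed to nearest PSD")
    h2_tab <- data.frame(
      trait = gc_$traits,
      h2 = diag(gc_$S),
      h2_se = vapply(gc_$univariate, function(u) u$h2_se, numeric(1)),
      intercept = vapply(gc_$univariate, function(u) u$intercept, numeric(1)),
      truth = sim$architecture$h2,
      stringsAsFactors = FALSE)
    report$tables$ldsc <- h2_tab
    dir.create(file.path(out, "fits"), showWarnings = FALSE)
    utils::write.csv(data.frame(trait = rownames(gc_$S), gc_$S),
                     file.path(out, "fits", "S_matrix.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(entry = gc_$vech_names, gc_$V,
                                check.names = FALSE),
                     file.path(out, "fits", "V_matrix.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(traits = gc_$traits,
                              n_blocks = gc_$n_blocks, M = gc_$M,
                              smoothed_S = gc_$smoothed_S,
                              smoothed_V = gc_$smoothed_V),
                         file.path(out, "fits", "SV_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(h2_tab, file.path(out, "fits", "ldsc_h2.csv"),
                     row.names = FALSE, quote = FALSE)
    report <- stage_msg(report, "ldsc", "ok",
                        sprintf("%d traits, %d blocks", length(gc_$traits),
                                gc_$n_blocks))
  }
  if (st[["gsem"]]) {
    stop_if_not(!is.null(gc_), "gsem stage needs the ldsc stage")
    model <- path_model(traits = gc_$traits,
                        noncog = intersect(c("EA", "IN", "DE"), gc_$traits))
    fit <- grab(fit_path_model(gc_, model))
    effects <- grab(gwas_by_subtraction(gc_, set, fit))
    write_snp_effects(effects, file.path(out, "sumstats"))
    gsem_tab <- data.frame(
      parameter = names(fit$estimates),
      estimate = unname(fit$estimates), se = unname(fit$se),
      stringsAsFactors = FALSE)
    report$tables$gsem <- gsem_tab
    utils::write.csv(gsem_tab, file.path(out, "fits", "gsem_model.csv"),
                     row.names = FALSE, quote = FALSE)
    report <- stage_msg(report, "gsem", "ok",
                        sprintf("discrepancy %.4g, SRMR %.4f",
                                fit$discrepancy, fit$srmr))
  }

  # -- pgs -----------------------------------------------------------------
  if (st[["pgs"]]) {
    stop_if_not(!is.null(panel), "pgs stage needs the simulate stage")
    if (is.null(effects)) {
      stop_if_not(!is.null(config$weights_dir),
                  "missing weights input: enable the gsem stage or supply weights_dir")
      wc <- read_pgs_weights(file.path(config$weights_dir,
                                       "cog.weights.tsv"))
      wn <- read_pgs_weights(file.path(config$weights_dir,
                                       "noncog.weights.tsv"))
      weights <- list(cog = wc, noncog = wn)
      class(weights$cog) <- c("pgs_weights", "data.frame")
      class(weights$noncog) <- c("pgs_weights", "data.frame")
    } else {
      weights <- list()
      for (f in c("cog", "noncog")) {
        fs <- factor_sumstats(effects, f)
        h2f <- grab(ldsc_univariate(fs, ld, config$n_blocks))$h2
        h2f <- min(max(h2f, 0.05), 1)
        weights[[f]] <- grab(ldpred_inf_weights(fs, ld, h2 = h2f))
      }
    }
    write_pgs_weights(weights$cog, file.path(out, "fits", "cog.weights.tsv"))
    write_pgs_weights(weights$noncog,
                      file.path(out, "fits", "noncog.weights.tsv"))
    scores <- grab(score_individuals(panel, list(weights$cog,
                                                 weights$noncog),
                                     names = c("pgs_cog", "pgs_noncog")))
    cohort <- scored_cohort(scores, pheno)
    write_phenotypes(cohort, file.path(out, "phenotypes", "scored.csv"))
    prof <- grab(pgs_developmental_profile(cohort, seed = sim$seed))
    report$tables$pgs <- prof
    utils::write.csv(prof, file.path(out, "fits", "pgs_profile.csv"),
                     row.names = FALSE, quote = FALSE)
    report <- stage_msg(report, "pgs", "ok",
                        sprintf("%d ages analysed", length(unique(prof$age))))
  }

  # -- family --------------------------------------------------------------
  if (st[["family"]]) {
    stop_if_not(!is.null(cohort), "family stage needs the pgs stage")
    dec <- decompose_within_between(cohort)
    fam_rows <- lapply(sim$ages, function(a) {
      wf <- fit_within_between_model(cohort, dec, age = a)
      data.frame(age = a, term = names(wf$beta), beta = unname(wf$beta),
                 se = unname(wf$se), stringsAsFactors = FALSE)
    })
    fam_tab <- do.call(rbind, fam_rows)
    report$tables$family <- fam_tab
    utils::write.csv(fam_tab, file.path(out, "fits", "within_between.csv"),
                     row.names = FALSE, quote = FALSE)
    report <- stage_msg(report, "family", "ok",
                        sprintf("%d DZ families",
                                length(unique(dec$family_id))))
  }

  # -- gxe -----------------------------------------------------------------
  if (st[["gxe"]]) {
    stop_if_not(!is.null(cohort), "gxe stage needs the pgs stage")
    last_age <- sim$ages[length(sim$ages)]
    gxe <- grab(gxe_model(cohort, age = last_age, seed = sim$seed))
    keep <- gxe$terms$interaction |
      gxe$terms$term %in% c("pgs_cog", "pgs_noncog", "ses")
    gxe_tab <- cbind(age = last_age, gxe$terms[keep, , drop = FALSE])
    report$tables$gxe <- gxe_tab
    report$tables$slopes <- cbind(
      pgs = rep(c("pgs_cog", "pgs_noncog"), each = 4),
      rbind(slopes_by_ses(gxe, "pgs_cog"), slopes_by_ses(gxe, "pgs_noncog")))
    utils::write.csv(gxe_tab, file.path(out, "fits", "gxe.csv"),
                     row.names = FALSE, quote = FALSE)
    report <- stage_msg(report, "gxe", "ok",
                        sprintf("age %s, %d interaction terms", last_age,
                                sum(gxe$terms$interaction)))
  }

  class(report) <- "run_report"
  write_report(report, file.path(out, "report.md"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  print(x$status, row.names = FALSE)
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in unique(x$warnings)) cat("  -", w, "\n")
  }
  invisible(x)
}

write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# Synthetic study run report")
  wl("")
  wl("## Stage status")
  wl("")
  if (!is.null(report$status)) {
    for (i in seq_len(nrow(report$status))) {
      wl("- ", report$status$stage[i], ": ", report$status$status[i],
         " (", report$status$note[i], ")")
    }
  }
  for (nm in names(report$tables)) {
    wl("")
    wl("## ", nm)
    wl("")
    tb <- report$tables[[nm]]
    num <- vapply(tb, is.numeric, logical(1))
    tb[num] <- lapply(tb[num], function(v) round(v, 4))
    hdr <- paste(names(tb), collapse = " | ")
    wl(hdr)
    wl(paste(rep("---", ncol(tb)), collapse = " | "))
    for (i in seq_len(nrow(tb))) {
      wl(paste(vapply(tb[i, ], as.character, character(1)),
               collapse = " | "))
    }
  }
  wl("")
  wl("## Warnings")
  wl("")
  if (length(report$warnings)) {
    for (w in unique(report$warnings)) wl("- ", w)
  } else {
    wl("- none")
  }
  invisible(path)
}
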