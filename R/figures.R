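#' Render the report's summary figures
#'
#' Produces the study's figure analogues from a completed run report:
#' stacked variance-share bars from the trivariate Cholesky decomposition,
#' PGS-effect-by-age lines, within/between-family effect bars, and simple
#' slopes of achievement on the PGS at different SES levels. Figures whose
#' stage is missing from the report are skipped with a notice.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory for PDF files.
#' @return Invisibly, the paths of the figures written.
#' @export
make_figures <- function(report, dir = file.path(report$config$out_dir,
                                                 "figures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  skip <- function(nm) message("figure skipped (missing stage table): ", nm)

  tw <- report$tables$twin
  if (!is.null(tw)) {
    path <- file.path(dir, "variance_shares.pdf")
    grDevices::pdf(path, width = 5, height = 4)
    sh <- tw$estimate[match(c("share_cog", "share_noncog_independent",
                              "share_achievement_specific"), tw$parameter)]
    graphics::barplot(matrix(sh, 3, 1),
                      col = c("gold", "orange", "firebrick"),
                      names.arg = "achievement",
                      ylab = "proportion of variance",
                      main = "Genetic variance in achievement")
    graphics::legend("topright",
                     legend = c("Cog-shared", "NonCog beyond Cog",
                                "achievement-specific"),
                     fill = c("gold", "orange", "firebrick"), bty = "n",
                     cex = 0.8)
    grDevices::dev.off()
    written <- c(written, path)
  } else skip("variance_shares")

  pg <- report$tables$pgs
  if (!is.null(pg)) {
    path <- file.path(dir, "pgs_by_age.pdf")
    grDevices::pdf(path, width = 5, height = 4)
    ages <- sort(unique(pg$age))
    bc <- pg$beta[pg$term == "pgs_cog"][order(unique(pg$age))]
    bn <- pg$beta[pg$term == "pgs_noncog"][order(unique(pg$age))]
    rng <- range(0, bc, bn)
    graphics::plot(ages, bc, type = "b", pch = 16, col = "steelblue",
                   ylim = rng + c(0, 0.05), xlab = "age",
                   ylab = "standardized beta",
                   main = "PGS prediction of achievement")
    graphics::lines(ages, bn, type = "b", pch = 17, col = "darkorange")
    graphics::legend("topleft", legend = c("Cog PGS", "NonCog PGS"),
                     col = c("steelblue", "darkorange"), pch = c(16, 17),
                     bty = "n")
    grDevices::dev.off()
    written <- c(written, path)
  } else skip("pgs_by_age")

  fam <- report$tables$family
  if (!is.null(fam)) {
    path <- file.path(dir, "within_between.pdf")
    grDevices::pdf(path, width = 6, height = 4)
    ages <- sort(unique(fam$age))
    terms <- unique(fam$term)
    mat <- vapply(terms, function(tm) {
      fam$beta[fam$term == tm][order(fam$age[fam$term == tm])]
    }, numeric(length(ages)))
    graphics::barplot(t(mat), beside = TRUE, names.arg = ages,
                      col = grDevices::hcl.colors(length(terms), "Zissou 1"),
                      xlab = "age", ylab = "standardized beta",
                      main = "Between vs within family PGS effects")
    graphics::legend("topleft", legend = terms, bty = "n", cex = 0.7,
                     fill = grDevices::hcl.colors(length(terms), "Zissou 1"))
    grDevices::dev.off()
    written <- c(written, path)
  } else skip("within_between")

  sl <- report$tables$slopes
  if (!is.null(sl)) {
    path <- file.path(dir, "slopes_by_ses.pdf")
    grDevices::pdf(path, width = 5, height = 4)
    graphics::plot(NULL, xlim = range(sl$ses_value),
                   ylim = range(sl$slope) + c(-0.05, 0.05),
                   xlab = "SES (standardized)", ylab = "PGS slope",
                   main = "PGS slopes across SES")
    for (p in unique(sl$pgs)) {
      d <- sl[sl$pgs == p, ]
      graphics::lines(d$ses_value, d$slope, type = "b",
                      col = if (p == "pgs_cog") "steelblue" else "darkorange",
                      pch = 16)
    }
    graphics::legend("topleft", legend = unique(sl$pgs),
                     col = c("steelblue", "darkorange"), pch = 16, bty = "n")
    grDevices::dev.off()
    written <- c(written, path)
  } else skip("slopes_by_ses")

  if (!length(written)) message("empty report: no figures written")
  invisible(written)
}
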