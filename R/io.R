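# Readers and writers for the interchange dialects used by the pipeline:
# PLINK-.raw-style dosage tables, LDSC-style sumstats TSVs, LD-score TSVs,
# PGS-weight TSVs and long-format phenotype CSVs. All writers produce
# deterministic plain text (no timestamps, fixed column order).

#' Write a genotype panel as a PLINK-.raw-style dosage table
#'
#' Columns `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP
#' named `<SNPID>_<A1>` holding counts of allele A1 in 0/1/2.
#'
#' @param panel A [simulate_genotype_panel()] result.
#' @param path Output file.
#' @export
write_genotype_raw <- function(panel, path) {
  meta <- panel$meta
  pat <- ifelse(meta$role %in% c("twin1", "twin2"),
                paste0(meta$family_id, "_P1"), "0")
  mat <- ifelse(meta$role %in% c("twin1", "twin2"),
                paste0(meta$family_id, "_P2"), "0")
  hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
           paste(panel$snp_info$snp, panel$snp_info$a1, sep = "_"))
  lead <- data.frame(FID = meta$family_id, IID = meta$id, PAT = pat,
                     MAT = mat, SEX = meta$sex, PHENOTYPE = -9,
                     stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  body <- cbind(as.matrix(lead), panel$geno)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PLINK-.raw-style dosage table
#'
#' @param path File written by [write_genotype_raw()] (or any `.raw` export
#'   with the standard six leading columns).
#' @return A list with `meta` (FID/IID/PAT/MAT/SEX), `geno` (numeric matrix),
#'   and `snp_info` (`snp`, `a1` parsed from the header).
#' @export
read_genotype_raw <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  lead <- d[, 1:6]
  geno <- as.matrix(d[, -(1:6), drop = FALSE])
  nm <- colnames(geno)
  a1 <- sub(".*_", "", nm)
  snp <- sub("_[^_]*$", "", nm)
  rownames(geno) <- lead$IID
  list(meta = lead, geno = geno,
       snp_info = data.frame(snp = snp, a1 = a1, stringsAsFactors = FALSE))
}

#' Write LDSC-style summary statistics, one TSV per trait
#'
#' @param set A [sumstats_set()].
#' @param dir Output directory; files are named `<trait>.sumstats.tsv`.
#' @export
write_sumstats <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in set$traits) {
    utils::write.table(set$tables[[tr]][, c("SNP", "A1", "A2", "Z", "N")],
                       file.path(dir, paste0(tr, ".sumstats.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(set$snp_info)) {
    utils::write.table(set$snp_info,
                       file.path(dir, "snp_info.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read LDSC-style summary statistics
#'
#' @param files Named character vector of sumstats TSV paths (names become
#'   trait labels; unnamed paths are labelled from the file name).
#' @param snp_info_file Optional SNP metadata TSV (as written by
#'   [write_sumstats()]).
#' @return A [sumstats_set()].
#' @export
read_sumstats <- function(files, snp_info_file = NULL) {
  nm <- names(files) %||% rep("", length(files))
  nm[nm == ""] <- sub("\\.sumstats\\.tsv$", "", basename(files[nm == ""]))
  tables <- stats::setNames(lapply(files, function(f) {
    utils::read.table(f, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }), nm)
  snp_info <- if (!is.null(snp_info_file)) {
    utils::read.table(snp_info_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  sumstats_set(tables, snp_info = snp_info)
}

#' Write LD scores as a TSV (CHR = block id, SNP, BP = index, L2)
#' @param ld An [build_ld_reference()] result.
#' @param path Output file.
#' @export
write_ld_scores <- function(ld, path) {
  utils::write.table(
    data.frame(CHR = ld$snp_info$block, SNP = ld$snp_info$snp,
               BP = ld$snp_info$bp, L2 = ld$ldscores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD-score TSV (columns CHR SNP BP L2)
#' @param path File path.
#' @return Data frame with those columns.
#' @export
read_ld_scores <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write PGS weights as a TSV (SNP A1 WEIGHT)
#' @param weights A `pgs_weights` data frame from [ldpred_inf_weights()].
#' @param path Output file.
#' @export
write_pgs_weights <- function(weights, path) {
  utils::write.table(weights[, c("SNP", "A1", "WEIGHT")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PGS-weights TSV
#' @param path File path.
#' @return Data frame with columns SNP, A1, WEIGHT.
#' @export
read_pgs_weights <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write phenotypes (long format, one row per individual per age) as CSV
#' @param phenotypes A `cohort_phenotypes` or `twin_cohort` data frame.
#' @param path Output file.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV written by [write_phenotypes()]
#' @param path File path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
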