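#' Simulate a family-structured genotype panel
#'
#' Generates nuclear twin families: two parents per family, each composed of
#' two haplotypes drawn under the LD reference, and two children who each
#' receive one haplotype per parent with free recombination between LD blocks
#' and none within. MZ pairs duplicate the first child's genotype exactly;
#' DZ co-twins draw independent transmissions and therefore share each
#' parental transmission with probability 1/2. True Cog and NonCog genetic
#' values are computed from the architecture's per-SNP effects on the
#' standardized-genotype scale and standardized against the parent
#' (founder) distribution.
#'
#' @param config A [sim_config()].
#' @param ld An [build_ld_reference()] reference built from the same
#'   configuration.
#' @return An object of class `genotype_panel` with elements `meta`
#'   (individual id, family id, role, zygosity, sex), `geno` (individuals x
#'   SNPs allele-count matrix in 0/1/2, counts of allele A1), `snp_info`,
#'   `g_cog`, `g_noncog`, and `transmissions` (per-block transmission choices
#'   for each twin, used to audit meiotic sharing).
#' @export
simulate_genotype_panel <- function(config, ld) {
  F_ <- config$n_families
  M <- config$n_snps
  stop_if_not(nrow(ld$snp_info) == M,
              "LD reference does not match config n_snps")
  eff <- true_effects(config)

  with_seed(derive_seed(config$seed, "panel"), {
    n_mz <- round(config$prop_mz * F_)
    zyg <- c(rep("MZ", n_mz), rep("DZ", F_ - n_mz))

    # Parent haplotypes: rows 4f-3..4f belong to family f
    # (parent1 hap a/b, parent2 hap a/b).
    Hp <- sample_haplotypes(4L * F_, ld)

    B <- length(ld$blocks)
    # Transmission indicators: 0 = first parental haplotype, 1 = second,
    # one choice per family x block x parent x twin.
    draw_trans <- function() matrix(sample(0:1, F_ * B, TRUE), F_, B)
    S <- list(t1p1 = draw_trans(), t1p2 = draw_trans(),
              t2p1 = draw_trans(), t2p2 = draw_trans())
    mz <- zyg == "MZ"
    S$t2p1[mz, ] <- S$t1p1[mz, ]
    S$t2p2[mz, ] <- S$t1p2[mz, ]

    child_geno <- function(Sp1, Sp2) {
      G <- matrix(0L, F_, M)
      base1 <- 4L * (seq_len(F_) - 1L) + 1L # parent1 hap a row
      base2 <- base1 + 2L                   # parent2 hap a row
      for (b in seq_len(B)) {
        idx <- ld$blocks[[b]]
        G[, idx] <- Hp[base1 + Sp1[, b], idx, drop = FALSE] +
          Hp[base2 + Sp2[, b], idx, drop = FALSE]
      }
      G
    }
    G1 <- child_geno(S$t1p1, S$t1p2)
    G2 <- child_geno(S$t2p1, S$t2p2)

    base <- 4L * (seq_len(F_) - 1L)
    parent1_geno <- Hp[base + 1L, , drop = FALSE] + Hp[base + 2L, , drop = FALSE]
    parent2_geno <- Hp[base + 3L, , drop = FALSE] + Hp[base + 4L, , drop = FALSE]

    geno <- rbind(parent1_geno, parent2_geno, G1, G2)
    fam <- sprintf("F%04d", seq_len(F_))
    meta <- data.frame(
      id = c(paste0(fam, "_P1"), paste0(fam, "_P2"),
             paste0(fam, "_T1"), paste0(fam, "_T2")),
      family_id = c(fam, fam, fam, fam),
      role = rep(c("parent1", "parent2", "twin1", "twin2"), each = F_),
      zygosity = c(rep("none", 2L * F_), zyg, zyg),
      sex = sample(c(1L, 2L), 4L * F_, TRUE),
      stringsAsFactors = FALSE
    )
    # co-twins share sex for MZ pairs
    t1 <- which(meta$role == "twin1"); t2 <- which(meta$role == "twin2")
    meta$sex[t2][mz] <- meta$sex[t1][mz]
    rownames(geno) <- meta$id

    founders <- meta$role %in% c("parent1", "parent2")
    mu <- colMeans(geno[founders, , drop = FALSE])
    sd <- sqrt(pmax(colMeans(geno[founders, , drop = FALSE]^2) - mu^2, 1e-12))
    Xs <- sweep(sweep(geno, 2, mu, "-"), 2, sd, "/")
    score <- function(u) {
      g <- as.vector(Xs %*% u)
      (g - mean(g[founders])) / stats::sd(g[founders])
    }
    g_cog <- score(eff$u_cog)
    g_noncog <- score(eff$u_noncog)

    structure(list(meta = meta, geno = geno, snp_info = ld$snp_info,
                   g_cog = stats::setNames(g_cog, meta$id),
                   g_noncog = stats::setNames(g_noncog, meta$id),
                   transmissions = S, zygosity = zyg,
                   founder_maf = mu / 2),
              class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  tab <- table(x$meta$zygosity[x$meta$role == "twin1"])
  cat(sprintf("Genotype panel: %d families (%s), %d SNPs\n",
              length(unique(x$meta$family_id)),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              ncol(x$geno)))
  invisible(x)
}

#' Mean fraction of shared parental transmissions among DZ pairs
#'
#' Audits meiosis in a simulated panel: for every DZ family and LD block,
#' checks whether the co-twins received the same parental haplotype, averaged
#' over both parents. The expectation under free recombination between blocks
#' is 1/2.
#'
#' @param panel A [simulate_genotype_panel()] result.
#' @return A single number in \[0, 1\].
#' @export
dz_transmission_sharing <- function(panel) {
  dz <- panel$zygosity == "DZ"
  stop_if_not(any(dz), "panel contains no DZ families")
  S <- panel$transmissions
  shared <- (S$t1p1[dz, , drop = FALSE] == S$t2p1[dz, , drop = FALSE]) +
    (S$t1p2[dz, , drop = FALSE] == S$t2p2[dz, , drop = FALSE])
  mean(shared) / 2
}
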