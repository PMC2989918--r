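# Stage 5: mixed-model likelihood-ratio scans of every phenotype set with
# each marker type (single SNP, the three haplotype blockings, tree edges).
# P-value matrices go to scratch; the per-method locus tables to scratch too.

source("analysis/00_config.R")

panel <- read_genotypes(file.path(paths$scratch, "panel.csv"),
                        dialect = "csv")
G <- panel$genotypes; map <- panel$map
P <- as.matrix(read.csv(file.path(paths$scratch, "panel_imputed.csv"),
                        row.names = 1, check.names = FALSE))
blockings <- readRDS(file.path(paths$scratch, "blockings.rds"))
trees <- readRDS(file.path(paths$scratch, "trees.rds"))
ph <- readRDS(file.path(paths$scratch, "phenotypes.rds"))

K <- kinship_allele_sharing(G)
spectral <- emma_spectral(K, matrix(1, nrow(G), 1L))
designs <- list(
  single_snp = snp_design(P, map),
  four_gamete = incidence_matrix(blockings$four_gamete$blocks, P,
                                 blockings$four_gamete$singletons, map = map),
  diversity = incidence_matrix(blockings$diversity$blocks, P,
                               blockings$diversity$singletons, map = map),
  slidewin3 = incidence_matrix(blockings$slidewin3$blocks, P,
                               blockings$slidewin3$singletons, map = map),
  treescan = clade_membership_matrix(blockings$four_gamete$blocks, trees, P,
                                     blockings$four_gamete$singletons,
                                     map = map))
modes <- c(single_snp = "single_snp", four_gamete = "haplotype",
           diversity = "haplotype", slidewin3 = "haplotype",
           treescan = "treescan")

scans <- list()
for (set_nm in names(ph$sets)) {
  Y <- ph$sets[[set_nm]]$Y
  for (m in names(designs)) {
    t0 <- Sys.time()
    pm <- matrix(NA_real_, nrow(Y), 0L)
    rows <- vector("list", nrow(Y))
    for (r in seq_len(nrow(Y))) {
      sc <- lrt_scan(Y[r, ], designs[[m]], K, mode = modes[[m]],
                     spectral = spectral)
      rows[[r]] <- sc$p
      if (r == 1L) {
        scans[[m]] <- sc[, c("locus", "chrom", "start_cM", "end_cM")]
      }
    }
    pm <- do.call(rbind, rows)
    saveRDS(pm, file.path(paths$scratch,
                          sprintf("pvals_%s_%s.rds", set_nm, m)))
    message(sprintf("%s / %s: %d x %d p-values [%.1fs]", set_nm, m,
                    nrow(pm), ncol(pm),
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
}
saveRDS(scans, file.path(paths$scratch, "scan_loci.rds"))
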