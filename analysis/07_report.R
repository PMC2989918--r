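# Stage 7: permutation thresholds for an experiment-wise error rate of
# 0.05 per marker type, effective test numbers, and a Manhattan-style table
# (-log10 p per method along the map) for one example phenotype.

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
  slidewin3 = incidence_matrix(blockings$slidewin3$blocks, P,
                               blockings$slidewin3$singletons, map = map),
  treescan = clade_membership_matrix(blockings$four_gamete$blocks, trees, P,
                                     blockings$four_gamete$singletons,
                                     map = map))
modes <- c(single_snp = "single_snp", four_gamete = "haplotype",
           slidewin3 = "haplotype", treescan = "treescan")

# permutation thresholds on one representative phenotype (reduced n_perm so
# the whole stage stays desk-cheap; the estimator is the study's)
y <- ph$sets$single_p06_h75$Y[1L, ]
n_perm <- 200L
thr_rows <- lapply(names(designs), function(m) {
  res <- permutation_threshold(
    y, function(yy) lrt_scan(yy, designs[[m]], K, mode = modes[[m]],
                             spectral = spectral)$p,
    eer = 0.05, n_perm = n_perm, seed = stage_seed(10L))
  data.frame(method = m, n_loci = nrow(designs[[m]]$columns),
             p_threshold = signif(res$p_threshold, 3),
             effective_tests = round(res$effective_tests, 1),
             n_perm = n_perm)
})
thr <- do.call(rbind, thr_rows)
write.table(thr, file.path(paths$results, "thresholds_effective_tests.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("permutation thresholds (EER 0.05):")
print(thr)

# Manhattan-style table for the same phenotype
man <- do.call(rbind, lapply(names(designs), function(m) {
  sc <- lrt_scan(y, designs[[m]], K, mode = modes[[m]], spectral = spectral)
  data.frame(method = m, locus = sc$locus, chrom = sc$chrom,
             cM = (sc$start_cM + sc$end_cM) / 2,
             neg_log10_p = round(-log10(sc$p), 3))
}))
# the full per-locus table is bulky; it stays in scratch, with the top
# hits per method kept as a small results table
write.table(man, file.path(paths$scratch, "manhattan_example.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
top <- do.call(rbind, lapply(split(man, man$method), function(d)
  utils::head(d[order(-d$neg_log10_p), ], 5L)))
write.table(top, file.path(paths$results, "manhattan_top_hits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("Manhattan table: %d rows (top hits kept in results/)",
                nrow(man)))
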