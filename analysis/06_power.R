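# Stage 6: bootstrap power at the target empirical FDRs for every phenotype
# set and marker type (Table-3/4-style), plus the marker-QTL LD
# information-content comparison (Table-5-style).

source("analysis/00_config.R")

panel <- read_genotypes(file.path(paths$scratch, "panel.csv"),
                        dialect = "csv")
G <- panel$genotypes; map <- panel$map
blockings <- readRDS(file.path(paths$scratch, "blockings.rds"))
trees <- readRDS(file.path(paths$scratch, "trees.rds"))
ph <- readRDS(file.path(paths$scratch, "phenotypes.rds"))
scan_loci <- readRDS(file.path(paths$scratch, "scan_loci.rds"))

methods <- names(scan_loci)
rows <- list()
for (set_nm in names(ph$sets)) {
  truths <- ph$sets[[set_nm]]$truths
  for (m in methods) {
    pm <- readRDS(file.path(paths$scratch,
                            sprintf("pvals_%s_%s.rds", set_nm, m)))
    for (ft in study$fdr_targets) {
      bp <- bootstrap_power_at_fdr(pm, scan_loci[[m]], truths,
                                   fdr_target = ft,
                                   n_boot = study$n_boot,
                                   window_cM = study$truth_window_cM,
                                   seed = stage_seed(9L))
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_nm, method = m, fdr_target = ft,
        power = round(bp$power, 3), se = round(bp$se, 3),
        unreliable = bp$unreliable)
    }
  }
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(paths$results, "table34_power.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("power at empirical FDR (single-SNP QTL cells):")
print(subset(tab, startsWith(set, "single") & fdr_target == 0.10))
message("pair-QTL cells (p = 0.06, h2 = 0.75):")
print(subset(tab, startsWith(set, "pair")))

# Table-5-style LD comparison for the single-SNP QTL set: the QTL indicator
# comes from the full panel, every candidate marker from the scan panel
# (which excludes the QTL themselves)
full <- readRDS(file.path(paths$scratch, "panel_full.rds"))
qtls <- lapply(ph$qtl_ids, function(id)
  qtl_spec("single_snp_removed", id, p = 0.06,
           chrom = full$map_full$chrom[full$map_full$marker == id],
           cM = full$map_full$cM[full$map_full$marker == id]))
cmp <- qtl_ld_comparison(
  qtls,
  list(single_snp = list(kind = "snp", G = G),
       four_gamete = list(kind = "blocks",
                          blocks = blockings$four_gamete$blocks, G = G),
       diversity = list(kind = "blocks",
                        blocks = blockings$diversity$blocks, G = G),
       slidewin3 = list(kind = "blocks",
                        blocks = blockings$slidewin3$blocks, G = G),
       treescan = list(kind = "edges",
                       blocks = blockings$four_gamete$blocks,
                       trees = trees, G = G)),
  full$G_full, map, window_cM = study$truth_window_cM)
write.table(cmp$superiority,
            file.path(paths$results, "table5_ld_superiority.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write.table(cmp$summary, file.path(paths$results, "table5_ld_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("mean max marker-QTL LD by method:")
print(cmp$summary, digits = 3)
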