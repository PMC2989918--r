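# Stage 1: generate the synthetic inbred panel, inject missingness, filter,
# order tied markers, select the 400-line association panel, and impute.
# Writes the panel and a Table-1-style SNP summary under results/.

source("analysis/00_config.R")

sim <- generate_genotypes(panel_cfg)
G0 <- inject_missing(sim$genotypes, panel_cfg$missing_rate,
                     seed = stage_seed(2L))
flt <- filter_markers(G0, sim$map, maf_min = panel_cfg$maf_min,
                      drop_duplicate_lines = TRUE)
ord <- order_tied_markers(flt$genotypes, flt$map)
G <- ord$genotypes; map <- ord$map
message(sprintf("panel: %d lines x %d markers after filtering (%d dropped)",
                nrow(G), ncol(G), length(flt$dropped_markers)))

sel <- kmeans_select(G, k = study$n_selected_lines, target = "lines",
                     seed = stage_seed(3L))
G_full <- G[sel, , drop = FALSE]
message(sprintf("selected %d lines; %d missing calls",
                length(sel), sum(is.na(G_full))))

# designate the QTL SNPs now and remove them from the scan panel: blocking,
# kinship and every scan design see only the remaining markers, as the
# study design prescribes for "removed" single-SNP QTL
qtl_ids <- suppressWarnings(
  choose_qtl_snps(G_full, map, n = study$n_qtl,
                  maf_min = study$qtl_maf_min))
keep <- !(map$marker %in% qtl_ids)
G <- G_full[, keep, drop = FALSE]
map_scan <- map[keep, , drop = FALSE]
rownames(map_scan) <- NULL
P <- impute_genotypes(G, map_scan)
message(sprintf("QTL designated: %d; scan panel: %d markers",
                length(qtl_ids), ncol(G)))

# Table-1-style summary of the scan panel
map <- map_scan
p1 <- colMeans(G, na.rm = TRUE)
maf <- pmin(p1, 1 - p1)
adj <- adjacent_r2(G, map)
max_win <- vapply(seq_len(ncol(G)), function(j)
  max_ld_in_window(G[, j], list(chrom = map$chrom[j], cM = map$cM[j]),
                   G, map, window_cM = 20, exclude = j)$value, numeric(1))
tab1 <- rbind(
  maf = ld_summary(maf),
  adjacent_r2 = ld_summary(adj$r2),
  max_r2_20cM_window = ld_summary(max_win))
write.table(round(tab1, 3), file.path(paths$results, "table1_snp_summary.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
message("SNP summary (min/median/mean/max):")
print(round(tab1, 3))

write_genotypes(G, map, file.path(paths$scratch, "panel.csv"),
                dialect = "csv")
write.csv(P, file.path(paths$scratch, "panel_imputed.csv"))
saveRDS(list(G_full = G_full, map_full = ord$map, qtl_ids = qtl_ids),
        file.path(paths$scratch, "panel_full.rds"))
write_sim_config(panel_cfg, file.path(paths$results, "panel_config.yaml"))
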