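# Stage 4: designate QTL SNPs and polygene markers, then simulate the
# phenotype grid: single-SNP QTL over (p, h2) cells, plus pair-QTL sets
# built from each blocking (the "younger causal variant" scenario).

source("analysis/00_config.R")

panel <- read_genotypes(file.path(paths$scratch, "panel.csv"),
                        dialect = "csv")
G <- panel$genotypes; map <- panel$map      # scan panel (QTL removed)
full <- readRDS(file.path(paths$scratch, "panel_full.rds"))
qtl_ids <- full$qtl_ids
blockings <- readRDS(file.path(paths$scratch, "blockings.rds"))

# polygene markers come from the scan panel, so no designated QTL doubles
# as a polygene marker; phenotypes are simulated from the full panel, which
# still carries the QTL genotypes
poly <- kmeans_select(G, k = study$n_polygene, target = "markers",
                      seed = stage_seed(4L))
message(sprintf("polygene: %d markers; QTL set: %d SNPs (median MAF %.2f)",
                length(poly), length(qtl_ids),
                median(pmin(colMeans(full$G_full[, qtl_ids], na.rm = TRUE),
                            1 - colMeans(full$G_full[, qtl_ids],
                                         na.rm = TRUE)))))

single_specs <- function(p) lapply(qtl_ids, function(id)
  qtl_spec("single_snp_removed", id, p = p,
           chrom = full$map_full$chrom[full$map_full$marker == id],
           cM = full$map_full$cM[full$map_full$marker == id]))

sets <- list()
for (p in study$p_grid) for (h2 in study$h2_grid) {
  nm <- sprintf("single_p%02d_h%02d", round(100 * p), round(100 * h2))
  sets[[nm]] <- simulate_phenotype_set(
    full$G_full, single_specs(p), h2 = h2, poly,
    reps_per_qtl = study$reps_per_qtl, seed = stage_seed(5L))
}
# pair-QTL sets at the separating cell (p = 0.06, h2 = 0.75), one per blocking
for (nm in c("slidewin3", "four_gamete", "diversity")) {
  method <- if (nm == "slidewin3") "slidewin3" else nm
  specs <- make_pair_qtl_specs(blockings[[nm]]$blocks, G, map,
                               method = method, p = 0.06,
                               seed = stage_seed(6L))
  set.seed(stage_seed(7L))
  specs <- specs[sample(length(specs), min(study$n_qtl, length(specs)))]
  sets[[paste0("pair_", nm)]] <- simulate_phenotype_set(
    full$G_full, specs, h2 = 0.75, poly,
    reps_per_qtl = study$reps_per_qtl, seed = stage_seed(8L))
}
for (nm in names(sets)) {
  message(sprintf("  %s: %d phenotypes", nm, nrow(sets[[nm]]$Y)))
}
saveRDS(list(sets = sets, poly = poly, qtl_ids = qtl_ids),
        file.path(paths$scratch, "phenotypes.rds"))
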