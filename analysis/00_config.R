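# Shared configuration for the analysis drivers. Everything downstream of
# this file is derived from `master_seed`, so the whole study reruns
# bit-identically. The panel is a scaled-down emulation of a Barley-CAP-like
# dataset: 400 selected lines, 600 mapped SNPs on 7 chromosomes; the
# simulation grid follows the study design (QTL sizes p in {0.03, 0.06,
# 0.12}, heritabilities {0.25, 0.75}) with reduced replicate counts.

library(haploscan)

master_seed <- 20260924L
stage_seed <- function(k) master_seed %% 1000000L + k  # per-stage derivation

paths <- list(
  results = "results",
  scratch = "scratch/analysis"
)
for (p in paths) dir.create(p, recursive = TRUE, showWarnings = FALSE)

panel_cfg <- sim_config(
  n_lines = 500L,       # pre-selection panel; 400 lines are k-means-selected
  n_markers = 600L,
  n_chromosomes = 7L,
  chrom_length_cM = 150,
  tie_fraction = 0.6,
  maf_min = 0.028,
  missing_rate = 0.007,
  seed = stage_seed(1L)
)

study <- list(
  n_selected_lines = 400L,
  n_qtl = 40L,            # scaled from the study's 100
  reps_per_qtl = 3L,      # scaled from 10; 120 replicates per cell
  qtl_maf_min = 0.10,
  p_grid = c(0.03, 0.06, 0.12),
  h2_grid = c(0.25, 0.75),
  n_polygene = 200L,      # scaled from 400
  fdr_targets = c(0.10, 0.20),
  truth_window_cM = 10,
  n_boot = 300L,
  n_perm = 1000L
)
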