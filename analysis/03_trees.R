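# Stage 3: parsimony trees over the four-gamete blocks and Newick export.
# Recombinant (tree-incompatible) alleles are excluded per block and counted.

source("analysis/00_config.R")

blockings <- readRDS(file.path(paths$scratch, "blockings.rds"))
fg <- blockings$four_gamete

trees <- lapply(fg$blocks, function(b) {
  if (nrow(b$alleles) < 2L) return(NULL)
  parsimony_tree(b$alleles$allele, b$alleles$freq)
})
n_edges <- vapply(trees, function(t) if (is.null(t)) 0L else
  length(t$edges), integer(1))
n_excl <- vapply(trees, function(t) if (is.null(t)) 0L else
  length(t$excluded), integer(1))
message(sprintf(
  "trees for %d blocks: %d edges total, %d blocks with excluded recombinants",
  sum(!vapply(trees, is.null, logical(1))), sum(n_edges), sum(n_excl > 0L)))

nwk <- vapply(seq_along(trees), function(i) {
  if (is.null(trees[[i]])) return(NA_character_)
  tree_newick(trees[[i]])
}, character(1))
writeLines(nwk[!is.na(nwk)],
           file.path(paths$results, "four_gamete_trees.nwk"))
saveRDS(trees, file.path(paths$scratch, "trees.rds"))
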