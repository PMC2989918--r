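# Haplotype blocking, allele enumeration, and the incidence matrix.

# two-SNP panel with the rarest gamete class at a controlled frequency
two_snp_panel <- function(rare_frac, n = 100L) {
  n_rare <- round(rare_frac * n)
  x <- c(rep(0L, 50L), rep(1L, n - 50L))
  y <- c(rep(0L, 25L), rep(1L, 25L), rep(0L, n - 50L - n_rare),
         rep(1L, n_rare))
  G <- cbind(A = x, B = y)
  rownames(G) <- sprintf("L%03d", seq_len(n))
  map <- data.frame(marker = c("A", "B"), chrom = 1L, cM = c(1, 2))
  list(G = G, map = map)
}

test_that("four-gamete growth respects the recombinant-frequency cutoff", {
  # all four gametes, rarest at 3%: boundary between the SNPs
  p3 <- two_snp_panel(0.03)
  res3 <- four_gamete_blocks(p3$G, p3$map, recombinant_cutoff = 0.02)
  expect_length(res3$blocks, 0L)
  expect_identical(res3$singletons, c(1L, 2L))
  # rarest at 1%: tolerated, SNPs merge
  p1 <- two_snp_panel(0.01)
  res1 <- four_gamete_blocks(p1$G, p1$map, recombinant_cutoff = 0.02)
  expect_length(res1$blocks, 1L)
  expect_identical(res1$blocks[[1L]]$marker_index_range, c(1L, 2L))
  # only three gamete classes: merge regardless
  p0 <- two_snp_panel(0)
  res0 <- four_gamete_blocks(p0$G, p0$map)
  expect_length(res0$blocks, 1L)
})

test_that("four-gamete blocks partition the map and are stable", {
  sim <- small_panel()
  res <- four_gamete_blocks(sim$genotypes, sim$map)
  covered <- sort(c(unlist(lapply(res$blocks, function(b)
    seq(b$marker_index_range[1L], b$marker_index_range[2L]))),
    res$singletons))
  expect_identical(covered, seq_len(ncol(sim$genotypes)))
  # no block spans chromosomes
  for (b in res$blocks) {
    idx <- seq(b$marker_index_range[1L], b$marker_index_range[2L])
    expect_length(unique(sim$map$chrom[idx]), 1L)
  }
  # stability: re-blocking a block's own markers reproduces it whole
  for (b in res$blocks[seq_len(min(5L, length(res$blocks)))]) {
    idx <- seq(b$marker_index_range[1L], b$marker_index_range[2L])
    sub <- four_gamete_blocks(sim$genotypes[, idx, drop = FALSE],
                              sim$map[idx, ])
    expect_length(sub$blocks, 1L)
    expect_identical(sub$blocks[[1L]]$marker_index_range,
                     c(1L, length(idx)))
  }
})

# exhaustive diversity-partition oracle over one chromosome of <= 12 markers
oracle_diversity <- function(G, coverage, common_freq) {
  m <- ncol(G)
  cov_of <- function(idx) {
    haps <- apply(G[, idx, drop = FALSE], 1L, paste, collapse = "")
    tab <- table(haps) / length(haps)
    sum(tab[tab >= common_freq])
  }
  best <- NULL
  for (mask in 0:(2^(m - 1L) - 1L)) {   # cut points after marker i
    cuts <- which(bitwAnd(mask, 2^(0:(m - 2L))) > 0L)
    bounds <- c(0L, cuts, m)
    segs <- lapply(seq_len(length(bounds) - 1L), function(k)
      seq(bounds[k] + 1L, bounds[k + 1L]))
    ok <- all(vapply(segs, function(s)
      length(s) == 1L || cov_of(s) >= coverage, logical(1)))
    if (!ok) next
    n_seg <- length(segs)
    multi <- sum(lengths(segs)[lengths(segs) > 1L])
    key <- c(n_seg, -multi)
    if (is.null(best) || key[1L] < best$key[1L] ||
        (key[1L] == best$key[1L] && key[2L] < best$key[2L])) {
      best <- list(key = key, segs = segs)
    }
  }
  best$segs
}

test_that("diversity DP matches exhaustive partition enumeration", {
  # 5-SNP toy where a 4-SNP block strands 4% of lines on rare haplotypes
  set.seed(31)
  n <- 100L
  h1 <- c(0L, 0L, 0L, 0L, 0L); h2 <- c(1L, 1L, 1L, 0L, 1L)
  h3 <- c(0L, 1L, 1L, 1L, 1L)
  G <- rbind(
    matrix(h1, 48L, 5L, byrow = TRUE),
    matrix(h2, 38L, 5L, byrow = TRUE),
    matrix(h3, 10L, 5L, byrow = TRUE),
    matrix(c(1L, 0L, 1L, 1L, 0L), 2L, 5L, byrow = TRUE),  # rare 2%
    matrix(c(0L, 1L, 0L, 0L, 1L), 2L, 5L, byrow = TRUE))  # rare 2%
  colnames(G) <- sprintf("M%d", 1:5)
  rownames(G) <- sprintf("L%03d", seq_len(n))
  map <- data.frame(marker = colnames(G), chrom = 1L, cM = 1:5)
  res <- diversity_blocks(G, map, coverage = 0.97, common_freq = 0.028)
  got <- lapply(res$blocks, function(b)
    seq(b$marker_index_range[1L], b$marker_index_range[2L]))
  got <- c(got, as.list(res$singletons))
  got <- got[order(vapply(got, min, integer(1)))]
  want <- oracle_diversity(G, 0.97, 0.028)
  # the DP must attain the oracle's optimum (segment count, then SNPs in
  # multi-SNP blocks); exact segment choice may differ only on exact ties
  key <- function(segs) c(length(segs),
                          sum(lengths(segs)[lengths(segs) > 1L]))
  expect_identical(key(got), key(want))
  # every emitted multi-SNP block satisfies the coverage constraint
  for (b in res$blocks) {
    idx <- seq(b$marker_index_range[1L], b$marker_index_range[2L])
    haps <- apply(G[, idx, drop = FALSE], 1L, paste, collapse = "")
    tab <- table(haps) / n
    expect_gte(sum(tab[tab >= 0.028]), 0.97)
  }
  # same check on LD-structured data against the oracle (first 10 markers)
  sim <- small_panel()
  G2 <- sim$genotypes[, 1:10]
  map2 <- sim$map[1:10, ]
  res2 <- diversity_blocks(G2, map2, coverage = 0.97, common_freq = 0.028)
  got2 <- c(lapply(res2$blocks, function(b)
    seq(b$marker_index_range[1L], b$marker_index_range[2L])),
    as.list(res2$singletons))
  got2 <- got2[order(vapply(got2, min, integer(1)))]
  want2 <- oracle_diversity(G2, 0.97, 0.028)
  expect_identical(key(got2), key(want2))
  # and every multi-SNP block is feasible under the coverage rule
  for (b in res2$blocks) {
    idx <- seq(b$marker_index_range[1L], b$marker_index_range[2L])
    haps <- apply(G2[, idx, drop = FALSE], 1L, paste, collapse = "")
    tab <- table(haps) / nrow(G2)
    expect_gte(sum(tab[tab >= 0.028]), 0.97)
  }
})

test_that("uniform panels collapse to one block per chromosome", {
  G <- matrix(rep(c(0L, 1L), each = 20L), 40L, 6L)
  dimnames(G) <- list(sprintf("L%02d", 1:40), sprintf("M%d", 1:6))
  map <- data.frame(marker = colnames(G), chrom = rep(1:2, each = 3L),
                    cM = rep(1:3, 2L))
  res <- diversity_blocks(G, map)
  expect_length(res$blocks, 2L)
  expect_length(res$singletons, 0L)
})

test_that("sliding windows count and cover as expected", {
  sim <- small_panel()
  map <- sim$map
  res <- sliding_window_blocks(sim$genotypes, map, size = 3L)
  n_c <- table(map$chrom)
  expect_length(res$blocks, sum(pmax(n_c - 2L, 0L)))
  # 5 SNPs on one chromosome -> 3 windows; 2 SNPs -> none
  G5 <- sim$genotypes[, 1:7]
  map5 <- data.frame(marker = colnames(G5), chrom = c(rep(1L, 5L), 2L, 2L),
                     cM = c(1:5, 1:2))
  r5 <- sliding_window_blocks(G5, map5, size = 3L)
  expect_length(r5$blocks, 3L)
  # every marker of a long-enough chromosome is covered
  covered <- unique(unlist(lapply(r5$blocks, function(b)
    seq(b$marker_index_range[1L], b$marker_index_range[2L]))))
  expect_identical(sort(covered), 1:5)
})

test_that("allele enumeration ranks, thresholds, and pools rare classes", {
  # 3-SNP block, haplotype counts 50/30/15/4/1 over 100 lines
  haps <- c(rep("000", 50L), rep("011", 30L), rep("110", 15L),
            rep("101", 4L), rep("111", 1L))
  G <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  colnames(G) <- sprintf("M%d", 1:3)
  rownames(G) <- sprintf("L%03d", seq_len(100L))
  map <- data.frame(marker = colnames(G), chrom = 1L, cM = 1:3)
  b <- new_block_for_test(1L, 1:3, map, "four_gamete")
  be <- enumerate_alleles(b, G, common_allele_freq = 0.02)
  expect_identical(be$alleles$allele, c("000", "011", "110", "101"))
  expect_equal(be$alleles$freq, c(0.50, 0.30, 0.15, 0.04))
  expect_equal(be$rare_freq, 0.01)
  # single-SNP block with MAF 0.3
  b1 <- new_block_for_test(1L, 1L, map, "four_gamete")
  G1 <- cbind(M1 = c(rep(0L, 70L), rep(1L, 30L)))
  rownames(G1) <- rownames(G)
  be1 <- enumerate_alleles(b1, G1)
  expect_identical(be1$alleles$allele, c("0", "1"))
  expect_equal(be1$alleles$freq, c(0.7, 0.3))
})

test_that("incidence matrix implements the k-column probability layout", {
  haps <- c(rep("000", 50L), rep("011", 30L), rep("110", 15L),
            rep("101", 5L))
  G <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  colnames(G) <- sprintf("M%d", 1:3)
  rownames(G) <- sprintf("L%03d", seq_len(100L))
  map <- data.frame(marker = colnames(G), chrom = 1L, cM = 1:3)
  b <- enumerate_alleles(new_block_for_test(1L, 1:3, map, "four_gamete"), G)
  P <- matrix(as.numeric(G), 100L, 3L, dimnames = dimnames(G))
  im <- incidence_matrix(list(b), P, map = map)
  # k common alleles -> k columns (k-1 allele columns + rare)
  expect_identical(ncol(im$X), 4L)
  # allele-1 carriers with complete data: all zeros
  expect_true(all(im$X[1:50, ] == 0))
  # allele-2 carriers: 1 in the first column only
  expect_true(all(im$X[51:80, 1L] == 1))
  expect_true(all(im$X[51:80, -1L] == 0))
  # rare column is zero everywhere here (all haplotypes common)
  expect_true(all(im$X[, 4L] == 0))
  # a line imputed 50/50 at one SNP splits its mass
  P2 <- P
  P2[1L, 3L] <- 0.5   # "000" vs "001": 001 is rare here
  im2 <- incidence_matrix(list(b), P2, map = map)
  expect_equal(sum(im2$X[1L, ]), 0.5)   # half mass off allele 1
  expect_true(all(rowSums(im2$X) <= 1 + 1e-9))
})

test_that("singleton SNP columns carry minor-allele probabilities", {
  G <- cbind(M1 = c(rep(0L, 70L), rep(1L, 30L)),
             M2 = c(rep(1L, 80L), rep(0L, 20L)))
  rownames(G) <- sprintf("L%03d", 1:100)
  map <- data.frame(marker = colnames(G), chrom = 1L, cM = c(1, 5))
  P <- matrix(as.numeric(G), 100L, 2L, dimnames = dimnames(G))
  im <- incidence_matrix(list(), P, singletons = 1:2, map = map)
  expect_equal(unname(colMeans(im$X)), c(0.3, 0.2))
  expect_identical(im$columns$chrom, c(1L, 1L))
  expect_equal(im$columns$start_cM, c(1, 5))
})

test_that("block statistics reflect the blocking's structure", {
  sim <- small_panel()
  G <- sim$genotypes; map <- sim$map
  sw <- sliding_window_blocks(G, map, size = 3L)
  sw$blocks <- lapply(sw$blocks, enumerate_alleles, G = G)
  st <- block_stats(sw$blocks, sw$singletons, map, G)
  expect_equal(st$prop_map_in_blocks, 1, tolerance = 1e-9)
  expect_equal(st$var_size_snp, 0)
  expect_identical(st$n_single_snps, 0L)
  expect_identical(st$n_loci, length(sw$blocks))
  # single-SNP "blocking": He equals 2p(1-p) averaged over SNPs
  st1 <- block_stats(list(), seq_len(ncol(G)), map, G)
  p <- colMeans(G)
  expect_equal(st1$mean_He, mean(2 * p * (1 - p)), tolerance = 1e-12)
  expect_identical(st1$n_loci, ncol(G))
})

test_that("block TSV export writes the BED-like layout", {
  sim <- small_panel()
  sw <- sliding_window_blocks(sim$genotypes, sim$map, size = 3L)
  sw$blocks <- lapply(sw$blocks[1:4], enumerate_alleles, G = sim$genotypes)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_blocks_tsv(sw$blocks, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), 4L)
  expect_identical(names(back),
                   c("chrom", "start_cM", "end_cM", "block_id", "method",
                     "n_SNPs", "n_common_alleles"))
  expect_true(all(back$end_cM >= back$start_cM))
})
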