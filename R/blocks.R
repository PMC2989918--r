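# Haplotype blocking: four-gamete (recombination) blocks, diversity-coverage
# blocks by dynamic programming, overlapping sliding windows; block-allele
# enumeration and the probabilistic haplotype incidence matrix used as the
# fixed-effect design in the association scan.
#
# Blocking always runs on the original (possibly missing) calls with
# complete-case haplotype counting; imputed probabilities enter only when the
# incidence matrix is built.

new_block <- function(chrom, idx, map, method) {
  list(chrom = chrom,
       marker_index_range = c(min(idx), max(idx)),
       markers = map$marker[idx],
       start_cM = map$cM[min(idx)], end_cM = map$cM[max(idx)],
       alleles = NULL, method = method)
}

# frequency table of complete-case haplotype strings over marker columns idx
haplotype_counts <- function(G, idx) {
  sub <- G[, idx, drop = FALSE]
  ok <- rowSums(is.na(sub)) == 0L
  if (!any(ok)) return(table(character(0)))
  haps <- apply(sub[ok, , drop = FALSE], 1L, paste, collapse = "")
  table(haps)
}

# TRUE if every pair of markers in idx passes the four-gamete test: no pair
# shows all four gamete classes each at frequency > cutoff (complete cases
# per pair)
four_gamete_ok <- function(G, idx, cutoff) {
  if (length(idx) < 2L) return(TRUE)
  for (a in seq_len(length(idx) - 1L)) {
    x <- G[, idx[a]]
    for (b in seq((a + 1L), length(idx))) {
      y <- G[, idx[b]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n == 0L) next
      cnt <- c(sum(x[ok] == 0 & y[ok] == 0), sum(x[ok] == 0 & y[ok] == 1),
               sum(x[ok] == 1 & y[ok] == 0), sum(x[ok] == 1 & y[ok] == 1))
      if (all(cnt / n > cutoff)) return(FALSE)
    }
  }
  TRUE
}

#' Four-gamete haplotype blocks
#'
#' Greedy left-to-right block growth within each chromosome: a marker joins
#' the current block unless, paired with any marker already in the block, all
#' four two-locus gamete classes are observed each at frequency above
#' `recombinant_cutoff` (evidence of historical recombination). Blocks of one
#' marker are reported as unblocked singleton SNPs.
#'
#' @param G line x marker 0/1 matrix (original calls; missing allowed).
#' @param map marker map in `G` column order, sorted by (chrom, cM).
#' @param recombinant_cutoff tolerated frequency of the rarest gamete class;
#'   the default 0.02 treats classes at 2% or below as compatible with no
#'   recombination.
#' @return `list(blocks, singletons)`: `blocks` is a list of block records
#'   (chromosome, inclusive marker index range, cM interval, method label),
#'   `singletons` an integer vector of unblocked marker indices.
#' @export
four_gamete_blocks <- function(G, map, recombinant_cutoff = 0.02) {
  stopifnot(ncol(G) == nrow(map))
  blocks <- list()
  singletons <- integer(0)
  for (idx_c in split(seq_len(nrow(map)), map$chrom)) {
    cur <- idx_c[1L]
    for (m in idx_c[-1L]) {
      if (four_gamete_ok(G, c(cur, m), recombinant_cutoff)) {
        cur <- c(cur, m)
      } else {
        if (length(cur) >= 2L) {
          blocks[[length(blocks) + 1L]] <-
            new_block(map$chrom[cur[1L]], cur, map, "four_gamete")
        } else singletons <- c(singletons, cur)
        cur <- m
      }
    }
    if (length(cur) >= 2L) {
      blocks[[length(blocks) + 1L]] <-
        new_block(map$chrom[cur[1L]], cur, map, "four_gamete")
    } else singletons <- c(singletons, cur)
  }
  list(blocks = blocks, singletons = singletons)
}

# coverage of a candidate block: fraction of complete-haplotype lines whose
# haplotype has frequency >= common_freq
block_coverage <- function(G, idx, common_freq) {
  cnt <- haplotype_counts(G, idx)
  if (length(cnt) == 0L) return(0)
  freq <- cnt / sum(cnt)
  sum(cnt[freq >= common_freq]) / sum(cnt)
}

#' Diversity-coverage haplotype blocks (dynamic programming)
#'
#' Partitions each chromosome's markers into contiguous segments such that in
#' every segment at least `coverage` of the lines carry a haplotype allele of
#' frequency at least `common_freq`. Among feasible partitions the block count
#' is minimized; ties are broken by maximizing the number of markers inside
#' multi-SNP blocks (fewest singletons). Single-marker segments are always
#' feasible and are reported as unblocked singletons.
#'
#' @inheritParams four_gamete_blocks
#' @param coverage minimum fraction of lines on common haplotypes per block.
#' @param common_freq frequency above which a haplotype counts as common.
#' @param max_span largest block size (in markers) the DP considers; bounds
#'   compute and matches the scale of observed block sizes.
#' @return `list(blocks, singletons)` as [four_gamete_blocks()].
#' @export
diversity_blocks <- function(G, map, coverage = 0.97, common_freq = 0.028,
                             max_span = 30L) {
  stopifnot(ncol(G) == nrow(map))
  blocks <- list()
  singletons <- integer(0)
  for (idx_c in split(seq_len(nrow(map)), map$chrom)) {
    n <- length(idx_c)
    # feasible[j, i]: segment of markers idx_c[i..j] satisfies the coverage rule
    # DP over prefix: best[i] = (n_blocks, -n_in_multi) lexicographic
    INF <- c(Inf, Inf)
    best <- matrix(Inf, n + 1L, 2L)     # cost rows: (count, -snps_in_multi)
    best[1L, ] <- c(0, 0)
    back <- integer(n + 1L)
    for (j in seq_len(n)) {
      lo <- max(1L, j - max_span + 1L)
      for (i in j:lo) {
        seg <- idx_c[i:j]
        if (length(seg) > 1L &&
            block_coverage(G, seg, common_freq) < coverage) {
          # extending left can only lower coverage or keep it infeasible for
          # the same right end in most data, but not always; keep scanning
          next
        }
        cand <- best[i, ] + c(1, if (length(seg) > 1L) -length(seg) else 0)
        if (cand[1L] < best[j + 1L, 1L] ||
            (cand[1L] == best[j + 1L, 1L] && cand[2L] < best[j + 1L, 2L])) {
          best[j + 1L, ] <- cand
          back[j + 1L] <- i
        }
      }
    }
    # reconstruct
    j <- n
    segs <- list()
    while (j > 0L) {
      i <- back[j + 1L]
      segs[[length(segs) + 1L]] <- idx_c[i:j]
      j <- i - 1L
    }
    for (seg in rev(segs)) {
      if (length(seg) >= 2L) {
        blocks[[length(blocks) + 1L]] <-
          new_block(map$chrom[seg[1L]], seg, map, "diversity")
      } else singletons <- c(singletons, seg)
    }
  }
  list(blocks = blocks, singletons = singletons)
}

#' Overlapping sliding-window blocks
#'
#' One block per run of `size` consecutive markers within a chromosome;
#' chromosomes with fewer than `size` markers contribute none. Every marker of
#' a sufficiently long chromosome is covered, so no singletons are emitted.
#'
#' @inheritParams four_gamete_blocks
#' @param size window size in markers (3 reproduces the SlideWin3 design).
#' @return `list(blocks, singletons = integer(0))`.
#' @export
sliding_window_blocks <- function(G, map, size = 3L) {
  stopifnot(ncol(G) == nrow(map), size >= 1L)
  blocks <- list()
  for (idx_c in split(seq_len(nrow(map)), map$chrom)) {
    n <- length(idx_c)
    if (n < size) next
    for (s in seq_len(n - size + 1L)) {
      seg <- idx_c[s:(s + size - 1L)]
      blocks[[length(blocks) + 1L]] <-
        new_block(map$chrom[seg[1L]], seg, map, "sliding_window")
    }
  }
  list(blocks = blocks, singletons = integer(0))
}

#' Enumerate common haplotype alleles of a block
#'
#' Haplotype strings are counted over lines with complete data for the block;
#' alleles at frequency `>= common_allele_freq` are listed most-frequent-first
#' (ties broken by string), and rarer haplotypes are pooled into a `"rare"`
#' class whose total frequency is reported.
#'
#' @param block a block record.
#' @param G line x marker matrix the block indexes into.
#' @param common_allele_freq frequency threshold for a common allele.
#' @return the block with `alleles` (data.frame: `allele`, `freq`) and
#'   `rare_freq` filled in.
#' @export
enumerate_alleles <- function(block, G, common_allele_freq = 0.02) {
  idx <- seq(block$marker_index_range[1L], block$marker_index_range[2L])
  cnt <- haplotype_counts(G, idx)
  if (length(cnt) == 0L) stop("block has no complete haplotypes")
  freq <- as.numeric(cnt) / sum(cnt)
  nm <- names(cnt)
  keep <- freq >= common_allele_freq
  o <- order(-freq[keep], nm[keep])
  block$alleles <- data.frame(allele = nm[keep][o], freq = freq[keep][o],
                              stringsAsFactors = FALSE)
  block$rare_freq <- sum(freq[!keep])
  block
}

# per-line probability of carrying haplotype string `hap` in marker columns
# idx, as the product of per-SNP allele probabilities
hap_prob <- function(P, idx, hap) {
  bits <- as.integer(strsplit(hap, "")[[1L]])
  pr <- rep(1, nrow(P))
  for (k in seq_along(idx)) {
    pk <- P[, idx[k]]
    pr <- pr * (if (bits[k] == 1L) pk else 1 - pk)
  }
  pr
}

#' Probabilistic haplotype incidence matrix
#'
#' Builds the fixed-effect design for the haplotype association scan. For a
#' block with `k` common alleles (allele 1 the most frequent), `k` columns are
#' created: columns `1..(k-1)` hold the per-line probabilities of carrying
#' alleles `2..k`, and column `k` the probability of carrying a pooled rare
#' (minor) allele, computed as `1 -` the summed probabilities of the common
#' alleles. A line certainly carrying allele 1 therefore has all-zero entries
#' for the block. Haplotype-allele probabilities are products of the per-SNP
#' allele probabilities from imputation. Unblocked SNPs contribute one column
#' each: the probability of carrying the panel-minor allele.
#'
#' @param blocks list of blocks with alleles enumerated
#'   (see [enumerate_alleles()]).
#' @param allele_probs line x marker allele-1 probability matrix from
#'   [impute_genotypes()].
#' @param singletons integer indices of unblocked markers.
#' @param map optional marker map in `allele_probs` column order; used to
#'   position singleton-SNP columns.
#' @param tol tolerance on internal probability consistency.
#' @return list with `X` (line x column numeric design), `columns`
#'   (data.frame: `locus`, `type`, `allele`, `chrom`, `start_cM`, `end_cM`,
#'   `df_group`) where `df_group` labels the columns tested jointly per locus.
#' @export
incidence_matrix <- function(blocks, allele_probs, singletons = integer(0),
                             map = NULL, tol = 1e-6) {
  cols <- list()
  meta <- list()
  for (b_i in seq_along(blocks)) {
    b <- blocks[[b_i]]
    stopifnot(!is.null(b$alleles))
    idx <- seq(b$marker_index_range[1L], b$marker_index_range[2L])
    k <- nrow(b$alleles)
    pr <- vapply(b$alleles$allele, function(h) hap_prob(allele_probs, idx, h),
                 numeric(nrow(allele_probs)))
    pr <- matrix(pr, nrow(allele_probs), k)
    tot <- rowSums(pr)
    if (any(tot > 1 + tol)) {
      stop("haplotype probabilities exceed 1 for block ", b_i)
    }
    rare <- pmax(0, 1 - tot)
    locus_id <- sprintf("%s_blk%04d", b$method, b_i)
    X_b <- cbind(pr[, -1L, drop = FALSE], rare)
    for (cc in seq_len(ncol(X_b))) {
      cols[[length(cols) + 1L]] <- X_b[, cc]
      meta[[length(meta) + 1L]] <- data.frame(
        locus = locus_id, type = "block",
        allele = if (cc < ncol(X_b)) b$alleles$allele[cc + 1L] else "rare",
        chrom = b$chrom, start_cM = b$start_cM, end_cM = b$end_cM,
        stringsAsFactors = FALSE)
    }
  }
  for (s in singletons) {
    p1 <- allele_probs[, s]
    minor_is_1 <- mean(p1) <= 0.5
    cols[[length(cols) + 1L]] <- if (minor_is_1) p1 else 1 - p1
    meta[[length(meta) + 1L]] <- data.frame(
      locus = paste0("snp_", colnames(allele_probs)[s]), type = "snp",
      allele = if (minor_is_1) "1" else "0",
      chrom = if (is.null(map)) NA else map$chrom[s],
      start_cM = if (is.null(map)) NA_real_ else map$cM[s],
      end_cM = if (is.null(map)) NA_real_ else map$cM[s],
      stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, cols)
  columns <- do.call(rbind, meta)
  rownames(columns) <- NULL
  columns$df_group <- match(columns$locus, unique(columns$locus))
  rownames(X) <- rownames(allele_probs)
  colnames(X) <- paste(columns$locus, columns$allele, sep = ".")
  list(X = X, columns = columns)
}

#' Summary statistics of a blocking
#'
#' Table of locus counts, allele counts, diversity and size moments for one
#' blocking method: number of loci (blocks plus unblocked SNPs), single SNPs
#' remaining, total and common (MAF floor) allele counts, mean expected
#' heterozygosity and major-allele frequency over loci, proportion of the
#' genetic map inside blocks, and block-size moments in cM and SNPs.
#'
#' @param blocks list of blocks with alleles enumerated.
#' @param singletons unblocked marker indices.
#' @param map marker map.
#' @param G genotype matrix (for singleton allele frequencies).
#' @param maf_floor MAF floor for the "common alleles" count.
#' @return a one-row data.frame of summary statistics.
#' @export
block_stats <- function(blocks, singletons, map, G, maf_floor = 0.028) {
  n_loci <- length(blocks) + length(singletons)
  # per-locus allele frequency lists: blocks use enumerated common + rare
  freq_sets <- c(
    lapply(blocks, function(b) {
      f <- b$alleles$freq
      if (b$rare_freq > 0) f <- c(f, b$rare_freq)
      f / sum(f)
    }),
    lapply(singletons, function(s) {
      p <- mean(G[, s], na.rm = TRUE)
      c(max(p, 1 - p), min(p, 1 - p))
    })
  )
  n_alleles <- vapply(freq_sets, length, integer(1))
  n_common <- vapply(freq_sets, function(f) sum(f >= maf_floor), integer(1))
  he <- vapply(freq_sets, expected_heterozygosity, numeric(1))
  major <- vapply(freq_sets, max, numeric(1))
  size_cM <- vapply(blocks, function(b) b$end_cM - b$start_cM, numeric(1))
  size_snp <- vapply(blocks, function(b)
    diff(b$marker_index_range) + 1L, integer(1))
  # proportion of map covered by block intervals (union per chromosome)
  map_len <- sum(vapply(split(map$cM, map$chrom),
                        function(p) diff(range(p)), numeric(1)))
  cov_len <- 0
  for (ch in unique(map$chrom)) {
    iv <- do.call(rbind, lapply(blocks[vapply(blocks, function(b)
      identical(b$chrom, ch), logical(1))],
      function(b) c(b$start_cM, b$end_cM)))
    if (is.null(iv) || nrow(iv) == 0L) next
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    cur <- iv[1L, ]
    for (r in seq_len(nrow(iv))[-1L]) {
      if (iv[r, 1L] <= cur[2L]) cur[2L] <- max(cur[2L], iv[r, 2L])
      else { cov_len <- cov_len + diff(cur); cur <- iv[r, ] }
    }
    cov_len <- cov_len + diff(cur)
  }
  data.frame(
    n_loci = n_loci,
    n_single_snps = length(singletons),
    total_alleles = sum(n_alleles),
    common_alleles = sum(n_common),
    mean_He = mean(he),
    mean_major_freq = mean(major),
    prop_map_in_blocks = if (map_len > 0) cov_len / map_len else NA_real_,
    mean_size_cM = if (length(blocks)) mean(size_cM) else NA_real_,
    median_size_cM = if (length(blocks)) stats::median(size_cM) else NA_real_,
    var_size_cM = if (length(blocks) > 1L) stats::var(size_cM) else 0,
    max_size_cM = if (length(blocks)) max(size_cM) else NA_real_,
    mean_size_snp = if (length(blocks)) mean(size_snp) else NA_real_,
    median_size_snp = if (length(blocks)) stats::median(size_snp) else NA_real_,
    var_size_snp = if (length(blocks) > 1L) stats::var(size_snp) else 0,
    max_size_snp = if (length(blocks)) max(size_snp) else NA_integer_
  )
}

#' Export blocks as a BED-like TSV
#'
#' @param blocks list of blocks (alleles optional).
#' @param path output path.
#' @return the exported data.frame, invisibly written to `path`.
#' @export
write_blocks_tsv <- function(blocks, path) {
  df <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(chrom = b$chrom, start_cM = b$start_cM, end_cM = b$end_cM,
               block_id = sprintf("%s_blk%04d", b$method, i),
               method = b$method,
               n_SNPs = diff(b$marker_index_range) + 1L,
               n_common_alleles = if (is.null(b$alleles)) NA_integer_
                                  else nrow(b$alleles),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
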