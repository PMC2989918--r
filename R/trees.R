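# Parsimony trees over the haplotype alleles of a block, and clade-membership
# design columns for the tree-edge (TreeScan-style) association scan.
#
# Block alleles are short binary strings. A set of binary haplotypes admits a
# perfect phylogeny exactly when no pair of sites shows all four gametes; on
# such a set every segregating site induces one tree edge (sites with the
# same bipartition stack onto the same edge), so the tree length equals the
# number of segregating sites. Alleles that break compatibility (recombinant
# haplotypes) are dropped, lowest frequency first, and reported as excluded.

allele_bits <- function(alleles) {
  do.call(rbind, lapply(strsplit(alleles, ""), as.integer))
}

# sites violating pairwise compatibility? TRUE if the set admits a perfect
# phylogeny
perfect_phylogeny_ok <- function(bits) {
  s <- ncol(bits)
  if (s < 2L || nrow(bits) < 4L) return(TRUE)
  for (a in seq_len(s - 1L)) for (b in seq((a + 1L), s)) {
    pat <- unique(bits[, c(a, b), drop = FALSE])
    if (nrow(pat) == 4L) return(FALSE)
  }
  TRUE
}

#' Maximum-parsimony tree of block haplotype alleles
#'
#' Builds the perfect phylogeny of the block's common haplotype alleles. If
#' the full allele set is incompatible (contains recombinant haplotypes),
#' alleles are dropped greedily by ascending frequency (ties by allele
#' string) until the remainder admits a perfect phylogeny; dropped alleles
#' are reported as `excluded`. Edges are the distinct site-induced
#' bipartitions of the included alleles; each edge's length is the number of
#' sites inducing it, and the total tree length equals the number of
#' segregating sites among included alleles.
#'
#' @param alleles character vector of equal-length binary haplotype strings.
#' @param freqs allele frequencies (same order); used only for the drop
#'   order and stored on the result.
#' @return an object of class `parsimony_tree`: list with `tips` (included
#'   allele strings, most frequent first), `excluded`, `freqs`, `edges`
#'   (list of `list(clade, length)` where `clade` is the allele-string set on
#'   the side away from the most frequent allele) and `length` (tree length).
#' @export
parsimony_tree <- function(alleles, freqs = NULL) {
  stopifnot(length(alleles) >= 2L, !anyDuplicated(alleles))
  if (is.null(freqs)) freqs <- rep(1 / length(alleles), length(alleles))
  stopifnot(length(freqs) == length(alleles))
  o <- order(-freqs, alleles)
  alleles <- alleles[o]; freqs <- freqs[o]
  included <- seq_along(alleles)
  excluded <- integer(0)
  repeat {
    bits <- allele_bits(alleles[included])
    if (perfect_phylogeny_ok(bits)) break
    if (length(included) <= 2L) break
    # drop the currently lowest-frequency included allele
    drop <- included[length(included)]
    excluded <- c(excluded, drop)
    included <- included[-length(included)]
  }
  bits <- allele_bits(alleles[included])
  tips <- alleles[included]
  # edges: distinct site bipartitions; clade = side not containing tip 1
  # (the most frequent allele), so nested clades form a laminar family
  edges <- list()
  if (ncol(bits) >= 1L && length(tips) >= 2L) {
    pat_key <- character(0)
    for (s in seq_len(ncol(bits))) {
      v <- bits[, s]
      if (length(unique(v)) < 2L) next  # non-segregating among included
      side <- v != v[1L]                # away from the most frequent allele
      key <- paste(as.integer(side), collapse = "")
      hit <- match(key, pat_key)
      if (is.na(hit)) {
        pat_key <- c(pat_key, key)
        edges[[length(edges) + 1L]] <- list(clade = tips[side], length = 1L)
      } else {
        edges[[hit]]$length <- edges[[hit]]$length + 1L
      }
    }
  }
  structure(
    list(tips = tips, excluded = alleles[excluded],
         freqs = stats::setNames(freqs, alleles)[tips],
         edges = edges,
         length = sum(vapply(edges, `[[`, integer(1), "length"))),
    class = "parsimony_tree")
}

#' Enumerate the clade bipartitions of a parsimony tree
#'
#' One bipartition per positive-length edge; both sides are always non-empty
#' (trivial splits never arise because each edge is induced by a site that
#' segregates among the included alleles).
#'
#' @param tree a [parsimony_tree()].
#' @return list of `list(clade_A, clade_B)` character vectors of allele
#'   strings; `clade_A` is the side away from the most frequent allele.
#' @export
enumerate_edges <- function(tree) {
  stopifnot(inherits(tree, "parsimony_tree"))
  lapply(tree$edges, function(e) {
    list(clade_A = e$clade, clade_B = setdiff(tree$tips, e$clade))
  })
}

#' Newick string of a parsimony tree
#'
#' Tips are labelled by allele index in `tree$tips` order (1 = most frequent)
#' with branch lengths equal to mutation counts; zero-length pendant edges
#' place an allele at an internal node, mirroring how a perfect phylogeny is
#' usually drawn.
#'
#' @param tree a [parsimony_tree()].
#' @param labels optional tip labels (default `1..k` in `tips` order).
#' @return a Newick string (terminated by `;`).
#' @export
tree_newick <- function(tree, labels = NULL) {
  stopifnot(inherits(tree, "parsimony_tree"))
  k <- length(tree$tips)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  # laminar family of clades (sides away from tip 1), largest first
  clades <- lapply(tree$edges, function(e) match(e$clade, tree$tips))
  lens <- vapply(tree$edges, `[[`, integer(1), "length")
  o <- order(-vapply(clades, length, integer(1)))
  clades <- clades[o]; lens <- lens[o]
  # recursive nesting: clades are laminar, singleton clades are pendant edges
  nest <- function(members, avail) {
    kids <- list()
    taken <- integer(0)
    for (ci in avail) {
      cl <- clades[[ci]]
      if (length(cl) < length(members) && all(cl %in% members) &&
          !any(cl %in% taken)) {
        kids[[length(kids) + 1L]] <- ci
        taken <- c(taken, cl)
      }
    }
    parts <- character(0)
    for (ci in kids) {
      cl <- clades[[ci]]
      inner <- avail[vapply(avail, function(cj)
        cj != ci && all(clades[[cj]] %in% cl) &&
          length(clades[[cj]]) < length(cl), logical(1))]
      body <- if (length(cl) == 1L) labels[cl] else nest(cl, inner)
      parts <- c(parts, sprintf("%s:%d.00", body, lens[ci]))
    }
    for (tp in setdiff(members, taken)) {
      parts <- c(parts, sprintf("%s:0.00", labels[tp]))
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(nest(seq_len(k), seq_along(clades)), ";")
}

#' Clade-membership design columns for the tree-edge scan
#'
#' For each positive-length edge of each block's parsimony tree, two columns
#' are produced: the probability the line belongs to the first clade (the
#' side away from the most frequent allele), and the probability it belongs
#' to neither clade (it carries a rare haplotype or a recombinant allele
#' excluded from the tree). Unblocked SNPs are appended as single
#' minor-allele-probability columns.
#'
#' @param blocks list of blocks with alleles enumerated.
#' @param trees list of [parsimony_tree()] objects, parallel to `blocks`.
#' @param allele_probs line x marker allele-1 probability matrix.
#' @param singletons unblocked marker indices.
#' @param map optional marker map in `allele_probs` column order; positions
#'   singleton-SNP columns.
#' @param tol probability consistency tolerance.
#' @return list with `X` (design), `columns` metadata (one row per column:
#'   `locus`, `edge`, `role` in `clade`/`neither`/`snp`, positions,
#'   `df_group`); the two columns of one edge share a `df_group`, and edges
#'   of the same block share a `locus` but are tested one edge (1 df) at a
#'   time.
#' @export
clade_membership_matrix <- function(blocks, trees, allele_probs,
                                    singletons = integer(0), map = NULL,
                                    tol = 1e-6) {
  stopifnot(length(blocks) == length(trees))
  cols <- list(); meta <- list()
  for (b_i in seq_along(blocks)) {
    b <- blocks[[b_i]]
    tr <- trees[[b_i]]
    if (is.null(tr) || length(tr$edges) == 0L) next
    idx <- seq(b$marker_index_range[1L], b$marker_index_range[2L])
    # per-line probabilities of each common allele, and of "none of the tree"
    pr_common <- vapply(b$alleles$allele,
                       function(h) hap_prob(allele_probs, idx, h),
                       numeric(nrow(allele_probs)))
    pr_common <- matrix(pr_common, nrow(allele_probs),
                        nrow(b$alleles),
                        dimnames = list(NULL, b$alleles$allele))
    if (any(rowSums(pr_common) > 1 + tol)) {
      stop("inconsistent allele probabilities for block ", b_i)
    }
    in_tree <- colnames(pr_common) %in% tr$tips
    p_neither <- pmax(0, 1 - rowSums(pr_common[, in_tree, drop = FALSE]))
    locus_id <- sprintf("%s_blk%04d", b$method, b_i)
    for (e_i in seq_along(tr$edges)) {
      cladeA <- tr$edges[[e_i]]$clade
      pA <- rowSums(pr_common[, colnames(pr_common) %in% cladeA,
                              drop = FALSE])
      cols[[length(cols) + 1L]] <- pA
      meta[[length(meta) + 1L]] <- data.frame(
        locus = locus_id, edge = e_i, role = "clade",
        chrom = b$chrom, start_cM = b$start_cM, end_cM = b$end_cM,
        stringsAsFactors = FALSE)
      cols[[length(cols) + 1L]] <- p_neither
      meta[[length(meta) + 1L]] <- data.frame(
        locus = locus_id, edge = e_i, role = "neither",
        chrom = b$chrom, start_cM = b$start_cM, end_cM = b$end_cM,
        stringsAsFactors = FALSE)
    }
  }
  for (s in singletons) {
    p1 <- allele_probs[, s]
    minor_is_1 <- mean(p1) <= 0.5
    cols[[length(cols) + 1L]] <- if (minor_is_1) p1 else 1 - p1
    meta[[length(meta) + 1L]] <- data.frame(
      locus = paste0("snp_", colnames(allele_probs)[s]), edge = NA_integer_,
      role = "snp",
      chrom = if (is.null(map)) NA else map$chrom[s],
      start_cM = if (is.null(map)) NA_real_ else map$cM[s],
      end_cM = if (is.null(map)) NA_real_ else map$cM[s],
      stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, cols)
  columns <- do.call(rbind, meta)
  rownames(columns) <- NULL
  key <- paste(columns$locus, columns$edge)
  columns$df_group <- match(key, unique(key))  # one group per (locus, edge)
  rownames(X) <- rownames(allele_probs)
  colnames(X) <- sprintf("%s.e%s.%s", columns$locus,
                         ifelse(is.na(columns$edge), "0", columns$edge),
                         columns$role)
  list(X = X, columns = columns)
}
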