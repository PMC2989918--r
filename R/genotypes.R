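# Genotype I/O, marker filtering, tied-marker ordering, and probabilistic
# imputation of missing haploid calls.

#' Minor-allele frequency implied by a carrier-count threshold
#'
#' The MAF floor equivalent to requiring at least `n_carriers` of `n_lines`
#' haploid lines to carry the minor allele.
#'
#' @param n_carriers minimum number of minor-allele carriers.
#' @param n_lines panel size.
#' @return `n_carriers / n_lines`.
#' @export
maf_for_carriers <- function(n_carriers, n_lines) {
  stopifnot(n_carriers >= 0, n_lines >= 1, n_carriers <= n_lines)
  n_carriers / n_lines
}

#' Write and read haploid genotypes
#'
#' Two dialects are supported. `"csv"` writes the calls as a lines x markers
#' table (header row = marker IDs, first column = line IDs, missing = empty)
#' with the map in a side file `<path>.map.csv` (`marker`, `chrom`, `cM`).
#' `"ped"` writes PLINK-style `.ped`/`.map`: haploid lines are emitted as
#' homozygous diploids (`0 -> A A`, `1 -> B B`, missing -> `0 0`); on reading,
#' heterozygous diploid genotypes (e.g. `A B`) are collapsed to missing, as
#' residual heterozygosity in an inbred panel is treated as a bad call.
#'
#' @param G line x marker 0/1 matrix with dimnames.
#' @param map data.frame (`marker`, `chrom`, `cM`) in `G`'s column order.
#' @param path output path; for `"ped"`, `.ped`/`.map` extensions are added.
#' @param dialect `"csv"` or `"ped"`.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns `list(genotypes, map)`.
#' @export
write_genotypes <- function(G, map, path, dialect = c("csv", "ped")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(G), ncol(G) == nrow(map),
            identical(colnames(G), map$marker))
  if (dialect == "csv") {
    df <- data.frame(line = rownames(G), G, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    utils::write.csv(map, paste0(path, ".map.csv"), row.names = FALSE)
  } else {
    code <- matrix("0 0", nrow(G), ncol(G))
    code[!is.na(G) & G == 0L] <- "A A"
    code[!is.na(G) & G == 1L] <- "B B"
    ped <- cbind(rownames(G), rownames(G), "0", "0", "0", "-9", code)
    utils::write.table(ped, paste0(path, ".ped"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = " ")
    utils::write.table(
      data.frame(map$chrom, map$marker, map$cM, 0L),
      paste0(path, ".map"), quote = FALSE,
      row.names = FALSE, col.names = FALSE, sep = " "
    )
  }
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, dialect = c("csv", "ped")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    map <- utils::read.csv(paste0(path, ".map.csv"), stringsAsFactors = FALSE)
    G <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(G) <- "integer"
    rownames(G) <- df[[1L]]
    bad <- which(!(G %in% c(0L, 1L, NA)))
    if (length(bad)) {
      stop("unknown genotype code at data row ",
           ((bad[1L] - 1L) %% nrow(G)) + 1L)
    }
  } else {
    ped <- utils::read.table(paste0(path, ".ped"), stringsAsFactors = FALSE,
                             colClasses = "character")
    map <- utils::read.table(paste0(path, ".map"), stringsAsFactors = FALSE,
                             col.names = c("chrom", "marker", "cM", "bp"))
    map <- data.frame(marker = map$marker, chrom = map$chrom, cM = map$cM,
                      stringsAsFactors = FALSE)
    n_alleles <- ncol(ped) - 6L
    if (n_alleles != 2L * nrow(map)) {
      stop("ped has ", n_alleles, " allele columns but map lists ",
           nrow(map), " markers")
    }
    a1 <- as.matrix(ped[, 6L + 2L * seq_len(nrow(map)) - 1L])
    a2 <- as.matrix(ped[, 6L + 2L * seq_len(nrow(map))])
    bad <- !(a1 %in% c("A", "B", "0")) | !(a2 %in% c("A", "B", "0"))
    if (any(bad)) {
      stop("unknown allele code in .ped at line ", which(rowSums(bad) > 0)[1L])
    }
    G <- matrix(NA_integer_, nrow(ped), nrow(map))
    G[a1 == "A" & a2 == "A"] <- 0L
    G[a1 == "B" & a2 == "B"] <- 1L
    # heterozygous (A B / B A) and any genotype with a 0 stay missing
    rownames(G) <- ped[[2L]]
    colnames(G) <- map$marker
  }
  if (!identical(colnames(G), map$marker)) {
    stop("marker IDs in genotype table and map disagree")
  }
  list(genotypes = G, map = map)
}

minor_carrier_count <- function(g) {
  n1 <- sum(g == 1L, na.rm = TRUE)
  n0 <- sum(g == 0L, na.rm = TRUE)
  min(n0, n1)
}

#' Filter markers and collapse duplicate lines
#'
#' Removes markers whose minor-allele carrier count (over non-missing calls)
#' is below threshold and, optionally, markers without a map position.
#' Duplicate lines -- pairs whose calls agree at every jointly observed
#' marker, with at least `dup_overlap` of markers jointly observed -- are
#' reduced to the first line in panel order.
#'
#' @param G line x marker 0/1 matrix.
#' @param map marker map data.frame (`marker`, `chrom`, `cM`); markers missing
#'   from `map` are unmapped.
#' @param min_minor_carriers carrier-count threshold (retained iff count `>=`
#'   threshold). Mutually exclusive with `maf_min`.
#' @param maf_min MAF threshold; converted to a carrier count via
#'   `ceiling(maf_min * n_lines)`.
#' @param require_mapped drop markers absent from `map`.
#' @param drop_duplicate_lines collapse duplicate lines as described.
#' @param dup_overlap minimum fraction of markers jointly observed for a pair
#'   to be considered comparable (duplicate detection ignores missing calls).
#' @return `list(genotypes, map, dropped_markers, dropped_lines)`.
#' @export
filter_markers <- function(G, map, min_minor_carriers = NULL, maf_min = NULL,
                           require_mapped = TRUE, drop_duplicate_lines = FALSE,
                           dup_overlap = 0.95) {
  stopifnot(is.matrix(G), xor(is.null(min_minor_carriers), is.null(maf_min)))
  if (is.null(min_minor_carriers)) {
    min_minor_carriers <- ceiling(maf_min * nrow(G))
  }
  mapped <- colnames(G) %in% map$marker
  carriers <- apply(G, 2L, minor_carrier_count)
  keep <- carriers >= min_minor_carriers & (mapped | !require_mapped)
  if (!any(keep)) warning("no markers pass the filter")
  dropped_markers <- colnames(G)[!keep]
  G2 <- G[, keep, drop = FALSE]
  map2 <- map[match(colnames(G2), map$marker), , drop = FALSE]
  map2 <- map2[!is.na(map2$marker), , drop = FALSE]
  rownames(map2) <- NULL

  dropped_lines <- character(0)
  if (drop_duplicate_lines && nrow(G2) > 1L) {
    keep_line <- rep(TRUE, nrow(G2))
    for (i in seq_len(nrow(G2) - 1L)) {
      if (!keep_line[i]) next
      gi <- G2[i, ]
      for (j in seq((i + 1L), nrow(G2))) {
        if (!keep_line[j]) next
        gj <- G2[j, ]
        both <- !is.na(gi) & !is.na(gj)
        if (mean(both) >= dup_overlap && all(gi[both] == gj[both])) {
          keep_line[j] <- FALSE
        }
      }
    }
    dropped_lines <- rownames(G2)[!keep_line]
    G2 <- G2[keep_line, , drop = FALSE]
  }
  list(genotypes = G2, map = map2,
       dropped_markers = dropped_markers, dropped_lines = dropped_lines)
}

# all permutations of 1..n as a matrix (n! rows); n is at most 8 here
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# sum of adjacent-pair r2 over a marker index sequence (NA pairs contribute 0)
adjacency_objective <- function(G, ord) {
  if (length(ord) < 2L) return(0)
  s <- 0
  for (k in seq_len(length(ord) - 1L)) {
    v <- ld_r2(G[, ord[k]], G[, ord[k + 1L]])$value
    if (!is.na(v)) s <- s + v
  }
  s
}

#' Order markers within tied map positions to maximize adjacent LD
#'
#' Markers sharing a cM position have unknown relative order. Within every
#' tied run, this chooses the permutation maximizing the sum of adjacent-pair
#' r-squared including the pairs formed with the flanking non-tied markers:
#' exhaustively for runs of up to `exhaustive_max` markers, and by repeated
#' 2-opt local search from the input order above that. Marker IDs break exact
#' objective ties, so the result is deterministic. Only within-tie order
#' changes; cM values and the marker multiset are untouched.
#'
#' @param G line x marker 0/1 matrix in `map` order.
#' @param map data.frame (`marker`, `chrom`, `cM`) sorted by (chrom, cM).
#' @param exhaustive_max largest tied-run size searched exhaustively.
#' @return `list(genotypes, map)` with columns/rows reordered within ties.
#' @export
order_tied_markers <- function(G, map, exhaustive_max = 8L) {
  stopifnot(ncol(G) == nrow(map), identical(colnames(G), map$marker))
  o <- order(map$chrom, map$cM)
  stopifnot(identical(o, seq_len(nrow(map))))  # pre: already map-sorted
  runs <- split(seq_len(nrow(map)), list(map$chrom, map$cM), drop = TRUE)
  perm <- seq_len(nrow(map))
  for (run in runs) {
    n <- length(run)
    if (n < 2L) next
    left <- if (min(run) > 1L && map$chrom[min(run) - 1L] == map$chrom[run[1L]]) {
      min(run) - 1L
    } else NA_integer_
    right <- if (max(run) < nrow(map) &&
                 map$chrom[max(run) + 1L] == map$chrom[run[1L]]) {
      max(run) + 1L
    } else NA_integer_
    score <- function(ord_in_run) {
      seqn <- c(left, run[ord_in_run], right)
      adjacency_objective(G, seqn[!is.na(seqn)])
    }
    tiebreak <- function(ord_in_run) {
      paste(colnames(G)[run[ord_in_run]], collapse = "\r")
    }
    if (n <= exhaustive_max) {
      P <- all_perms(n)
      sc <- apply(P, 1L, score)
      best <- which(sc > max(sc) - 1e-12)
      if (length(best) > 1L) {
        best <- best[order(vapply(best, function(b) tiebreak(P[b, ]),
                                  character(1)))][1L]
      }
      perm[run] <- run[P[best, ]]
    } else {
      cur <- seq_len(n)
      cur_sc <- score(cur)
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (i in seq_len(n - 1L)) {
          for (j in seq((i + 1L), n)) {
            cand <- cur
            cand[i:j] <- rev(cand[i:j])  # 2-opt segment reversal
            s <- score(cand)
            if (s > cur_sc + 1e-12) {
              cur <- cand; cur_sc <- s; improved <- TRUE
            }
          }
        }
      }
      perm[run] <- run[cur]
    }
  }
  map2 <- map
  map2$marker <- map$marker[perm]
  list(genotypes = G[, perm, drop = FALSE], map = map2)
}

#' Impute missing calls as allele probabilities
#'
#' A windowed nearest-haplotype vote standing in for model-based haplotype
#' imputation: for each missing call, lines are compared to the target line
#' over the `window` flanking markers on each side (proportion of matching
#' calls among jointly observed ones); the `k` most similar lines with an
#' observed call at the target marker vote, weighted by similarity, and the
#' weighted allele-1 frequency is the imputed probability. Non-missing calls
#' pass through as exact 0/1.
#'
#' @param G line x marker 0/1 matrix.
#' @param map marker map in `G` column order (windows never cross
#'   chromosomes).
#' @param window number of flanking markers on each side.
#' @param k number of nearest lines that vote.
#' @param seed integer seed (reserved for stochastic imputation back-ends;
#'   the default vote is deterministic).
#' @return line x marker numeric matrix of allele-1 probabilities.
#' @export
impute_genotypes <- function(G, map, window = 10L, k = 20L, seed = 1L) {
  stopifnot(is.matrix(G), ncol(G) == nrow(map))
  if (any(colSums(!is.na(G)) == 0L)) {
    stop("marker(s) entirely missing cannot be imputed: ",
         paste(colnames(G)[colSums(!is.na(G)) == 0L], collapse = ", "))
  }
  P <- matrix(as.numeric(G), nrow(G), ncol(G), dimnames = dimnames(G))
  miss <- which(is.na(G), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(P)
  chrom_idx <- split(seq_len(nrow(map)), map$chrom)
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1L]; m <- miss[r, 2L]
    idx <- chrom_idx[[as.character(map$chrom[m])]]
    pos <- match(m, idx)
    win <- idx[max(1L, pos - window):min(length(idx), pos + window)]
    win <- setdiff(win, m)
    gi <- G[i, win]
    donors <- which(!is.na(G[, m]))
    if (length(donors) == 0L) stop("no donor for marker ", colnames(G)[m])
    sim <- vapply(donors, function(j) {
      both <- !is.na(gi) & !is.na(G[j, win])
      if (!any(both)) return(0.5)  # uninformative donor
      mean(gi[both] == G[j, win][both])
    }, numeric(1))
    ord <- order(-sim, donors)  # deterministic: similarity, then line index
    top <- donors[ord[seq_len(min(k, length(donors)))]]
    w <- sim[ord[seq_len(min(k, length(donors)))]]
    if (sum(w) == 0) w <- rep(1, length(w))
    P[i, m] <- sum(w * G[top, m]) / sum(w)
  }
  P
}
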