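# Pairwise linkage-disequilibrium and diversity statistics. All LD here is
# complete-case: pairs of lines missing at either locus are dropped, and a
# locus monomorphic on the complete cases yields NA (undefined), never 0.

#' Squared correlation (r-squared) between two biallelic loci
#'
#' Computed over complete cases as the squared Pearson correlation of the
#' 0/1 allele codes, which for haploid data equals D^2 / (pA pa pB pb).
#'
#' @param x,y 0/1 integer vectors of equal length (NA = missing).
#' @return a list with `value` (r-squared in `[0, 1]`, or `NA` if either
#'   locus is monomorphic on complete cases) and `n_informative` (number of
#'   lines observed at both loci).
#' @export
ld_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2L) return(list(value = NA_real_, n_informative = n))
  xs <- x[ok]; ys <- y[ok]
  if (length(unique(xs)) < 2L || length(unique(ys)) < 2L) {
    return(list(value = NA_real_, n_informative = n))
  }
  r <- stats::cor(xs, ys)
  list(value = min(r * r, 1), n_informative = n)
}

#' Standardized multiallelic LD statistic (chi-squared prime)
#'
#' Pearson chi-squared on the k x l haplotype-count table of two categorical
#' loci, standardized by N * (min(k, l) - 1) so the value lies in `[0, 1]`.
#' For two biallelic loci it reduces exactly to [ld_r2()].
#'
#' @param a,b categorical vectors (factors, characters, or integers) of equal
#'   length; NA = missing.
#' @return list with `value` and `n_informative`, as [ld_r2()].
#' @export
chi2prime <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 2L) return(list(value = NA_real_, n_informative = n))
  av <- factor(a[ok]); bv <- factor(b[ok])
  k <- nlevels(av); l <- nlevels(bv)
  if (k < 2L || l < 2L) return(list(value = NA_real_, n_informative = n))
  tab <- table(av, bv)
  exp_ <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - exp_)^2 / exp_)
  list(value = min(chi2 / (n * (min(k, l) - 1L)), 1), n_informative = n)
}

#' Maximum LD to a focal locus within a map window
#'
#' Scans all loci on the focal locus's chromosome whose map distance is at
#' most `window_cM / 2` (a "`window_cM` window" is centered on the focal
#' locus) and returns the largest pairwise LD value, the focal locus itself
#' excluded.
#'
#' @param focal vector of calls at the focal locus.
#' @param focal_pos list or data.frame row with `chrom` and `cM` of the focal
#'   locus.
#' @param others matrix (lines x loci) of candidate loci.
#' @param others_map data.frame with `chrom`, `cM` per column of `others`.
#' @param window_cM full window width in cM (markers within `window_cM / 2`).
#' @param metric `"r2"` or `"chi2prime"`.
#' @param exclude integer column indices of `others` never considered (e.g.
#'   the focal locus itself if present in `others`).
#' @return list with `value` (`NA` if the window is empty or all pairwise
#'   values undefined) and `n_candidates`.
#' @export
max_ld_in_window <- function(focal, focal_pos, others, others_map,
                             window_cM = 20, metric = c("r2", "chi2prime"),
                             exclude = integer(0)) {
  metric <- match.arg(metric)
  stopifnot(nrow(others_map) == ncol(others))
  half <- window_cM / 2
  sel <- which(others_map$chrom == focal_pos$chrom &
                 abs(others_map$cM - focal_pos$cM) <= half)
  sel <- setdiff(sel, exclude)
  if (length(sel) == 0L) return(list(value = NA_real_, n_candidates = 0L))
  f <- if (metric == "r2") ld_r2 else chi2prime
  vals <- vapply(sel, function(j) f(focal, others[, j])$value, numeric(1))
  if (all(is.na(vals))) return(list(value = NA_real_, n_candidates = length(sel)))
  list(value = max(vals, na.rm = TRUE), n_candidates = length(sel))
}

#' Expected heterozygosity from allele frequencies
#'
#' `He = 1 - sum(p_i^2)` for a locus with allele frequencies `freqs`.
#'
#' @param freqs numeric vector of allele frequencies summing to 1.
#' @param tol tolerance on the frequency sum.
#' @return expected heterozygosity in `[0, 1)`.
#' @export
expected_heterozygosity <- function(freqs, tol = 1e-8) {
  stopifnot(all(freqs >= 0))
  if (abs(sum(freqs) - 1) > tol) {
    stop("allele frequencies must sum to 1 (got ", sum(freqs), ")")
  }
  1 - sum(freqs^2)
}

#' Adjacent-pair r-squared along the map
#'
#' r-squared between each marker and its map successor within a chromosome;
#' the column order of `G` must match the row order of `map`.
#'
#' @param G line x marker 0/1 matrix.
#' @param map data.frame with `chrom`, `cM` per marker, map-ordered.
#' @return data.frame (`marker1`, `marker2`, `chrom`, `gap_cM`, `r2`).
#' @export
adjacent_r2 <- function(G, map) {
  stopifnot(ncol(G) == nrow(map))
  out <- lapply(split(seq_len(nrow(map)), map$chrom), function(idx) {
    if (length(idx) < 2L) return(NULL)
    i <- idx[-length(idx)]; j <- idx[-1L]
    data.frame(
      marker1 = colnames(G)[i], marker2 = colnames(G)[j],
      chrom = map$chrom[i], gap_cM = map$cM[j] - map$cM[i],
      r2 = vapply(seq_along(i),
                  function(k) ld_r2(G[, i[k]], G[, j[k]])$value, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Five-number-style summary of an LD or frequency vector
#'
#' @param x numeric vector (NAs dropped).
#' @return named numeric vector: min, median, mean, max.
#' @export
ld_summary <- function(x) {
  x <- x[!is.na(x)]
  c(min = min(x), median = stats::median(x), mean = mean(x), max = max(x))
}
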