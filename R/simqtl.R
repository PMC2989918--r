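# Phenotype simulation: single-SNP and SNP-pair QTL, a summed-marker
# polygene, and Gaussian error, combined with exact in-sample control of the
# QTL variance fraction p and the heritability h2.

#' Representative selection by k-means clustering
#'
#' Clusters items (lines over marker space, or markers over line space) by
#' k-means on the raw 0/1 vectors and returns the item nearest each cluster
#' centroid (Euclidean distance); exact distance ties are broken by a seeded
#' random choice. Missing calls are filled with the item-wise mean for the
#' clustering only. Used both to select a diverse panel of lines and to pick
#' one polygene marker per genomic cluster so no two polygene markers tag the
#' same haplotype block.
#'
#' @param G line x marker 0/1 matrix.
#' @param k number of clusters / representatives.
#' @param target `"lines"` or `"markers"`.
#' @param seed integer seed (k-means initialization and tie-breaks).
#' @return character vector of `k` selected line or marker IDs.
#' @export
kmeans_select <- function(G, k = 400L, target = c("lines", "markers"),
                          seed = 1L) {
  target <- match.arg(target)
  M <- if (target == "lines") G else t(G)
  stopifnot(k <= nrow(M))
  if (k == nrow(M)) return(rownames(M))
  # column-mean fill for clustering only
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    for (j in which(colSums(is.na(M)) > 0L)) M[is.na(M[, j]), j] <- mu[j]
  }
  storage.mode(M) <- "double"
  with_seed(seed, {
    km <- stats::kmeans(M, centers = k, iter.max = 50L, nstart = 1L)
    sel <- character(k)
    for (cl in seq_len(k)) {
      idx <- which(km$cluster == cl)
      d <- sqrt(rowSums((M[idx, , drop = FALSE] -
                           matrix(km$centers[cl, ], length(idx),
                                  ncol(M), byrow = TRUE))^2))
      best <- idx[d <= min(d) + 1e-12]
      sel[cl] <- rownames(M)[if (length(best) > 1L) sample(best, 1L) else best]
    }
    sel
  })
}

#' Choose QTL SNPs spread over the map with low mutual LD
#'
#' The genome is swept in `n` equal-cM strata (over the concatenated
#' chromosome maps); within each stratum, among markers with MAF at least
#' `maf_min`, the SNP minimizing the maximum r-squared to the already-chosen
#' set is taken. A stratum with no eligible SNP borrows the nearest eligible
#' SNP outside it, with a warning.
#'
#' @param G line x marker 0/1 matrix.
#' @param map marker map in column order.
#' @param n number of QTL SNPs.
#' @param maf_min MAF eligibility floor for QTL.
#' @return character vector of `n` marker IDs.
#' @export
choose_qtl_snps <- function(G, map, n = 100L, maf_min = 0.10) {
  p <- colMeans(G, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  eligible <- maf >= maf_min
  if (sum(eligible) < n) stop("fewer than n markers pass maf_min")
  # global coordinate: chromosome offsets stack the maps end to end
  chroms <- unique(map$chrom)
  offs <- stats::setNames(cumsum(c(0, vapply(chroms, function(ch)
    max(map$cM[map$chrom == ch]) + 1, numeric(1))))[seq_along(chroms)], chroms)
  gpos <- map$cM + offs[as.character(map$chrom)]
  brk <- seq(min(gpos), max(gpos), length.out = n + 1L)
  stratum <- pmin(findInterval(gpos, brk, rightmost.closed = TRUE), n)
  chosen <- integer(0)
  for (s in seq_len(n)) {
    cand <- which(stratum == s & eligible & !(seq_along(gpos) %in% chosen))
    if (length(cand) == 0L) {
      pool <- which(eligible & !(seq_along(gpos) %in% chosen))
      mid <- (brk[s] + brk[s + 1L]) / 2
      cand <- pool[which.min(abs(gpos[pool] - mid))]
      warning("stratum ", s, " empty; borrowing nearest eligible SNP")
    }
    if (length(chosen) == 0L) {
      pick <- cand[1L]
    } else {
      worst <- vapply(cand, function(m) {
        mx <- 0
        for (c0 in chosen) {
          v <- ld_r2(G[, m], G[, c0])$value
          if (!is.na(v) && v > mx) mx <- v
        }
        mx
      }, numeric(1))
      pick <- cand[which.min(worst)]
    }
    chosen <- c(chosen, pick)
  }
  colnames(G)[chosen]
}

#' QTL specification
#'
#' @param kind `"single_snp_removed"` (causal SNP dropped from the scan
#'   design), `"single_snp_retained"`, or `"snp_pair"` (effect carried by a
#'   two-SNP allele combination).
#' @param markers one marker ID, or two for `"snp_pair"`.
#' @param combo for `"snp_pair"`, the targeted allele pair, e.g. `c(0, 0)`.
#' @param p proportion of phenotypic variance due to the QTL.
#' @param chrom,cM QTL position (for pairs, the pair midpoint).
#' @return a `qtl_spec` list.
#' @export
qtl_spec <- function(kind, markers, combo = NULL, p, chrom, cM) {
  kind <- match.arg(kind,
                    c("single_snp_removed", "single_snp_retained", "snp_pair"))
  stopifnot(p > 0, p < 1,
            length(markers) == if (kind == "snp_pair") 2L else 1L)
  structure(list(kind = kind, markers = markers, combo = combo, p = p,
                 chrom = chrom, cM = cM), class = "qtl_spec")
}

#' Carrier indicator of a QTL specification
#'
#' 0/1 vector over lines: for a single-SNP QTL the allele code itself, for a
#' pair QTL the indicator of carrying the targeted allele combination (the
#' intersection of the two single-SNP carrier sets); `NA` where a component
#' call is missing.
#'
#' @param G line x marker matrix.
#' @param qtl a [qtl_spec()].
#' @return numeric vector of length `nrow(G)`.
#' @export
qtl_indicator <- function(G, qtl) {
  if (qtl$kind == "snp_pair") {
    a <- G[, qtl$markers[1L]]; b <- G[, qtl$markers[2L]]
    ind <- as.numeric(a == qtl$combo[1L] & b == qtl$combo[2L])
    ind[is.na(a) | is.na(b)] <- NA
  } else {
    ind <- as.numeric(G[, qtl$markers])
  }
  ind
}

#' Simulate one phenotype: QTL + polygene + error
#'
#' The phenotype is `a*q + g + e`: `q` the centered QTL carrier indicator
#' with additive effect inversely proportional to its standard deviation (so
#' QTL of different MAF contribute equal variance), `g` the centered sum of
#' polygene marker scores, `e` standard-normal error. With
#' `exact_scaling = TRUE` (default), the polygene and error components are
#' orthogonalized against the components before them and all three are
#' rescaled so that the realized in-sample variance fractions are exactly
#' `p` (QTL) and `h2` (QTL + polygene); with `FALSE`, components are scaled
#' by their sample standard deviations only, so fractions hold in
#' expectation.
#'
#' @param G line x marker matrix (missing QTL/polygene calls are mean-filled
#'   for the simulation).
#' @param qtl a [qtl_spec()].
#' @param h2 heritability, in `(0, 1)`; must be `>= p`.
#' @param polygene_markers marker IDs whose summed scores form the polygene.
#' @param seed integer seed for the error draw.
#' @param exact_scaling exact in-sample variance control (see above).
#' @return numeric phenotype vector (one value per line) with a `truth`
#'   attribute: the spec, `h2`, and realized variance fractions.
#' @export
simulate_phenotype <- function(G, qtl, h2, polygene_markers, seed = 1L,
                               exact_scaling = TRUE) {
  stopifnot(inherits(qtl, "qtl_spec"), h2 > 0, h2 < 1, qtl$p <= h2)
  n <- nrow(G)
  q <- qtl_indicator(G, qtl)
  if (anyNA(q)) q[is.na(q)] <- mean(q, na.rm = TRUE)
  if (stats::sd(q) == 0) stop("monomorphic QTL: carrier indicator has sd 0")
  Gp <- G[, polygene_markers, drop = FALSE]
  if (anyNA(Gp)) {
    mu <- colMeans(Gp, na.rm = TRUE)
    for (j in which(colSums(is.na(Gp)) > 0L)) Gp[is.na(Gp[, j]), j] <- mu[j]
  }
  g_raw <- rowSums(Gp)
  e_raw <- with_seed(seed, stats::rnorm(n))
  unit <- function(v) {
    v <- v - mean(v)
    v / stats::sd(v)
  }
  qs <- unit(q)   # effect 1/sd(q) applied to centered indicator
  if (exact_scaling) {
    # orthogonalize each later component against the earlier ones so the
    # in-sample variance decomposition is exact
    gs <- unit(stats::lm.fit(cbind(1, qs), g_raw)$residuals)
    es <- unit(stats::lm.fit(cbind(1, qs, gs), e_raw)$residuals)
  } else {
    gs <- unit(g_raw)
    es <- unit(e_raw)
  }
  y <- sqrt(qtl$p) * qs + sqrt(h2 - qtl$p) * gs + sqrt(1 - h2) * es
  vq <- stats::var(sqrt(qtl$p) * qs) / stats::var(y)
  vg <- stats::var(sqrt(qtl$p) * qs + sqrt(h2 - qtl$p) * gs) / stats::var(y)
  attr(y, "truth") <- list(qtl = qtl, h2 = h2, realized_p = vq,
                           realized_h2 = vg, seed = seed)
  names(y) <- rownames(G)
  y
}

#' Build SNP-pair QTL specifications from a blocking
#'
#' For sliding windows the targeted pair is block positions 1-2 with allele
#' combination `(0, 0)`; for four-gamete or diversity blocks it is the two
#' center SNPs (`floor` of the midpoint and its successor). Specs whose
#' carrier frequency falls below `min_carrier_freq` are dropped. If more
#' specs are requested than blocks exist, the supplementary combination
#' `(0, 1)` is assigned to a seeded random subset of blocks.
#'
#' @param blocks list of blocks.
#' @param G line x marker matrix.
#' @param map marker map.
#' @param method `"slidewin3"`, `"four_gamete"` or `"diversity"` (controls
#'   pair placement).
#' @param p QTL variance fraction stored on each spec.
#' @param n_specs number of specs wanted; `NULL` = one per eligible block.
#' @param min_carrier_freq minimum carrier frequency of the combination.
#' @param seed seed for the supplementary-combination subset.
#' @return list of [qtl_spec()] objects.
#' @export
make_pair_qtl_specs <- function(blocks, G, map,
                                method = c("slidewin3", "four_gamete",
                                           "diversity"),
                                p = 0.06, n_specs = NULL,
                                min_carrier_freq = 0.028, seed = 1L) {
  method <- match.arg(method)
  build <- function(b, combo) {
    rng <- b$marker_index_range
    n_snp <- rng[2L] - rng[1L] + 1L
    if (n_snp < 2L) return(NULL)
    if (method == "slidewin3") {
      i1 <- rng[1L]; i2 <- rng[1L] + 1L
    } else {
      i1 <- rng[1L] + (n_snp - 2L) %/% 2L  # floor-midpoint pair
      i2 <- i1 + 1L
    }
    mk <- map$marker[c(i1, i2)]
    a <- G[, i1]; b2 <- G[, i2]
    ok <- !is.na(a) & !is.na(b2)
    cf <- mean(a[ok] == combo[1L] & b2[ok] == combo[2L])
    if (!is.finite(cf) || cf < min_carrier_freq || cf > 1 - min_carrier_freq) {
      return(NULL)
    }
    qtl_spec("snp_pair", mk, combo = combo, p = p,
             chrom = b$chrom, cM = mean(map$cM[c(i1, i2)]))
  }
  primary <- Filter(Negate(is.null), lapply(blocks, build, combo = c(0L, 0L)))
  if (is.null(n_specs) || length(primary) >= n_specs) {
    if (!is.null(n_specs)) primary <- primary[seq_len(n_specs)]
    return(primary)
  }
  extra_n <- n_specs - length(primary)
  supp <- with_seed(seed, {
    idx <- sample(seq_along(blocks))
    out <- list()
    for (i in idx) {
      s <- build(blocks[[i]], combo = c(0L, 1L))
      if (!is.null(s)) out[[length(out) + 1L]] <- s
      if (length(out) >= extra_n) break
    }
    out
  })
  c(primary, supp)
}

#' Simulation driver: phenotype matrix over a QTL set
#'
#' Each QTL produces `reps_per_qtl` phenotypes (differing only in the error
#' draw), giving `length(qtls) * reps_per_qtl` replicates per `(p, h2)` cell.
#'
#' @param G line x marker matrix.
#' @param qtls list of [qtl_spec()] objects.
#' @param h2 heritability.
#' @param polygene_markers polygene marker IDs.
#' @param reps_per_qtl phenotypes per QTL.
#' @param seed base seed; replicate `r` of QTL `i` uses
#'   `seed + (i - 1) * reps_per_qtl + (r - 1)`.
#' @param exact_scaling see [simulate_phenotype()].
#' @return list: `Y` (replicate x line matrix), `truths` (list of truth
#'   records parallel to rows).
#' @export
simulate_phenotype_set <- function(G, qtls, h2, polygene_markers,
                                   reps_per_qtl = 10L, seed = 1L,
                                   exact_scaling = TRUE) {
  n_rep <- length(qtls) * reps_per_qtl
  Y <- matrix(NA_real_, n_rep, nrow(G))
  truths <- vector("list", n_rep)
  r <- 0L
  for (i in seq_along(qtls)) {
    for (k in seq_len(reps_per_qtl)) {
      r <- r + 1L
      y <- simulate_phenotype(G, qtls[[i]], h2, polygene_markers,
                              seed = seed + r - 1L,
                              exact_scaling = exact_scaling)
      Y[r, ] <- y
      truths[[r]] <- attr(y, "truth")
    }
  }
  colnames(Y) <- rownames(G)
  list(Y = Y, truths = truths)
}
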