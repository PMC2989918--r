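# Power / false-discovery-rate evaluation of association scans against
# simulated QTL truth, bootstrap power at a target empirical FDR,
# permutation-based experiment-wise thresholds and effective test numbers,
# and the marker-QTL LD information-content comparison.

# distance (cM) from a scan locus to a QTL position: SNP loci use the point
# position, block loci the nearest boundary of the closed cM interval
# (distance 0 if the QTL lies inside the block)
locus_qtl_distance <- function(chrom, start_cM, end_cM, qtl_chrom, qtl_cM) {
  ifelse(chrom != qtl_chrom, Inf,
         ifelse(qtl_cM >= start_cM & qtl_cM <= end_cM, 0,
                pmin(abs(qtl_cM - start_cM), abs(qtl_cM - end_cM))))
}

#' Classify scan discoveries against a QTL truth
#'
#' A locus significant at `alpha` is a true discovery iff its nearest point
#' (the SNP position, or the closest boundary of the block interval) lies
#' within `window_cM` of the QTL position on the same chromosome.
#'
#' @param scan scan result data.frame from [lrt_scan()].
#' @param qtl a [qtl_spec()] (its `chrom`/`cM` define the truth position).
#' @param window_cM half-window in cM (10 corresponds to a 20 cM window
#'   centered on the QTL).
#' @param alpha significance threshold on the scan p-values.
#' @return list: `n_true`, `n_total` (significant loci), `hit` (at least one
#'   true discovery).
#' @export
classify_discoveries <- function(scan, qtl, window_cM = 10, alpha) {
  ok <- scan$tested & !is.na(scan$p)
  sig <- ok & scan$p <= alpha
  d <- locus_qtl_distance(scan$chrom, scan$start_cM, scan$end_cM,
                          qtl$chrom, qtl$cM)
  n_total <- sum(sig)
  n_true <- sum(sig & d <= window_cM)
  list(n_true = n_true, n_total = n_total, hit = n_true > 0L)
}

#' Power and FDR as a function of the nominal threshold
#'
#' For every distinct observed p-value as threshold `alpha`: power is the
#' fraction of replicates with at least one true discovery (a significant
#' locus within `window_cM` of that replicate's QTL), and FDR is
#' `1 - true / total` pooled over replicates. Thresholds at which nothing is
#' significant are skipped (FDR undefined).
#'
#' @param pmatrix replicate x locus p-value matrix (NA = untested).
#' @param loci data.frame (`chrom`, `start_cM`, `end_cM`) per column of
#'   `pmatrix`.
#' @param truths list of truth records (each with `$qtl`), one per row.
#' @param window_cM truth half-window in cM.
#' @param max_points cap on the number of curve points; thresholds are
#'   thinned to p-value quantiles above this.
#' @return data.frame (`alpha`, `power`, `fdr`, `n_true`, `n_total`), sorted
#'   by `alpha`; power is non-decreasing in `alpha`.
#' @export
power_fdr_curve <- function(pmatrix, loci, truths, window_cM = 10,
                            max_points = 2000L) {
  stopifnot(nrow(pmatrix) == length(truths), ncol(pmatrix) == nrow(loci))
  R <- nrow(pmatrix)
  # per replicate: which loci are true for its QTL
  true_mask <- matrix(FALSE, R, ncol(pmatrix))
  for (r in seq_len(R)) {
    q <- truths[[r]]$qtl
    d <- locus_qtl_distance(loci$chrom, loci$start_cM, loci$end_cM,
                            q$chrom, q$cM)
    true_mask[r, ] <- d <= window_cM
  }
  pv <- as.vector(pmatrix)
  keep <- !is.na(pv)
  alphas <- sort(unique(pv[keep]))
  if (length(alphas) > max_points) {
    alphas <- unique(stats::quantile(pv[keep],
                                     probs = seq(0, 1,
                                                 length.out = max_points),
                                     type = 1L, names = FALSE))
  }
  # step-function counts via sorted pooled p-values (fully vectorized: this
  # runs inside every bootstrap resample)
  ord <- order(pv[keep])
  p_sorted <- pv[keep][ord]
  true_sorted <- as.vector(true_mask)[keep][ord]
  cum_true <- cumsum(true_sorted)
  # per-replicate minimum true p (for power)
  pm_true <- pmatrix
  pm_true[!true_mask] <- NA
  min_true_p <- suppressWarnings(apply(pm_true, 1L, min, na.rm = TRUE))
  min_true_p[!is.finite(min_true_p)] <- Inf
  n_total <- findInterval(alphas, p_sorted)
  ok <- n_total > 0L
  alphas <- alphas[ok]; n_total <- n_total[ok]
  n_true <- cum_true[n_total]
  power <- findInterval(alphas, sort(min_true_p)) / R
  out <- data.frame(alpha = alphas, power = power,
                    fdr = 1 - n_true / n_total,
                    n_true = n_true, n_total = n_total)
  rownames(out) <- NULL
  out
}

#' Interpolate power at a target FDR from a power/FDR curve
#'
#' Local linear regression of power on FDR over the nearest `frac` of curve
#' points around the target.
#'
#' @param curve data.frame from [power_fdr_curve()].
#' @param fdr_target target FDR.
#' @param frac fraction of curve points in the local fit.
#' @return interpolated power in `[0, 1]` (`NA` for an empty curve).
#' @export
interp_power_at_fdr <- function(curve, fdr_target, frac = 0.10) {
  if (is.null(curve) || nrow(curve) == 0L) return(NA_real_)
  k <- max(2L, ceiling(frac * nrow(curve)))
  nb <- curve[order(abs(curve$fdr - fdr_target)), ][seq_len(min(k, nrow(curve))), ]
  if (length(unique(nb$fdr)) < 2L) return(mean(nb$power))
  fit <- stats::lm(power ~ fdr, data = nb)
  unname(pmin(1, pmax(0, stats::predict(fit,
                                        newdata = data.frame(fdr = fdr_target)))))
}

#' Bootstrap power at a target empirical FDR
#'
#' Resamples replicate rows of the p-value matrix with replacement,
#' recomputes the power/FDR curve per resample, and interpolates power at
#' `fdr_target` by a local linear regression of power on FDR over the
#' nearest `neighborhood` fraction of curve points. The estimate is the mean
#' of the bootstrap distribution and the standard error its standard
#' deviation.
#'
#' @inheritParams power_fdr_curve
#' @param fdr_target target empirical FDR (e.g. 0.10 or 0.20).
#' @param n_boot number of bootstrap resamples.
#' @param neighborhood fraction of curve points used in the local fit.
#' @param seed integer seed.
#' @return list: `power`, `se`, `n_bootstrap`, `fdr_target`, `unreliable`
#'   (`TRUE` when the target FDR fell outside the achieved curve range in
#'   more than half the resamples).
#' @export
bootstrap_power_at_fdr <- function(pmatrix, loci, truths, fdr_target,
                                   n_boot = 1000L, window_cM = 10,
                                   neighborhood = 0.10, seed = 1L) {
  stopifnot(nrow(pmatrix) >= 10L)
  with_seed(seed, {
    R <- nrow(pmatrix)
    est <- numeric(n_boot)
    out_of_range <- logical(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(R, R, replace = TRUE)
      curve <- power_fdr_curve(pmatrix[idx, , drop = FALSE], loci,
                               truths[idx], window_cM = window_cM)
      out_of_range[b] <- is.null(curve) ||
        fdr_target < min(curve$fdr) || fdr_target > max(curve$fdr)
      est[b] <- interp_power_at_fdr(curve, fdr_target, neighborhood)
    }
    list(power = mean(est, na.rm = TRUE),
         se = stats::sd(est, na.rm = TRUE),
         n_bootstrap = n_boot, fdr_target = fdr_target,
         unreliable = mean(out_of_range) > 0.5)
  })
}

#' Permutation threshold for an experiment-wise error rate
#'
#' Permutes the phenotype against the (jointly held) genotype/kinship design
#' `n_perm` times, records the genome-wide minimum p-value of each permuted
#' scan, and takes the `eer` quantile of that distribution as the
#' significance threshold. The effective number of independent tests is
#' recovered from the Bonferroni/Sidak relation
#' `effective_tests = log(1 - eer) / log(1 - threshold)`.
#'
#' @param y phenotype vector.
#' @param scan_fun function of a (permuted) phenotype returning a full
#'   vector of p-values.
#' @param eer experiment-wise type I error rate.
#' @param n_perm number of permutations; must satisfy `n_perm * eer >= 5`.
#' @param seed integer seed.
#' @return list: `eer`, `p_threshold`, `effective_tests`, `n_permutations`,
#'   `min_p` (the permutation minimum-p distribution).
#' @export
permutation_threshold <- function(y, scan_fun, eer = 0.05, n_perm = 1000L,
                                  seed = 1L) {
  if (n_perm * eer < 5) {
    stop("n_perm too small for the requested quantile (n_perm * eer < 5)")
  }
  with_seed(seed, {
    minp <- vapply(seq_len(n_perm), function(b) {
      pv <- scan_fun(sample(y))
      min(pv, na.rm = TRUE)
    }, numeric(1))
    thr <- unname(stats::quantile(minp, probs = eer, type = 1L))
    list(eer = eer, p_threshold = thr,
         effective_tests = log(1 - eer) / log(1 - thr),
         n_permutations = n_perm, min_p = minp)
  })
}

#' Marker-QTL LD comparison across methods
#'
#' For each QTL and each method, the maximum LD between the QTL carrier
#' indicator and a marker within `window_cM`: r-squared for single SNPs,
#' the multiallelic chi-squared-prime for haplotype-block labels, and
#' r-squared against clade-membership indicators for tree edges. Reports the
#' per-method mean and SD of the max LD and the pairwise counts of one
#' method beating another by at least `margin` LD units.
#'
#' @param qtls list of [qtl_spec()] objects.
#' @param methods named list; each element is a list with `kind`
#'   (`"snp"`, `"blocks"` or `"edges"`) and the matching data: `G`+`map`
#'   for `"snp"`; `blocks`+`G` for `"blocks"`; `blocks`+`trees`+`G` for
#'   `"edges"`.
#' @param G line x marker matrix the QTL indicators are computed from.
#' @param map marker map.
#' @param window_cM half-window around each QTL.
#' @param margin superiority margin in LD units.
#' @return list: `max_ld` (QTL x method matrix), `superiority` (method x
#'   method counts, diagonal NA), `summary` (per-method mean and SD).
#' @export
qtl_ld_comparison <- function(qtls, methods, G, map, window_cM = 10,
                              margin = 0.1) {
  q_ind <- lapply(qtls, function(q) qtl_indicator(G, q))
  max_ld <- matrix(NA_real_, length(qtls), length(methods),
                   dimnames = list(NULL, names(methods)))
  for (mi in seq_along(methods)) {
    m <- methods[[mi]]
    for (qi in seq_along(qtls)) {
      q <- qtls[[qi]]
      ind <- q_ind[[qi]]
      best <- NA_real_
      if (m$kind == "snp") {
        sel <- which(map$chrom == q$chrom & abs(map$cM - q$cM) <= window_cM &
                       !(map$marker %in% q$markers))
        for (s in sel) {
          v <- ld_r2(ind, m$G[, s])$value
          if (!is.na(v) && (is.na(best) || v > best)) best <- v
        }
      } else {
        for (b_i in seq_along(m$blocks)) {
          b <- m$blocks[[b_i]]
          d <- locus_qtl_distance(b$chrom, b$start_cM, b$end_cM, q$chrom, q$cM)
          if (d > window_cM) next
          idx <- seq(b$marker_index_range[1L], b$marker_index_range[2L])
          sub <- m$G[, idx, drop = FALSE]
          okh <- rowSums(is.na(sub)) == 0L
          lab <- rep(NA_character_, nrow(sub))
          lab[okh] <- apply(sub[okh, , drop = FALSE], 1L, paste, collapse = "")
          if (m$kind == "blocks") {
            v <- chi2prime(ind, lab)$value
            if (!is.na(v) && (is.na(best) || v > best)) best <- v
          } else {  # edges: r2 of QTL vs each clade indicator
            tr <- m$trees[[b_i]]
            if (is.null(tr) || length(tr$edges) == 0L) next
            for (e in tr$edges) {
              memb <- ifelse(is.na(lab), NA,
                             ifelse(lab %in% e$clade, 1,
                                    ifelse(lab %in% tr$tips, 0, NA)))
              v <- ld_r2(ind, memb)$value
              if (!is.na(v) && (is.na(best) || v > best)) best <- v
            }
          }
        }
      }
      max_ld[qi, mi] <- best
    }
  }
  M <- length(methods)
  sup <- matrix(NA_real_, M, M, dimnames = list(names(methods), names(methods)))
  for (a in seq_len(M)) for (b in seq_len(M)) {
    if (a == b) next
    ok <- !is.na(max_ld[, a]) & !is.na(max_ld[, b])
    sup[a, b] <- sum(max_ld[ok, a] >= max_ld[ok, b] + margin)
  }
  list(max_ld = max_ld, superiority = sup,
       summary = data.frame(method = names(methods),
                            mean_ld = colMeans(max_ld, na.rm = TRUE),
                            sd_ld = apply(max_ld, 2L, stats::sd, na.rm = TRUE),
                            stringsAsFactors = FALSE))
}
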