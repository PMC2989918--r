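# Mixed-model association machinery: allele-sharing kinship, spectral
# (EMMA-style) variance-component estimation, and likelihood-ratio scans of
# arbitrary degrees of freedom over single SNPs, haplotype incidence columns,
# or parsimony-tree edge columns.
#
# Model: y = X b + h + e with h ~ N(0, sg2 K), e ~ N(0, se2 I), one record
# per line. Writing delta = se2 / sg2, a single eigendecomposition reduces
# every likelihood evaluation to O(n), which is what makes whole-genome
# likelihood-ratio scans cheap: the variance ratio is estimated once per
# phenotype under the null and the per-locus tests are generalized least
# squares in the rotated coordinates.

#' Allele-sharing kinship matrix
#'
#' `K[i, j]` is the proportion of markers, among those observed in both
#' lines, at which lines `i` and `j` carry the same allele. The diagonal is
#' 1. The matrix is symmetrized and made positive semidefinite by clipping
#' negative eigenvalues at zero (a documented adjustment; allele-sharing
#' matrices with missing data need not be PSD).
#'
#' @param G line x marker 0/1 matrix (NA = missing).
#' @return an n x n PSD kinship matrix with unit diagonal before clipping.
#' @export
kinship_allele_sharing <- function(G) {
  stopifnot(is.matrix(G), nrow(G) >= 2L)
  M <- !is.na(G)
  Gz <- G; Gz[!M] <- 0
  storage.mode(Gz) <- "double"; storage.mode(M) <- "double"
  both <- M %*% t(M)                       # jointly observed marker counts
  if (any(both == 0)) stop("line pair(s) share no observed marker")
  same1 <- Gz %*% t(Gz)                    # both allele 1
  same0 <- (M - Gz) %*% t(M - Gz)          # both allele 0
  K <- (same1 + same0) / both
  K <- (K + t(K)) / 2
  diag(K) <- 1
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < 0) {
    K <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    K <- (K + t(K)) / 2
  }
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

#' Spectral precomputation for the mixed-model scan
#'
#' Eigendecompositions shared by all likelihood evaluations for one
#' `(K, X_base)` pair: the full eigensystem of `K` for ML/GLS and the
#' eigensystem of the projected `K` (restricted space) for REML. Compute
#' once and pass to [lrt_scan()] when scanning many phenotypes against the
#' same kinship and base design.
#'
#' @param K kinship matrix.
#' @param X base fixed-effect design (full column rank).
#' @return an opaque list consumed by [lrt_scan()] and
#'   [fit_variance_components()] internals.
#' @export
emma_spectral <- function(K, X) {
  n <- nrow(K)
  q <- qr(X)$rank
  stopifnot(q == ncol(X))
  evK <- eigen(K, symmetric = TRUE)
  # restricted: eigen of S K S with S the projector orthogonal to X;
  # keep the n - q informative eigenpairs
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  evS <- eigen(S %*% K %*% S, symmetric = TRUE)
  list(n = n, q = q,
       xi = pmax(evK$values, 0), U = evK$vectors,
       lambda = pmax(evS$values[seq_len(n - q)], 0),
       W = evS$vectors[, seq_len(n - q), drop = FALSE])
}

ml_loglik <- function(delta, sp, ystar, Xstar) {
  w <- 1 / (sp$xi + delta)
  XtWX <- crossprod(Xstar, w * Xstar)
  b <- solve(XtWX, crossprod(Xstar, w * ystar))
  eta <- ystar - Xstar %*% b
  R <- sum(w * eta^2)
  0.5 * (sp$n * log(sp$n / (2 * pi)) - sp$n - sp$n * log(R) -
           sum(log(sp$xi + delta)))
}

reml_loglik <- function(delta, sp, eta_r) {
  nq <- sp$n - sp$q
  R <- sum(eta_r^2 / (sp$lambda + delta))
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(R) -
           sum(log(sp$lambda + delta)))
}

optimize_delta <- function(f, grid = exp(seq(log(1e-5), log(1e5),
                                             length.out = 100L))) {
  ll <- vapply(grid, f, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  if (opt$objective >= ll[i]) {
    list(delta = opt$maximum, loglik = opt$objective)
  } else {
    list(delta = grid[i], loglik = ll[i])
  }
}

#' REML/ML variance components by spectral one-dimensional optimization
#'
#' Estimates the variance ratio `delta = se2 / sg2` by maximizing the
#' restricted (REML) likelihood over a 100-point log-spaced grid on
#' `[1e-5, 1e5]` refined by bounded scalar search, then back-solves the
#' genetic and residual variances. The full-ML optimum is reported alongside
#' since likelihood-ratio tests of fixed effects use ML.
#'
#' @param y phenotype vector (one record per line).
#' @param X fixed-effect design (at least an intercept), full column rank.
#' @param K line x line kinship matrix (PSD).
#' @return list: `sigma2_g`, `sigma2_e`, `delta`, `h2`
#'   (`sigma2_g / (sigma2_g + sigma2_e)`, the model-scale ratio),
#'   `h2_realized` (the ratio after rescaling `sigma2_g` by the mean
#'   diagonal of the double-centered kinship, which is the genetic variance
#'   fraction on the phenotype scale when `K` is an uncalibrated
#'   allele-sharing matrix), `loglik_restricted`, `loglik_full_ml`,
#'   `delta_ml`.
#' @export
fit_variance_components <- function(y, X = matrix(1, length(y), 1L), K) {
  stopifnot(all(is.finite(y)), nrow(K) == length(y), nrow(X) == length(y))
  sp <- emma_spectral(K, X)
  eta_r <- crossprod(sp$W, y)
  fr <- optimize_delta(function(d) reml_loglik(d, sp, eta_r))
  ystar <- crossprod(sp$U, y)
  Xstar <- crossprod(sp$U, X)
  fm <- optimize_delta(function(d) ml_loglik(d, sp, ystar, Xstar))
  sg2 <- sum(eta_r^2 / (sp$lambda + fr$delta)) / (sp$n - sp$q)
  se2 <- fr$delta * sg2
  # scale factor: only the double-centered part of K is identifiable next to
  # an intercept, and its mean diagonal converts sigma2_g to phenotype scale
  kappa <- mean(diag(K)) - 2 * mean(rowMeans(K)) + mean(K)
  list(sigma2_g = sg2, sigma2_e = se2, delta = fr$delta,
       h2 = 1 / (1 + fr$delta),
       h2_realized = sg2 * kappa / (sg2 * kappa + se2),
       loglik_restricted = fr$loglik, loglik_full_ml = fm$loglik,
       delta_ml = fm$delta)
}

# ML profile log-likelihood at fixed delta for design X (rotated inputs):
# profiled over b and sg2, equals const - (n/2) log(weighted RSS)
profile_ml_rss <- function(ystar_w, Xstar_w) {
  fit <- stats::lm.fit(Xstar_w, ystar_w)
  sum(fit$residuals^2)
}

#' Mixed-model likelihood-ratio association scan
#'
#' Tests each locus (a group of design columns) by a maximum-likelihood
#' likelihood-ratio test of adding the locus's columns to the base fixed
#' effects, with the polygenic covariance `sg2 K + se2 I` held at the
#' null-model estimate (the spectral shortcut: the kinship eigendecomposition
#' and the variance ratio are computed once per phenotype). The statistic is
#' referred to a chi-squared distribution with df equal to the number of
#' tested columns.
#'
#' Modes: `"single_snp"` tests every column of `design$X` on its own (1 df);
#' `"haplotype"` tests each locus's columns jointly (df = number of common
#' alleles at the locus minus 1, counting the rare column), after dropping
#' columns whose carrier mass (column mean) is below `rare_floor`;
#' `"treescan"` tests each tree edge with 1 df -- the clade-membership column
#' is added on top of a null that already contains the edge's
#' "neither-clade" column, so the contrast is between the two clades -- and
#' the minimum p over a block's edges is retained as the block's test.
#'
#' @param y phenotype vector.
#' @param design `list(X, columns)` from [incidence_matrix()],
#'   [clade_membership_matrix()] or [snp_design()].
#' @param K kinship matrix.
#' @param X_base base fixed-effect columns (default intercept only).
#' @param mode test mode, see above.
#' @param rare_floor carrier-mass floor below which haplotype columns are
#'   dropped from the test (haplotype mode only).
#' @param refit if `TRUE`, re-estimate the variance ratio by ML under every
#'   null and alternative model (exact but slow; for validation).
#' @param spectral optional precomputed [emma_spectral()] for `(K, X_base)`;
#'   pass it when scanning many phenotypes to avoid repeating the
#'   eigendecompositions.
#' @return data.frame, one row per locus: `locus`, `chrom`, `start_cM`,
#'   `end_cM`, `df`, `stat`, `p`, `tested` (`FALSE` when the augmented design
#'   is rank-deficient or no column survives the floor; such loci are
#'   reported, not dropped).
#' @export
lrt_scan <- function(y, design, K, X_base = matrix(1, length(y), 1L),
                     mode = c("single_snp", "haplotype", "treescan"),
                     rare_floor = 0.028, refit = FALSE, spectral = NULL) {
  mode <- match.arg(mode)
  X <- design$X
  columns <- design$columns
  stopifnot(nrow(X) == length(y), nrow(columns) == ncol(X))
  sp <- if (is.null(spectral)) emma_spectral(K, X_base) else spectral
  ystar <- crossprod(sp$U, y)
  Xstar_base <- crossprod(sp$U, X_base)
  Xstar_all <- crossprod(sp$U, X)
  fm <- optimize_delta(function(d) ml_loglik(d, sp, ystar, Xstar_base))
  delta <- fm$delta
  w <- 1 / sqrt(sp$xi + delta)
  yw <- as.vector(w * ystar)
  Bw <- w * Xstar_base
  Aw <- w * Xstar_all
  n <- sp$n
  rss0 <- profile_ml_rss(yw, Bw)
  rank0 <- qr(Bw)$rank

  test_group <- function(add_idx, covar_idx = integer(0)) {
    # returns c(stat, df, tested)
    Xn <- if (length(covar_idx)) cbind(Bw, Aw[, covar_idx, drop = FALSE]) else Bw
    Xa <- cbind(Xn, Aw[, add_idx, drop = FALSE])
    if (refit) {
      Xs_n <- if (length(covar_idx))
        cbind(Xstar_base, Xstar_all[, covar_idx, drop = FALSE]) else Xstar_base
      Xs_a <- cbind(Xs_n, Xstar_all[, add_idx, drop = FALSE])
      qn <- qr(Xs_n); qa <- qr(Xs_a)
      if (qa$rank < ncol(Xs_a)) return(c(NA_real_, length(add_idx), 0))
      ll0 <- optimize_delta(function(d) ml_loglik(d, sp, ystar, Xs_n))$loglik
      ll1 <- optimize_delta(function(d) ml_loglik(d, sp, ystar, Xs_a))$loglik
      stat <- max(0, 2 * (ll1 - ll0))
      return(c(stat, qa$rank - qn$rank, 1))
    }
    qa <- qr(Xa)
    if (qa$rank < ncol(Xa)) return(c(NA_real_, length(add_idx), 0))
    r0 <- if (length(covar_idx)) profile_ml_rss(yw, Xn) else rss0
    r1 <- sum(qr.resid(qa, yw)^2)
    stat <- max(0, n * (log(r0) - log(r1)))
    c(stat, length(add_idx), 1)
  }

  groups <- split(seq_len(nrow(columns)), columns$df_group)
  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    cidx <- groups[[gi]]
    info <- columns[cidx[1L], ]
    if (mode == "treescan" && !is.na(info$edge)) {
      add <- cidx[columns$role[cidx] == "clade"]
      covar <- cidx[columns$role[cidx] == "neither"]
      res <- test_group(add, covar)
    } else if (mode == "haplotype" && identical(info$type, "block")) {
      keep <- cidx[colMeans(X[, cidx, drop = FALSE]) >= rare_floor]
      res <- if (length(keep) == 0L) c(NA_real_, 0L, 0) else test_group(keep)
    } else {
      res <- test_group(cidx)
    }
    rows[[gi]] <- data.frame(
      locus = info$locus, chrom = info$chrom,
      start_cM = info$start_cM, end_cM = info$end_cM,
      df = as.integer(res[2L]), stat = res[1L],
      p = if (res[3L] == 1 && res[2L] >= 1L) {
        stats::pchisq(res[1L], df = res[2L], lower.tail = FALSE)
      } else NA_real_,
      tested = res[3L] == 1,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (mode == "treescan") {
    # retain the minimum-p edge as the representative test per block locus
    out <- do.call(rbind, lapply(split(out, out$locus), function(d) {
      if (all(is.na(d$p))) return(d[1L, ])
      best <- which.min(d$p)
      d[best, ]
    }))
    out <- out[order(out$chrom, out$start_cM, out$locus), ]
    rownames(out) <- NULL
  }
  attr(out, "delta") <- delta
  attr(out, "null_loglik") <- fm$loglik
  out
}

#' Single-SNP design for the association scan
#'
#' Wraps a genotype (or allele-probability) matrix as a scan design: one
#' column and one locus per marker.
#'
#' @param G line x marker matrix (0/1 or probabilities).
#' @param map marker map in column order.
#' @param exclude marker IDs to leave out of the design (e.g. a causal SNP
#'   simulated as removed from the panel).
#' @return `list(X, columns)` as accepted by [lrt_scan()].
#' @export
snp_design <- function(G, map, exclude = character(0)) {
  stopifnot(ncol(G) == nrow(map))
  keep <- which(!(colnames(G) %in% exclude))
  X <- G[, keep, drop = FALSE]
  storage.mode(X) <- "double"
  columns <- data.frame(
    locus = paste0("snp_", colnames(G)[keep]), type = "snp",
    allele = "1", chrom = map$chrom[keep],
    start_cM = map$cM[keep], end_cM = map$cM[keep],
    df_group = seq_along(keep), stringsAsFactors = FALSE)
  list(X = X, columns = columns)
}

# connected components of the line-trial design graph (union-find)
trial_components <- function(trials) {
  ids <- unique(trials$trial)
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ln in unique(trials$line)) {
    tr <- unique(trials$trial[trials$line == ln])
    if (length(tr) > 1L) {
      r <- find(match(tr[1L], ids))
      for (t2 in tr[-1L]) {
        r2 <- find(match(t2, ids))
        if (r2 != r) parent[r2] <- r
      }
    }
  }
  comp <- vapply(seq_along(ids), find, numeric(1))
  split(ids, comp)
}

#' Line BLUPs from unbalanced multi-trial records
#'
#' Quality-gates each program dataset, removes outliers, checks design
#' connectivity, and fits the mixed model with trial as a fixed effect and
#' line as a random effect; the line random effects (BLUPs) are returned.
#'
#' Gates: programs with more than one trial must reach entry-mean
#' repeatability `s2_line / (s2_line + s2_e / l) >= min_repeatability`
#' (`l` = number of trials); single-trial programs must have a coefficient of
#' variation below `max_cv`. Records whose within-trial standardized value
#' exceeds `outlier_sd` are removed before the final fit.
#'
#' @param trials data.frame (`line`, `program`, `trial`, `value`), e.g. from
#'   [generate_trial_phenotypes()].
#' @param min_repeatability repeatability gate for multi-trial programs.
#' @param max_cv coefficient-of-variation gate for single-trial programs.
#' @param outlier_sd standardized-value cutoff for outlier removal.
#' @return named numeric vector of line BLUPs with attributes
#'   `kept_programs`, `n_outliers_removed`, `varcomp` (line and residual
#'   variances from the final fit).
#' @export
blup_lines <- function(trials, min_repeatability = 0.5, max_cv = 0.10,
                       outlier_sd = 3) {
  stopifnot(all(c("line", "program", "trial", "value") %in% names(trials)))
  kept <- character(0)
  for (p in unique(trials$program)) {
    d <- trials[trials$program == p, ]
    l <- length(unique(d$trial))
    if (l > 1L) {
      fit <- suppressMessages(lme4::lmer(value ~ trial + (1 | line), data = d))
      vc <- as.data.frame(lme4::VarCorr(fit))
      s2l <- vc$vcov[vc$grp == "line"]
      s2e <- vc$vcov[vc$grp == "Residual"]
      rep_ <- s2l / (s2l + s2e / l)
      if (isTRUE(rep_ >= min_repeatability)) kept <- c(kept, p)
    } else {
      cv <- stats::sd(d$value) / abs(mean(d$value))
      if (is.finite(cv) && cv < max_cv) kept <- c(kept, p)
    }
  }
  if (length(kept) == 0L) stop("no program dataset passes the quality gates")
  d <- trials[trials$program %in% kept, ]
  # within-trial standardized values; > outlier_sd removed
  z <- stats::ave(d$value, d$trial, FUN = function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  })
  n_out <- sum(abs(z) > outlier_sd)
  d <- d[abs(z) <= outlier_sd, ]
  comp <- trial_components(d)
  if (length(comp) > 1L) {
    stop("trial design is disconnected; groups: ",
         paste(vapply(comp, paste, character(1), collapse = "+"),
               collapse = " | "))
  }
  fit <- suppressMessages(lme4::lmer(value ~ trial + (1 | line), data = d))
  re <- lme4::ranef(fit)$line
  blup <- stats::setNames(re[[1L]], rownames(re))
  vc <- as.data.frame(lme4::VarCorr(fit))
  attr(blup, "kept_programs") <- kept
  attr(blup, "n_outliers_removed") <- n_out
  attr(blup, "varcomp") <- c(line = vc$vcov[vc$grp == "line"],
                             residual = vc$vcov[vc$grp == "Residual"])
  blup
}
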