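# Shared fixtures, all generated in code. Sizes are kept small so the whole
# suite runs quickly; the acceptance tests use their own, larger runs.

# a small LD-structured panel reused across module tests
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_lines = 200L, n_markers = 300L, n_chromosomes = 3L,
                        chrom_length_cM = 120, seed = 101L)
      cache <<- c(generate_genotypes(cfg), list(config = cfg))
    }
    cache
  }
})

# direct dense log-likelihoods for the mixed model y = Xb + h + e,
# h ~ N(0, sg2 K), e ~ N(0, se2 I): the brute-force oracle the spectral
# implementation is checked against
dense_ml_loglik <- function(y, X, K, sg2, se2) {
  n <- length(y)
  V <- sg2 * K + se2 * diag(n)
  cV <- chol(V)
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  b <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
  r <- y - X %*% b
  Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(cV))) + sum(r * Vi_r))
}

dense_reml_loglik <- function(y, X, K, sg2, se2) {
  n <- length(y); q <- ncol(X)
  V <- sg2 * K + se2 * diag(n)
  cV <- chol(V)
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  b <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% b
  Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
  as.numeric(-0.5 * ((n - q) * log(2 * pi) + 2 * sum(log(diag(cV))) +
                       determinant(XtViX, logarithm = TRUE)$modulus -
                       determinant(crossprod(X), logarithm = TRUE)$modulus +
                       sum(r * Vi_r)))
}

# brute-force r2 via the two-locus gamete table: D^2 / (pA pa pB pb)
contingency_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  pA <- mean(x); pB <- mean(y)
  D <- mean(x == 1 & y == 1) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# bare block record (same shape the blockers emit) for unit tests
new_block_for_test <- function(chrom, idx, map, method) {
  list(chrom = chrom,
       marker_index_range = c(min(idx), max(idx)),
       markers = map$marker[idx],
       start_cM = map$cM[min(idx)], end_cM = map$cM[max(idx)],
       alleles = NULL, method = method)
}
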