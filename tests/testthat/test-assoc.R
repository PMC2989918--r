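# Kinship, spectral variance components, the likelihood-ratio scan, and
# trial BLUPs.

test_that("allele-sharing kinship matches a hand count", {
  G <- rbind(a = c(0L, 1L, 1L, 0L),
             b = c(0L, 1L, 0L, 1L),   # shares 2/4 with a
             c = c(1L, 0L, 0L, 1L))   # shares 0/4 with a, 2/4 with b
  K <- kinship_allele_sharing(G)
  expect_equal(unname(K["a", "b"]), 0.5)
  expect_equal(unname(K["a", "c"]), 0)
  expect_equal(unname(K["b", "c"]), 0.5)
  expect_equal(unname(diag(K)), rep(1, 3L))
  expect_equal(K, t(K))
  # missing entries: sharing over jointly observed markers only
  G2 <- rbind(a = c(0L, 1L, NA, 0L), b = c(0L, 1L, 1L, 1L))
  K2 <- kinship_allele_sharing(G2)
  expect_equal(unname(K2["a", "b"]), 2 / 3)
  expect_true(min(eigen(K2, symmetric = TRUE)$values) >= -1e-10)
  expect_error(kinship_allele_sharing(rbind(c(NA, 1L), c(0L, NA))),
               "no observed marker")
})

test_that("spectral likelihoods equal the dense-matrix oracle", {
  set.seed(41)
  n <- 18L
  G <- matrix(rbinom(n * 40L, 1L, 0.4), n)
  rownames(G) <- sprintf("L%02d", seq_len(n))
  K <- kinship_allele_sharing(G)
  y <- as.vector(chol(0.6 * K + 0.4 * diag(n)) %*% rnorm(n))
  X <- matrix(1, n, 1L)
  vc <- fit_variance_components(y, X, K)
  expect_equal(vc$loglik_restricted,
               dense_reml_loglik(y, X, K, vc$sigma2_g, vc$sigma2_e),
               tolerance = 1e-6)
  # optimum beats 50 random variance pairs under the dense oracle
  for (i in 1:50) {
    sg <- runif(1, 0.01, 3); se <- runif(1, 0.01, 3)
    expect_gte(vc$loglik_restricted + 1e-8,
               dense_reml_loglik(y, X, K, sg, se))
  }
})

test_that("REML/ML optima match a dense brute-force grid in h2", {
  # brute force: profile the total variance analytically and sweep h2
  dense_best_h2 <- function(y, X, K, restricted = TRUE) {
    n <- length(y); q <- ncol(X)
    grid <- seq(0.0005, 0.9995, by = 0.0005)
    ll <- vapply(grid, function(h) {
      H <- h * K + (1 - h) * diag(n)
      cH <- chol(H)
      Hi_y <- backsolve(cH, forwardsolve(t(cH), y))
      Hi_X <- backsolve(cH, forwardsolve(t(cH), X))
      XtHiX <- crossprod(X, Hi_X)
      b <- solve(XtHiX, crossprod(X, Hi_y))
      r <- y - X %*% b
      Hi_r <- backsolve(cH, forwardsolve(t(cH), r))
      rss <- sum(r * Hi_r)
      if (restricted) {
        st2 <- rss / (n - q)
        -0.5 * ((n - q) * log(st2) + 2 * sum(log(diag(cH))) +
                  determinant(XtHiX, logarithm = TRUE)$modulus + (n - q))
      } else {
        st2 <- rss / n
        -0.5 * (n * log(st2) + 2 * sum(log(diag(cH))) + n)
      }
    }, numeric(1))
    grid[which.max(ll)]
  }
  set.seed(43)
  for (rep in 1:3) {
    n <- 20L
    G <- matrix(rbinom(n * 60L, 1L, 0.5), n)
    rownames(G) <- sprintf("L%02d", seq_len(n))
    K <- kinship_allele_sharing(G)
    y <- as.vector(chol(0.5 * K + 0.5 * diag(n)) %*% rnorm(n))
    X <- matrix(1, n, 1L)
    vc <- fit_variance_components(y, X, K)
    expect_equal(vc$h2, dense_best_h2(y, X, K, TRUE), tolerance = 1e-3)
    expect_equal(1 / (1 + vc$delta_ml), dense_best_h2(y, X, K, FALSE),
                 tolerance = 1e-3)
  }
})

test_that("pure-noise phenotypes give a near-zero genetic fraction", {
  cfg <- sim_config(n_lines = 400L, n_markers = 200L, n_chromosomes = 2L,
                    seed = 47L)
  G <- generate_genotypes(cfg)$genotypes
  K <- kinship_allele_sharing(G)
  set.seed(1)
  vc <- fit_variance_components(rnorm(400L), K = K)
  expect_lt(vc$h2, 0.05)
})

test_that("simulated heritability is recovered on the realized scale", {
  cfg <- sim_config(n_lines = 300L, n_markers = 400L, n_chromosomes = 7L,
                    seed = 31L)
  sim <- generate_genotypes(cfg)
  G <- sim$genotypes; map <- sim$map
  K <- kinship_allele_sharing(G)
  qtl_ids <- choose_qtl_snps(G, map, n = 20L, maf_min = 0.10)
  poly <- kmeans_select(G, k = 150L, target = "markers", seed = 5L)
  h2s <- vapply(1:40, function(r) {
    q <- qtl_ids[((r - 1L) %% 20L) + 1L]
    spec <- qtl_spec("single_snp_retained", q, p = 0.12,
                     chrom = map$chrom[map$marker == q],
                     cM = map$cM[map$marker == q])
    y <- simulate_phenotype(G, spec, h2 = 0.75, poly, seed = 1000L + r)
    fit_variance_components(as.vector(y), K = K)$h2_realized
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.75), 0.05)
})

test_that("a noise-free SNP signal is found with overwhelming evidence", {
  sim <- small_panel()
  G <- sim$genotypes; map <- sim$map
  K <- kinship_allele_sharing(G)
  y <- as.numeric(scale(G[, 150L])) + 1e-6 * seq_len(nrow(G))
  sc <- lrt_scan(y, snp_design(G, map), K)
  # the causal SNP attains the scan minimum (perfect-LD copies may tie)
  p_causal <- sc$p[sc$locus == paste0("snp_", colnames(G)[150L])]
  expect_equal(p_causal, min(sc$p, na.rm = TRUE), tolerance = 1e-8)
  expect_lt(min(sc$p, na.rm = TRUE), 1e-10)
})

test_that("haplotype mode on 1-SNP loci equals single-SNP mode exactly", {
  sim <- small_panel()
  G <- sim$genotypes[, 1:40]; map <- sim$map[1:40, ]
  K <- kinship_allele_sharing(sim$genotypes)
  set.seed(3)
  y <- as.numeric(scale(G[, 7L])) * 0.5 + rnorm(nrow(G))
  P <- matrix(as.numeric(G), nrow(G), ncol(G), dimnames = dimnames(G))
  im <- incidence_matrix(list(), P, singletons = seq_len(ncol(G)), map = map)
  sc_hap <- lrt_scan(y, im, K, mode = "haplotype")
  sc_snp <- lrt_scan(y, snp_design(G, map), K, mode = "single_snp")
  expect_equal(sc_hap$stat, sc_snp$stat, tolerance = 1e-10)
  expect_equal(sc_hap$p, sc_snp$p, tolerance = 1e-10)
  expect_identical(sc_hap$df, sc_snp$df)
})

test_that("df equals tested column count and rare columns drop", {
  # one block, 4 common alleles, negligible rare mass -> df 3
  haps <- c(rep("000", 40L), rep("011", 30L), rep("110", 20L),
            rep("101", 10L))
  G <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  G <- G[rep(1:100, 2L), ]
  colnames(G) <- sprintf("M%d", 1:3)
  rownames(G) <- sprintf("L%03d", seq_len(200L))
  map <- data.frame(marker = colnames(G), chrom = 1L, cM = 1:3)
  b <- enumerate_alleles(new_block_for_test(1L, 1:3, map, "four_gamete"), G)
  P <- matrix(as.numeric(G), 200L, 3L, dimnames = dimnames(G))
  im <- incidence_matrix(list(b), P, map = map)
  K <- diag(200L); dimnames(K) <- list(rownames(G), rownames(G))
  set.seed(11)
  y <- rnorm(200L)
  sc <- lrt_scan(y, im, K, mode = "haplotype")
  expect_identical(sc$df, 3L)   # rare column (mass 0) dropped
  expect_true(sc$tested)
})

test_that("rank-deficient loci are reported untested, not dropped", {
  n <- 80L
  set.seed(13)
  G <- matrix(rbinom(n * 3L, 1L, 0.5), n)
  G <- cbind(G, const = 1L)   # collinear with the intercept
  colnames(G) <- sprintf("M%d", 1:4)
  rownames(G) <- sprintf("L%02d", seq_len(n))
  map <- data.frame(marker = colnames(G), chrom = 1L, cM = 1:4)
  K <- diag(n); dimnames(K) <- list(rownames(G), rownames(G))
  y <- rnorm(n)
  sc <- lrt_scan(y, snp_design(G, map), K)
  expect_identical(nrow(sc), 4L)
  expect_false(sc$tested[4L])
  expect_true(is.na(sc$p[4L]))
  expect_true(all(sc$tested[1:3]))
})

test_that("the LRT is invariant to affine rescaling of the phenotype", {
  sim <- small_panel()
  G <- sim$genotypes[, 1:30]; map <- sim$map[1:30, ]
  K <- kinship_allele_sharing(sim$genotypes)
  set.seed(19)
  y <- as.numeric(scale(G[, 5L])) * 0.4 + rnorm(nrow(G))
  sc1 <- lrt_scan(y, snp_design(G, map), K)
  sc2 <- lrt_scan(3.7 * y - 11, snp_design(G, map), K)
  expect_equal(sc1$stat, sc2$stat, tolerance = 1e-6)
})

test_that("fast scan and exact per-locus refit agree closely", {
  sim <- small_panel()
  G <- sim$genotypes[, 1:20]; map <- sim$map[1:20, ]
  K <- kinship_allele_sharing(sim$genotypes)
  set.seed(23)
  y <- as.numeric(scale(G[, 10L])) * 0.6 + rnorm(nrow(G))
  des <- snp_design(G, map)
  fast <- lrt_scan(y, des, K, refit = FALSE)
  exact <- lrt_scan(y, des, K, refit = TRUE)
  # the null-variance shortcut is an approximation: it tracks the exact
  # refit tightly for weak loci and is conservative (never larger) at
  # strong ones; rankings agree
  expect_identical(which.min(fast$p), which.min(exact$p))
  expect_gt(cor(fast$stat, exact$stat, method = "spearman"), 0.95)
  weak <- exact$stat < 3
  expect_lt(max(abs(fast$stat[weak] - exact$stat[weak])), 0.5)
  expect_true(all(fast$stat <= exact$stat + 1e-6))
})

test_that("treescan mode keeps the minimum-p edge per block", {
  haps <- c(rep("000", 80L), rep("011", 60L), rep("111", 40L),
            rep("100", 20L))
  G <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  colnames(G) <- sprintf("M%d", 1:3)
  rownames(G) <- sprintf("L%03d", seq_len(200L))
  map <- data.frame(marker = colnames(G), chrom = 1L, cM = 1:3)
  b <- enumerate_alleles(new_block_for_test(1L, 1:3, map, "four_gamete"), G)
  tr <- parsimony_tree(b$alleles$allele, b$alleles$freq)
  P <- matrix(as.numeric(G), 200L, 3L, dimnames = dimnames(G))
  cm <- clade_membership_matrix(list(b), list(tr), P, map = map)
  K <- diag(200L); dimnames(K) <- list(rownames(G), rownames(G))
  set.seed(29)
  # phenotype separates the 111 clade
  y <- as.numeric(haps == "111") + rnorm(200L, sd = 0.5)
  sc <- lrt_scan(y, cm, K, mode = "treescan")
  expect_identical(nrow(sc), 1L)      # one representative row per block
  expect_identical(sc$df, 1L)
  expect_lt(sc$p, 1e-6)
})

test_that("BLUPs recover simulated line values on connected designs", {
  lines <- sprintf("L%03d", 1:150)
  tp <- generate_trial_phenotypes(lines, n_programs = 3L,
                                  locations_per_program = 3L,
                                  variance_components = c(4, 1, 1),
                                  seed = 31L)
  truth <- attr(tp, "line_values")
  blup <- blup_lines(tp, min_repeatability = 0.5)
  common <- intersect(names(blup), names(truth))
  expect_gt(length(common), 100L)
  expect_gt(cor(blup[common], truth[common]), 0.9)
})

test_that("gross outliers are removed before the BLUP fit", {
  lines <- sprintf("L%03d", 1:80)
  tp <- generate_trial_phenotypes(lines, n_programs = 2L,
                                  locations_per_program = 2L,
                                  variance_components = c(1, 1, 1),
                                  seed = 37L)
  tp$value[5L] <- tp$value[5L] + 50  # +~35 SD within its trial
  blup <- blup_lines(tp, min_repeatability = 0)
  expect_gte(attr(blup, "n_outliers_removed"), 1L)
})

test_that("disconnected trial designs fail with named groups", {
  tp <- data.frame(
    line = c("a", "b", "a", "b", "x", "y", "x", "y"),
    program = rep(c("P1", "P2"), each = 4L),
    trial = rep(c("P1_T1", "P1_T2", "P2_T1", "P2_T2"), each = 2L),
    value = rnorm(8L))
  expect_error(blup_lines(tp, min_repeatability = 0, max_cv = Inf),
               "disconnected")
})
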