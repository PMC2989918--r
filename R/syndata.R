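# Synthetic genotype / map / phenotype generators for an inbred (haploid-coded)
# association panel with map-tied markers and block-like LD.

#' Simulation configuration for the founder-mosaic genotype generator
#'
#' Bundles and validates the parameters of [generate_genotypes()]. Defaults
#' emulate a Barley-CAP-like panel: haploid lines on 7 chromosomes, ~60% of
#' adjacent marker pairs sharing a map position, every marker with minor
#' allele frequency at least 0.028, and adjacent-pair r-squared averaging
#' roughly 0.45.
#'
#' @param n_lines number of inbred lines.
#' @param n_markers total number of biallelic markers across all chromosomes.
#' @param n_chromosomes number of chromosomes; markers are split as evenly as
#'   possible.
#' @param chrom_length_cM genetic length of each chromosome in centimorgans.
#' @param tie_fraction target fraction of adjacent marker pairs that share a
#'   map position (the map has limited resolution, so runs of markers are
#'   co-located).
#' @param ld_strength founder-haplotype retention at zero map distance, in
#'   (0, 1]. Controls how correlated co-located and nearby markers are.
#' @param ld_decay_cM e-folding map distance (cM) of the founder-haplotype
#'   correlation; LD between markers decays on this scale.
#' @param recomb_scale_cM map-distance scale (cM) of the line-level founder
#'   switching (mosaic recombination) process.
#' @param n_founders size of the founder haplotype pool each line is a mosaic
#'   of. Small pools give few common haplotypes per region.
#' @param maf_min hard lower bound on per-marker minor allele frequency,
#'   enforced exactly (markers are repaired, not dropped).
#' @param missing_rate proportion of calls set to missing by
#'   [inject_missing()]; stored here for convenience.
#' @param seed integer seed; identical configs give bit-identical output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 400L,
                       n_markers = 2098L,
                       n_chromosomes = 7L,
                       chrom_length_cM = 150,
                       tie_fraction = 0.6,
                       ld_strength = 0.60,
                       ld_decay_cM = 5,
                       recomb_scale_cM = 40,
                       n_founders = 8L,
                       maf_min = 0.028,
                       missing_rate = 0.007,
                       seed = 1L) {
  cfg <- list(
    n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_cM = as.numeric(chrom_length_cM),
    tie_fraction = as.numeric(tie_fraction),
    ld_strength = as.numeric(ld_strength),
    ld_decay_cM = as.numeric(ld_decay_cM),
    recomb_scale_cM = as.numeric(recomb_scale_cM),
    n_founders = as.integer(n_founders),
    maf_min = as.numeric(maf_min),
    missing_rate = as.numeric(missing_rate),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_lines >= 2L, cfg$n_chromosomes >= 1L,
    cfg$n_markers >= 3L * cfg$n_chromosomes,
    cfg$chrom_length_cM > 0,
    cfg$tie_fraction >= 0, cfg$tie_fraction < 1,
    cfg$ld_strength > 0, cfg$ld_strength <= 1,
    cfg$ld_decay_cM > 0, cfg$recomb_scale_cM > 0,
    cfg$n_founders >= 2L,
    cfg$maf_min >= 0, cfg$maf_min <= 0.5,
    cfg$missing_rate >= 0, cfg$missing_rate < 1
  )
  # a MAF floor must be attainable with at least one carrier flip
  if (cfg$maf_min > 0 && ceiling(cfg$maf_min * cfg$n_lines) > floor(cfg$n_lines / 2)) {
    stop("maf_min = ", cfg$maf_min, " is infeasible for n_lines = ", cfg$n_lines)
  }
  class(cfg) <- "sim_config"
  cfg
}

# run `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# cluster adjacent markers into runs sharing one cM position; cluster sizes
# are geometric with mean 1/(1 - tie_fraction) so the realized tie fraction
# is close to target
draw_tied_clusters <- function(n_markers, tie_fraction) {
  if (tie_fraction <= 0) return(rep(1L, n_markers))
  sizes <- integer(0)
  total <- 0L
  while (total < n_markers) {
    s <- 1L + stats::rgeom(1L, prob = 1 - tie_fraction)
    sizes <- c(sizes, s)
    total <- total + s
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (total - n_markers)
  sizes[sizes > 0L]
}

#' Generate a haploid genotype matrix and genetic map
#'
#' Lines are mosaics of a small founder-haplotype pool. Founder alleles follow
#' a Markov process along each chromosome whose retention decays with map
#' distance, and lines switch founders at a rate proportional to the cM gap,
#' so linkage disequilibrium decays with map distance and co-located markers
#' are strongly (but not perfectly) correlated. Markers whose minor allele
#' frequency falls below `maf_min` are repaired by flipping founder alleles
#' at that marker, so the marker count and the MAF floor are both honored
#' exactly.
#'
#' @param config a [sim_config()].
#' @return a list with elements `genotypes` (line x marker 0/1 matrix with
#'   dimnames) and `map` (data.frame: `marker`, `chrom`, `cM`, ordered by
#'   chromosome then position).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_lines
    K <- config$n_founders
    per_chrom <- diff(round(seq(0, config$n_markers,
                                length.out = config$n_chromosomes + 1L)))
    stopifnot(all(per_chrom >= 3L))
    G <- matrix(NA_integer_, n, config$n_markers)
    chrom <- integer(config$n_markers)
    cM <- numeric(config$n_markers)
    col0 <- 0L
    for (cc in seq_len(config$n_chromosomes)) {
      m_c <- per_chrom[cc]
      sizes <- draw_tied_clusters(m_c, config$tie_fraction)
      pos_clusters <- sort(stats::runif(length(sizes), 0, config$chrom_length_cM))
      pos <- rep(pos_clusters, sizes)
      d <- c(0, diff(pos))  # cM gap to previous marker (0 within tied runs)

      # founder haplotypes: Markov retention rho(d) = ld_strength * exp(-d/scale);
      # on non-retention the allele is redrawn at a per-marker target frequency,
      # which spreads the marginal MAF distribution below 0.5
      # target frequency is piecewise-constant along the chromosome (slowly
      # changing regional allele frequency), which keeps regional MAF away
      # from 0.5 for a realistic spread
      q <- numeric(m_c)
      q[1L] <- stats::runif(1L, 0.1, 0.9)
      for (m in seq_len(m_c)[-1L]) {
        q[m] <- if (stats::runif(1L) < 0.1) stats::runif(1L, 0.1, 0.9) else q[m - 1L]
      }
      fou <- matrix(NA_integer_, K, m_c)
      fou[, 1L] <- stats::rbinom(K, 1L, q[1L])
      for (m in seq_len(m_c)[-1L]) {
        rho <- config$ld_strength * exp(-d[m] / config$ld_decay_cM)
        redraw <- stats::runif(K) >= rho
        fou[, m] <- ifelse(redraw, stats::rbinom(K, 1L, q[m]), fou[, m - 1L])
      }
      # line mosaics: switch founder with prob 0.5*(1 - exp(-d/scale))
      z <- matrix(NA_integer_, n, m_c)
      z[, 1L] <- sample.int(K, n, replace = TRUE)
      for (m in seq_len(m_c)[-1L]) {
        s_p <- 0.5 * (1 - exp(-d[m] / config$recomb_scale_cM))
        sw <- stats::runif(n) < s_p
        z[, m] <- ifelse(sw, sample.int(K, n, replace = TRUE), z[, m - 1L])
      }
      g_c <- matrix(fou[cbind(as.vector(z), rep(seq_len(m_c), each = n))], n, m_c)

      # enforce the MAF floor by flipping founder alleles at offending markers
      min_minor <- ceiling(config$maf_min * n)
      for (m in seq_len(m_c)) {
        it <- 0L
        repeat {
          cnt1 <- sum(g_c[, m])
          minor <- min(cnt1, n - cnt1)
          if (minor >= min_minor) break
          it <- it + 1L
          if (it > 4L * K) stop("unable to satisfy maf_min at a marker")
          major_allele <- as.integer(cnt1 > n - cnt1)
          usage <- tabulate(z[, m], nbins = K)
          cand <- which(fou[, m] == major_allele & usage > 0L)
          if (length(cand) == 0L) cand <- which(usage > 0L)
          f <- cand[which.min(usage[cand])]
          fou[f, m] <- 1L - fou[f, m]
          g_c[z[, m] == f, m] <- fou[f, m]
        }
      }
      idx <- col0 + seq_len(m_c)
      G[, idx] <- g_c
      chrom[idx] <- cc
      cM[idx] <- pos
      col0 <- col0 + m_c
    }
    marker_ids <- sprintf("M%04d", seq_len(config$n_markers))
    dimnames(G) <- list(sprintf("L%04d", seq_len(n)), marker_ids)
    map <- data.frame(marker = marker_ids, chrom = chrom, cM = cM,
                      stringsAsFactors = FALSE)
    list(genotypes = G, map = map)
  })
}

#' Set genotype calls to missing completely at random
#'
#' @param G line x marker 0/1 matrix.
#' @param rate expected proportion of calls set to `NA`, in `[0, 1)`.
#' @param seed integer seed for the missing mask.
#' @return a copy of `G` with `NA` entries; `G` itself is unmodified.
#' @export
inject_missing <- function(G, rate, seed = 1L) {
  stopifnot(is.matrix(G), rate >= 0, rate < 1)
  if (rate == 0) return(G)
  with_seed(seed, {
    mask <- stats::runif(length(G)) < rate
    G[mask] <- NA_integer_
    G
  })
}

#' Generate unbalanced multi-trial phenotype records
#'
#' Emulates a cooperative phenotyping design: each breeding program grows its
#' own lines in its own trials (locations), and a small set of check lines is
#' shared across all trials so that trial effects are estimable. The record
#' value is additive: true line value + trial effect + residual noise.
#'
#' @param lines character vector of line identifiers.
#' @param n_programs number of breeding programs; non-check lines are split
#'   evenly among them.
#' @param locations_per_program number of trials (locations) per program.
#' @param variance_components numeric length-3 vector `(line, trial, residual)`
#'   of variance components, all `>= 0`.
#' @param n_checks number of shared check lines (taken from the head of
#'   `lines`) present in every trial.
#' @param seed integer seed.
#' @return a data.frame (`line`, `program`, `trial`, `value`) with the true
#'   line values in `attr(, "line_values")`.
#' @export
generate_trial_phenotypes <- function(lines, n_programs, locations_per_program,
                                      variance_components = c(1, 1, 1),
                                      n_checks = 5L, seed = 1L) {
  stopifnot(length(lines) > n_checks + n_programs,
            n_programs >= 1L, locations_per_program >= 1L,
            length(variance_components) == 3L,
            all(variance_components >= 0))
  v <- as.numeric(variance_components)
  with_seed(seed, {
    checks <- lines[seq_len(n_checks)]
    rest <- lines[-seq_len(n_checks)]
    program_of <- rep(seq_len(n_programs), length.out = length(rest))
    line_value <- stats::rnorm(length(lines), 0, sqrt(v[1L]))
    names(line_value) <- lines
    rec <- list()
    for (p in seq_len(n_programs)) {
      own <- rest[program_of == p]
      for (loc in seq_len(locations_per_program)) {
        trial_id <- sprintf("P%d_T%d", p, loc)
        t_eff <- stats::rnorm(1L, 0, sqrt(v[2L]))
        entries <- c(checks, own)
        rec[[length(rec) + 1L]] <- data.frame(
          line = entries,
          program = sprintf("P%d", p),
          trial = trial_id,
          value = line_value[entries] + t_eff +
            stats::rnorm(length(entries), 0, sqrt(v[3L])),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rec)
    rownames(out) <- NULL
    attr(out, "line_values") <- line_value
    out
  })
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  fields <- unclass(config)
  lines <- vapply(names(fields), function(nm) {
    sprintf("%s: %s", nm, format(fields[[nm]], scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  txt <- readLines(path)
  kv <- strsplit(txt, ": ", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(x) as.numeric(x[2L])),
    vapply(kv, `[[`, character(1), 1L)
  )
  do.call(sim_config, vals)
}
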