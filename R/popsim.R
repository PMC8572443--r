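#' Configuration for the forward-in-time population simulator
#'
#' The defaults describe the shipped demography: a Wright-Fisher monoecious
#' population of 92 breeding animals held for 45 discrete generations after
#' founding (building up linkage disequilibrium consistent with an effective
#' population size near 100), followed by a single expansion generation of
#' 5000 offspring drawn from those 92 parents. Five 100-Mb chromosomes carry
#' 4000 SNPs each at 1 cM/Mb; 5% of SNPs are flagged as the sparse "LD"
#' genotyping panel nested in the dense panel. These constants were tuned so
#' the LD-based effective-size estimator (see [ne_from_ld()]) returns
#' approximately 100 and mean r-squared near 0.15 Mb is about 0.2; they live
#' here in the config, not in the simulator code.
#'
#' @param n_founders number of founder animals.
#' @param n_generations total number of discrete generations to simulate
#'   (the last one is the expansion generation when `final_expansion` is set).
#' @param pop_size_per_gen breeding population size per generation; the main
#'   control on the realised effective population size.
#' @param final_expansion size of the last generation, or `NULL` to keep
#'   `pop_size_per_gen` throughout.
#' @param n_chromosomes,chrom_length_bp,snps_per_chromosome genome layout.
#' @param founder_maf_range range (low, high) of the uniform distribution the
#'   founder A2 allele frequencies are drawn from; must satisfy
#'   0 < low < high <= 0.5.
#' @param recombination_rate morgans per bp (default 1e-8, i.e. 1 cM/Mb).
#' @param ld_panel_fraction fraction of SNPs flagged as the sparse LD panel.
#' @param missing_rate optional rate of randomly masked genotypes in the
#'   final panel (0 by default; only used to exercise call-rate QC).
#' @param seed integer seed used by [simulate_population()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 92L,
                       n_generations = 46L,
                       pop_size_per_gen = 92L,
                       final_expansion = 5000L,
                       n_chromosomes = 5L,
                       chrom_length_bp = 1e8,
                       snps_per_chromosome = 4000L,
                       founder_maf_range = c(0.05, 0.5),
                       recombination_rate = 1e-8,
                       ld_panel_fraction = 0.05,
                       missing_rate = 0,
                       seed = NULL) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              pop_size_per_gen = as.integer(pop_size_per_gen),
              final_expansion = if (is.null(final_expansion)) NULL else
                as.integer(final_expansion),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              founder_maf_range = as.numeric(founder_maf_range),
              recombination_rate = as.numeric(recombination_rate),
              ld_panel_fraction = as.numeric(ld_panel_fraction),
              missing_rate = as.numeric(missing_rate),
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_founders", "pop_size_per_gen", "n_chromosomes",
              "snps_per_chromosome")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L) {
      stop_config("sim_config: %s must be a positive count", f)
    }
  }
  if (cfg$n_generations < 0L) stop_config("sim_config: n_generations must be >= 0")
  if (cfg$chrom_length_bp <= 0) stop_config("sim_config: chrom_length_bp must be > 0")
  r <- cfg$founder_maf_range
  if (length(r) != 2L || r[1] <= 0 || r[1] >= r[2] || r[2] > 0.5) {
    stop_config("sim_config: founder_maf_range must satisfy 0 < low < high <= 0.5")
  }
  if (cfg$recombination_rate < 0) stop_config("sim_config: recombination_rate must be >= 0")
  if (cfg$ld_panel_fraction <= 0 || cfg$ld_panel_fraction >= 1) {
    stop_config("sim_config: ld_panel_fraction must be in (0, 1)")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_config("sim_config: missing_rate must be in [0, 1)")
  }
  if (!is.null(cfg$final_expansion) && cfg$final_expansion <= 0L) {
    stop_config("sim_config: final_expansion must be a positive count")
  }
  if (cfg$snps_per_chromosome > cfg$chrom_length_bp) {
    stop_config("sim_config: more SNPs than bp on a chromosome")
  }
  invisible(cfg)
}

## Build dosage matrix + panel from a per-chromosome haplotype list.
## Haplotype matrices have 2 rows per animal (rows 2i-1, 2i).
.panel_from_haplotypes <- function(hap, map, ld_mask = NULL, ids = NULL) {
  dos <- do.call(cbind, lapply(hap, function(H) {
    H[seq(1L, nrow(H), by = 2L), , drop = FALSE] +
      H[seq(2L, nrow(H), by = 2L), , drop = FALSE]
  }))
  new_genotype_panel(dos, map, ld_mask = ld_mask, animal_ids = ids,
                     haplotypes = hap)
}

#' Simulate founder genotypes in linkage equilibrium
#'
#' Founder haplotypes are drawn independently per SNP with the A2 frequency
#' sampled uniformly from `founder_maf_range`, so founders carry no LD beyond
#' finite-sample noise. Genotypes are the sum of the two haplotypes; there
#' are no missing values.
#'
#' @param config a [sim_config()].
#' @param seed optional seed (defaults to the current RNG stream).
#' @return a `genotype_panel` with phased haplotypes attached.
#' @export
simulate_founders <- function(config, seed = NULL) {
  validate_sim_config(config)
  with_seed(seed, {
    nc <- config$n_chromosomes
    m <- config$snps_per_chromosome
    n <- config$n_founders
    maps <- vector("list", nc)
    hap <- vector("list", nc)
    for (cc in seq_len(nc)) {
      pos <- sort(sample.int(config$chrom_length_bp, m))
      p <- stats::runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
      ## column j filled with 2n Bernoulli(p[j]) draws
      hap[[cc]] <- matrix(stats::rbinom(2L * n * m, 1L, rep(p, each = 2L * n)),
                          nrow = 2L * n)
      maps[[cc]] <- data.frame(
        snp_id = sprintf("c%d_s%04d", cc, seq_len(m)),
        chr = cc, pos = pos, a1 = "A", a2 = "B",
        stringsAsFactors = FALSE
      )
    }
    .panel_from_haplotypes(hap, do.call(rbind, maps))
  })
}

## One round of meioses on a single chromosome.
## H: haplotypes (2 rows per parent); parents: parent index per gamete;
## pos: bp positions; len_m: map length in morgans. Crossover counts are
## Poisson(len_m), positions uniform on the chromosome (Haldane, no
## interference).
.meiosis_gametes <- function(H, parents, pos, len_m) {
  ng <- length(parents)
  out <- matrix(0L, ng, ncol(H))
  k <- stats::rpois(ng, len_m)
  start <- sample(c(0L, 1L), ng, replace = TRUE)
  mx <- pos[length(pos)]
  for (g in seq_len(ng)) {
    h1 <- H[2L * parents[g] - 1L, ]
    h2 <- H[2L * parents[g], ]
    if (k[g] == 0L) {
      out[g, ] <- if (start[g] == 0L) h1 else h2
    } else {
      br <- sort(stats::runif(k[g], 0, mx))
      seg <- (findInterval(pos, br) + start[g]) %% 2L
      out[g, ] <- ifelse(seg == 0L, h1, h2)
    }
  }
  out
}

#' Evolve a population by random mating with recombination
#'
#' Discrete, non-overlapping generations of Wright-Fisher random mating
#' (monoecious, selfing allowed): each gamete of each offspring comes from an
#' independently drawn parent, so heterozygosity decays by exactly
#' (1 - 1/(2N)) per generation in expectation. Crossover counts per
#' chromosome are Poisson with mean equal to the map length in morgans and
#' crossover positions are uniform (no interference, no mutation).
#'
#' @param panel a `genotype_panel` with haplotypes (as produced by
#'   [simulate_founders()]); if haplotypes are absent the genotypes are
#'   phased at random, which is exact for a panel in linkage equilibrium.
#' @param config a [sim_config()]; `n_generations` generations are run at
#'   `pop_size_per_gen`, with the final generation expanded to
#'   `final_expansion` when that is set.
#' @param seed optional seed.
#' @param keep_haplotypes keep phased haplotypes on the returned panel
#'   (turn off for large final generations to halve memory).
#' @return the evolved `genotype_panel`.
#' @export
evolve_population <- function(panel, config, seed = NULL, keep_haplotypes = TRUE) {
  validate_sim_config(config)
  if (n_animals(panel) < 2L) stop_config("evolve_population: need >= 2 animals")
  if (config$n_generations == 0L) return(panel)
  with_seed(seed, {
    chrs <- unique(panel$map$chr)
    hap <- panel$haplotypes %||% .random_phase(panel)
    len_m <- vapply(chrs, function(cc) {
      p <- panel$map$pos[panel$map$chr == cc]
      (p[length(p)] - p[1]) * config$recombination_rate
    }, numeric(1))
    sizes <- rep(config$pop_size_per_gen, config$n_generations)
    if (!is.null(config$final_expansion)) {
      sizes[config$n_generations] <- config$final_expansion
    }
    n_par <- n_animals(panel)
    for (g in seq_along(sizes)) {
      n_off <- sizes[g]
      for (ci in seq_along(chrs)) {
        pos <- panel$map$pos[panel$map$chr == chrs[ci]]
        g1 <- .meiosis_gametes(hap[[ci]], sample.int(n_par, n_off, replace = TRUE),
                               pos, len_m[ci])
        g2 <- .meiosis_gametes(hap[[ci]], sample.int(n_par, n_off, replace = TRUE),
                               pos, len_m[ci])
        H <- matrix(0L, 2L * n_off, ncol(g1))
        H[seq(1L, 2L * n_off, by = 2L), ] <- g1
        H[seq(2L, 2L * n_off, by = 2L), ] <- g2
        hap[[ci]] <- H
      }
      n_par <- n_off
    }
    ids <- sprintf("an%05d", seq_len(n_par))
    out <- .panel_from_haplotypes(hap, panel$map, ld_mask = panel$ld_mask,
                                  ids = ids)
    if (!keep_haplotypes) out$haplotypes <- NULL
    if (config$missing_rate > 0) {
      nmiss <- round(config$missing_rate * length(out$dosages))
      idx <- sample.int(length(out$dosages), nmiss)
      out$dosages[idx] <- NA_integer_
      out$allele_freqs <- unname(colMeans(out$dosages, na.rm = TRUE) / 2)
    }
    p <- allele_freqs(out)
    if (all(p %in% c(0, 1), na.rm = TRUE)) {
      stop_config("evolve_population: degenerate population (genome fixed)")
    }
    out
  })
}

## Random phasing for an unphased panel (exact under linkage equilibrium).
.random_phase <- function(panel) {
  chrs <- unique(panel$map$chr)
  n <- n_animals(panel)
  lapply(chrs, function(cc) {
    W <- panel$dosages[, panel$map$chr == cc, drop = FALSE]
    if (anyNA(W)) stop_config("cannot phase a panel with missing genotypes")
    m <- ncol(W)
    h1 <- matrix(0L, n, m)
    het <- W == 1L
    h1[het] <- stats::rbinom(sum(het), 1L, 0.5)
    h1[W == 2L] <- 1L
    h2 <- W - h1
    H <- matrix(0L, 2L * n, m)
    H[seq(1L, 2L * n, by = 2L), ] <- h1
    H[seq(2L, 2L * n, by = 2L), ] <- h2
    H
  })
}

#' Flag a nested sparse "LD" SNP panel
#'
#' Marks a uniform random subset of SNPs, stratified by chromosome (the
#' per-chromosome count is `round(fraction * m_chr)`), as the sparse panel
#' used for GRM construction, emulating a low-density genotyping array
#' nested in a dense one.
#'
#' @param panel a `genotype_panel`.
#' @param fraction fraction of SNPs to flag, in (0, 1].
#' @param seed optional seed.
#' @return the panel with `ld_mask` set.
#' @export
designate_ld_panel <- function(panel, fraction, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop_config("designate_ld_panel: fraction must be in (0, 1]")
  }
  with_seed(seed, {
    mask <- logical(n_snps(panel))
    for (cc in unique(panel$map$chr)) {
      idx <- which(panel$map$chr == cc)
      k <- if (fraction == 1) length(idx) else round(fraction * length(idx))
      mask[sample(idx, k)] <- TRUE
    }
    panel$ld_mask <- mask
    panel
  })
}

#' Simulate a complete genotype panel under the default demography
#'
#' Convenience wrapper: founders, `n_generations` of drift with
#' recombination, and LD-panel designation, all under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `genotype_panel` (haplotypes dropped to save memory).
#' @export
simulate_population <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    panel <- simulate_founders(config)
    panel <- evolve_population(panel, config, keep_haplotypes = FALSE)
    designate_ld_panel(panel, config$ld_panel_fraction)
  })
}
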