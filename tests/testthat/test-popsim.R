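test_that("founder panels respect dosage coding, determinism and the MAF distribution", {
  cfg <- sim_config(n_founders = 2L, n_generations = 0L, final_expansion = NULL,
                    n_chromosomes = 1L, chrom_length_bp = 1e6,
                    snps_per_chromosome = 10L)
  p <- simulate_founders(cfg, seed = 5L)
  expect_equal(dim(p$dosages), c(2L, 10L))
  expect_true(all(p$dosages %in% 0:2))
  expect_identical(simulate_founders(cfg, seed = 5L)$dosages, p$dosages)

  ## empirical mean MAF vs the U(0.05, 0.5) mean, 3 Monte-Carlo SEs
  cfg2 <- sim_config(n_founders = 500L, n_generations = 0L,
                     final_expansion = NULL, n_chromosomes = 1L,
                     chrom_length_bp = 1e7, snps_per_chromosome = 1000L)
  p2 <- simulate_founders(cfg2, seed = 9L)
  maf <- panel_maf(p2)
  se <- sd(maf) / sqrt(length(maf))
  expect_lt(abs(mean(maf) - mean(c(0.05, 0.5))), 3 * se)

  ## stored allele frequencies always recomputable from dosages
  expect_equal(p2$allele_freqs, allele_freqs(p2))
})

test_that("zero generations of evolution is the identity", {
  cfg <- sim_config(n_founders = 10L, n_generations = 0L, final_expansion = NULL,
                    n_chromosomes = 1L, chrom_length_bp = 1e6,
                    snps_per_chromosome = 20L)
  p <- simulate_founders(cfg, seed = 2L)
  expect_identical(evolve_population(p, cfg, seed = 3L)$dosages, p$dosages)
})

test_that("a fixed genome raises a degenerate-population error", {
  dos <- matrix(2L, 4, 6)
  p <- manual_panel(dos)
  cfg <- sim_config(n_founders = 4L, n_generations = 2L, pop_size_per_gen = 4L,
                    final_expansion = NULL, n_chromosomes = 1L,
                    chrom_length_bp = 1e6, snps_per_chromosome = 6L)
  expect_error(evolve_population(p, cfg, seed = 1L), "degenerate")
})

test_that("heterozygosity decays at the Wright-Fisher rate 1 - 1/(2N)", {
  N <- 25L; G <- 12L
  cfg <- sim_config(n_founders = N, n_generations = G, pop_size_per_gen = N,
                    final_expansion = NULL, n_chromosomes = 1L,
                    chrom_length_bp = 1e7, snps_per_chromosome = 250L,
                    founder_maf_range = c(0.2, 0.5))
  ratios <- vapply(1:20, function(rep) {
    founders <- simulate_founders(cfg, seed = 1000L + rep)
    h0 <- mean(2 * allele_freqs(founders) * (1 - allele_freqs(founders)))
    evolved <- evolve_population(founders, cfg, seed = 2000L + rep)
    p <- allele_freqs(evolved)
    mean(2 * p * (1 - p)) / h0
  }, numeric(1))
  expected <- (1 - 1 / (2 * N))^G
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - expected), 3 * se)
})

test_that("LD-panel designation is stratified, deterministic, and handles fraction 1", {
  p <- tiny_panel()
  full <- designate_ld_panel(p, 1)
  expect_true(all(full$ld_mask))

  frac <- designate_ld_panel(p, 0.2, seed = 7L)
  per_chr <- tapply(frac$ld_mask, frac$map$chr, sum)
  expect_true(all(per_chr == round(0.2 * table(frac$map$chr))))
  expect_identical(designate_ld_panel(p, 0.2, seed = 7L)$ld_mask, frac$ld_mask)
  expect_error(designate_ld_panel(p, 1.2), "fraction")
})

test_that("mean binned r2 does not increase with distance on the calibrated population", {
  exp <- desk_experiment()
  prof <- exp$prof_short
  ok <- !is.na(prof$mean_r2)
  trend <- cor(seq_along(prof$mean_r2)[ok], prof$mean_r2[ok], method = "spearman")
  expect_lte(trend, 0)
})

test_that("the calibrated demography reproduces the target LD level near 0.15 Mb", {
  exp <- desk_experiment()
  prof <- exp$prof_short # 25-kb bins: [125,150) and [150,175) kb are bins 6 and 7
  r2_band <- weighted.mean(prof$mean_r2[6:7], rowSums(prof$n_pairs)[6:7])
  expect_gt(r2_band, 0.15)
  expect_lt(r2_band, 0.25)
})
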