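test_that("QTL selection respects the MAF floor and the LD-panel exclusion", {
  ## 3 SNPs: MAF 0.04 (never a QTL), an LD-panel SNP, and a valid candidate
  dos <- cbind(
    c(1L, 1L, rep(0L, 23)),        # 2 of 50 alleles -> MAF 0.04
    rep(c(0L, 1L, 2L), length.out = 25),
    rep(c(2L, 1L, 0L, 1L), length.out = 25)
  )
  p <- manual_panel(dos, ld_mask = c(FALSE, TRUE, FALSE))
  for (s in 1:10) {
    arch <- select_qtl(p, 1L, maf_min = 0.05, seed = s)
    expect_identical(arch$qtl_indices, 3L)
  }
  expect_error(select_qtl(p, 3L), "candidate")

  ## exhaustive case: n_qtl equal to the pool size selects the whole pool
  p2 <- tiny_panel()
  pool <- which(!p2$ld_mask & panel_maf(p2) > 0.05)
  arch <- select_qtl(p2, length(pool), seed = 1L)
  expect_identical(arch$qtl_indices, pool)
  expect_true(all(!p2$ld_mask[arch$qtl_indices]))
})

test_that("QTL effects follow the gamma(0.4, scale 1.66) magnitude law with fair signs", {
  p <- tiny_panel()
  arch <- select_qtl(p, 10L, seed = 2L)
  big <- structure(list(qtl_indices = rep(arch$qtl_indices, 1000),
                        effects = NULL, n_qtl = 10000L, h2 = NULL,
                        scenario_id = NULL), class = "qtl_architecture")
  eff <- sample_effects(big, seed = 3L)$effects
  m <- mean(abs(eff))
  se <- sd(abs(eff)) / sqrt(length(eff))
  expect_lt(abs(m - 0.4 * 1.66), 3 * se)
  ## sign frequency within the binomial 99% interval around 0.5
  prop_pos <- mean(eff > 0)
  half_width <- qnorm(0.995) * sqrt(0.25 / length(eff))
  expect_lt(abs(prop_pos - 0.5), half_width)
  expect_identical(sample_effects(big, seed = 3L)$effects, eff)
})

test_that("trait simulation hits the variance contract exactly", {
  p <- tiny_panel()
  arch <- sample_effects(select_qtl(p, 15L, seed = 4L), seed = 5L)
  tr <- simulate_trait(p, arch, h2 = 0.3, seed = 6L)
  expect_equal(var(tr$tbv), 30, tolerance = 1e-12)
  expect_equal(tr$sigma_g2, 30)
  expect_equal(tr$sigma_e2, 70)
  expect_equal(tr$phenotypes, tr$tbv + tr$residuals)

  ## h2 = 1: no residual noise at all
  tr1 <- simulate_trait(p, arch, h2 = 1, seed = 7L)
  expect_identical(tr1$residuals, numeric(length(tr1$tbv)))
  expect_equal(tr1$phenotypes, tr1$tbv)

  ## monomorphic-QTL degenerate case
  dos <- cbind(rep(1L, 10), rep(2L, 10))
  pm <- manual_panel(dos)
  bad <- structure(list(qtl_indices = 2L, effects = 1, n_qtl = 1L,
                        h2 = NULL, scenario_id = NULL),
                   class = "qtl_architecture")
  expect_error(simulate_trait(pm, bad, h2 = 0.5), "variance")
})

test_that("phenotype regresses on TBV with slope 1", {
  exp <- desk_experiment()
  tr <- exp$traits[[2]] # h2 = 0.3, 100 QTLs, ~5000 animals
  fit <- lm(tr$phenotypes ~ tr$tbv)
  slope <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope - 1), 3 * se)
})

test_that("the full scenario grid simulates without error on the default panel", {
  exp <- desk_experiment()
  for (h2 in c(0.1, 0.3, 0.5)) {
    for (nq in c(100L, 500L, 2000L)) {
      arch <- sample_effects(select_qtl(exp$panel, nq, h2 = h2, seed = nq),
                             seed = nq + 1L)
      tr <- simulate_trait(exp$panel, arch, seed = nq + 2L)
      expect_equal(var(tr$tbv), 100 * h2, tolerance = 1e-10)
    }
  }
})

test_that("simulated fixed effects enter the phenotype additively", {
  p <- tiny_panel()
  arch <- sample_effects(select_qtl(p, 10L, seed = 1L), seed = 2L)
  tr <- simulate_trait(p, arch, h2 = 0.4, seed = 3L)
  covs <- simulate_covariates(p$animal_ids, seed = 4L)
  tr2 <- add_fixed_effects(tr, covs)
  expect_equal(tr2$phenotypes, attr(covs, "fixed_part") + tr$tbv + tr$residuals)
  X <- make_fixed_design(covs)
  expect_equal(nrow(X), length(p$animal_ids))
  expect_equal(qr(X)$rank, ncol(X))
})
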