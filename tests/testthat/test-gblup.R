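make_grm_obj <- function(G, ids = NULL) {
  ids <- ids %||% sprintf("id%02d", seq_len(nrow(G)))
  dimnames(G) <- list(ids, ids)
  structure(list(matrix = G, ids = ids, jitter = 0, n_snps_used = NA_integer_),
            class = "grm")
}

test_that("zero genetic variance collapses GBLUP to the phenotype mean", {
  set.seed(2)
  G <- diag(6) + 0.1
  grm <- make_grm_obj(G)
  y <- rnorm(6)
  f <- solve_gblup(y, grm, sigma_g2 = 0, sigma_e2 = 1)
  expect_equal(unname(f$gebv), rep(0, 6))
  expect_equal(f$mu, mean(y))
})

test_that("the MME solution matches the direct GLS/BLUP identity", {
  set.seed(3)
  Z <- matrix(rnorm(5 * 30), 5, 30)
  G <- tcrossprod(Z) / 30 + diag(0.05, 5)
  grm <- make_grm_obj(G)
  y <- rnorm(5, mean = 2)
  y[5] <- NA # one unphenotyped animal predicted through covariances
  sg <- 1.3; se <- 0.8
  f <- solve_gblup(y, grm, sg, se)

  obs <- which(!is.na(y))
  V <- sg * G[obs, obs] + se * diag(length(obs))
  X <- matrix(1, length(obs), 1)
  b <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y[obs]))
  g_or <- sg * G[, obs] %*% solve(V, y[obs] - X %*% b)
  expect_equal(unname(f$gebv), as.vector(g_or), tolerance = 1e-8)
  expect_equal(unname(f$fixed), as.vector(b), tolerance = 1e-8)

  ## reconstruction: fixed part + gebv + residual gives y back exactly
  expect_equal(unname(f$fixed[1] + f$gebv[obs] + f$residuals), y[obs],
               tolerance = 1e-10)
})

test_that("an animal unrelated to all phenotyped animals gets gebv 0", {
  G <- diag(4)
  G[1, 2] <- G[2, 1] <- 0.5 # animals 1-2 related; 4 is an island
  grm <- make_grm_obj(G)
  y <- c(1.2, -0.4, 0.7, NA)
  f <- solve_gblup(y, grm, 1, 1)
  expect_equal(unname(f$gebv[4]), 0, tolerance = 1e-10)
})

test_that("shrinkage: gebv norm is non-increasing in the variance ratio", {
  set.seed(4)
  Z <- matrix(rnorm(8 * 50), 8, 50)
  G <- tcrossprod(Z) / 50 + diag(0.05, 8)
  grm <- make_grm_obj(G)
  y <- rnorm(8)
  norms <- vapply(c(0.1, 1, 10, 100, 1000), function(k) {
    sqrt(sum(solve_gblup(y, grm, 1, k)$gebv^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("rank-deficient fixed designs fail naming the aliased columns", {
  G <- diag(5) + 0.01
  grm <- make_grm_obj(G)
  X <- cbind(`(Intercept)` = 1, a = 1:5, dup = 1:5)
  rownames(X) <- grm$ids
  expect_error(solve_gblup(rnorm(5), grm, 1, 1, fixed_design = X),
               "rank deficient.*dup")
})

test_that("adjusted phenotypes equal the phenotype minus the fitted fixed part", {
  real <- real_style_experiment()
  fit <- real$vc$fit
  y_adj <- adjusted_phenotypes(fit)
  expect_equal(y_adj, fit$y - as.vector(fit$X %*% fit$fixed),
               tolerance = 1e-10, ignore_attr = TRUE)
  ## fixed effects soak up variance
  expect_lt(var(y_adj), var(real$trait$phenotypes))

  ## intercept-only model: y_adj = y - mu
  G <- diag(6) + 0.05
  grm <- make_grm_obj(G)
  set.seed(5)
  y <- rnorm(6, 3)
  f <- solve_gblup(y, grm, 1, 1)
  expect_equal(unname(adjusted_phenotypes(f)), y - f$mu, tolerance = 1e-10)
})

test_that("the nested-Cholesky CV engine agrees with the general MME solver", {
  exp <- desk_experiment()
  ids <- exp$panel$animal_ids[1:120]
  grm <- make_grm_obj(exp$grm$matrix[ids, ids], ids)
  tr <- exp$traits[[2]]
  y <- setNames(tr$phenotypes, tr$animal_ids)[ids]
  tbv <- setNames(tr$tbv, tr$animal_ids)[ids]
  design <- make_design(ids, n_test = 20L, ref_sizes = c(40L, 80L),
                        n_replicates = 2L, seed = 9L)
  tab <- run_cv_simulated(tr, design, grm)
  for (j in 1:2) {
    for (i in 1:2) {
      s <- design$ref_sizes[i]
      ymask <- setNames(rep(NA_real_, length(ids)), ids)
      ref <- design$ref_ids[[j]][seq_len(s)]
      ymask[ref] <- y[ref]
      f <- solve_gblup(ymask, grm, tr$sigma_g2, tr$sigma_e2)
      r_direct <- cor(tbv[design$test_ids[[j]]], f$gebv[design$test_ids[[j]]])
      expect_equal(tab$r_values[i, j], r_direct, tolerance = 1e-8)
    }
  }
})
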