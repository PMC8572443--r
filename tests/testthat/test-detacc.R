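test_that("expected accuracy behaves at its boundary cases", {
  expect_equal(expected_accuracy(0, 0.3, 1, 1000), 0)
  expect_lt(abs(expected_accuracy(1e12, 0.3, 0.9, 1000) - 0.9), 1e-5)
  ## monotone non-decreasing curve, pointwise equal to the formula
  cv <- accuracy_curve(0.3, 1, 3000, n_max = 50000, step = 500)
  expect_true(all(diff(cv$accuracy) >= 0))
  expect_equal(cv$accuracy, expected_accuracy(cv$N, 0.3, 1, 3000))
  ## closed-form inversion: accuracy >= 0.9 iff N h2 >= Me * 0.81 / 0.19
  hit <- min(cv$N[cv$accuracy >= 0.9])
  n_star <- 3000 * 0.81 / 0.19 / 0.3
  expect_gte(hit, n_star)
  expect_lt(hit - 500, n_star)
  expect_error(expected_accuracy(100, 0.3, 1, -5), "Me")
})

test_that("the (w, Me) objective matches a literal double-loop oracle", {
  set.seed(12)
  sizes <- c(1000L, 2000L, 3000L, 5000L, 7000L, 9000L, 11000L)
  r <- matrix(runif(7 * 20, 0.2, 0.9), 7, 20)
  tab <- as_accuracy_table(r, sizes, h2 = 0.3)
  s2 <- apply(r, 1, var)
  oracle <- function(w, me) {
    tot <- 0
    for (i in 1:7) {
      for (j in 1:20) {
        E <- w * sqrt(sizes[i] * 0.3 / (sizes[i] * 0.3 + me))
        tot <- tot - (r[i, j] - E)^2 / (2 * s2[i])
      }
    }
    tot
  }
  for (par in list(c(0.5, 500), c(0.9, 3000), c(1, 100))) {
    expect_equal(loglik_w_me(par[1], par[2], tab), oracle(par[1], par[2]),
                 tolerance = 1e-12)
  }

  ## zero at the generating truth, strictly negative elsewhere
  E <- expected_accuracy(sizes, 0.3, 0.8, 2500)
  tab0 <- as_accuracy_table(matrix(rep(E, 20), 7, 20), sizes, h2 = 0.3)
  expect_warning(l0 <- loglik_w_me(0.8, 2500, tab0), "floored")
  expect_equal(l0, 0)
  expect_warning(l1 <- loglik_w_me(0.7, 2500, tab0), "floored")
  expect_lt(l1, 0)

  ## doubling the variances halves the magnitude
  s2b <- s2 * 2
  expect_equal(loglik_w_me(0.5, 500, tab, sigma_i2 = s2b),
               loglik_w_me(0.5, 500, tab, sigma_i2 = s2) / 2,
               tolerance = 1e-12)
})

test_that("the ML fit recovers (w, Me) exactly from a noiseless table", {
  sizes <- c(1000L, 2000L, 3000L, 5000L, 7000L, 9000L, 11000L)
  E <- expected_accuracy(sizes, 0.3, 1, 3000)
  tab <- as_accuracy_table(matrix(rep(E, 20), 7, 20), sizes, h2 = 0.3)
  fit <- suppressWarnings(fit_w_me(tab))
  expect_lt(abs(fit$w - 1), 1e-3)
  expect_lt(abs(fit$Me - 3000), 1)
  expect_equal(predict(fit, sizes), E, tolerance = 1e-3)
  expect_equal(unname(coef(fit)["Me"]), fit$Me)
})

test_that("no point of a coarse grid beats the returned optimum", {
  set.seed(14)
  sizes <- c(500L, 1000L, 2000L, 3000L)
  E <- expected_accuracy(sizes, 0.5, 0.92, 800)
  r <- matrix(rep(E, 10), 4, 10) + rnorm(40, 0, 0.02)
  tab <- as_accuracy_table(r, sizes, h2 = 0.5)
  fit <- fit_w_me(tab)
  grid_w <- seq(0, 1, by = 0.01)
  grid_me <- seq(10, 5000, by = 10)
  best_grid <- -Inf
  s2 <- fit$sigma_i2
  obj <- function(w, me) {
    Em <- w * sqrt(sizes * 0.5 / (sizes * 0.5 + me))
    -sum((r - Em)^2 / (2 * s2))
  }
  for (w in grid_w) {
    for (me in grid_me) {
      v <- obj(w, me)
      if (v > best_grid) best_grid <- v
    }
  }
  expect_gte(fit$loglik, best_grid - 1e-8)
})

test_that("a flat table is flagged non-identifiable", {
  tab <- as_accuracy_table(matrix(0.5, 3, 5), c(100L, 200L, 300L), h2 = 0.3)
  fit <- suppressWarnings(fit_w_me(tab))
  expect_false(fit$identifiable)
})

test_that("fitted (w, Me) predicts a held-out reference size", {
  exp <- desk_experiment()
  for (k in seq_along(exp$tables)) {
    tab <- exp$tables[[k]]
    held <- nrow(tab$r_values) # hold out the largest size
    sub <- as_accuracy_table(tab$r_values[-held, , drop = FALSE],
                             tab$ref_sizes[-held], h2 = tab$h2)
    fit <- fit_w_me(sub)
    pred <- predict(fit, tab$ref_sizes[held])
    obs <- mean(tab$r_values[held, ], na.rm = TRUE)
    sdv <- sd(tab$r_values[held, ], na.rm = TRUE)
    expect_lt(abs(pred - obs), 2 * sdv)
  }
})

test_that("Me from Ne follows the closed form and is monotone", {
  expect_equal(me_from_ne(50, 10), 2 * 50 * 10 / log(4 * 50 * 10))
  ne_grid <- seq(10, 10000, length.out = 50)
  expect_true(all(diff(me_from_ne(ne_grid, 31.6)) > 0))
  expect_error(me_from_ne(-1), "ne")
})

test_that("progeny-test EBV accuracy has the right edge cases", {
  expect_equal(ebv_accuracy(1, 0.36), sqrt(0.36) / 2)
  expect_lt(abs(ebv_accuracy(1e9, 0.3) - 1), 1e-4)
  expect_error(ebv_accuracy(0, 0.3), "n_progeny")
})
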