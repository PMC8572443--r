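test_that("animal call-rate filtering removes exactly the low-call animals", {
  p <- tiny_panel()
  out <- filter_animals_by_call_rate(p, 0.95)
  expect_equal(n_animals(out$panel), n_animals(p)) # no missing data -> no removals
  expect_equal(nrow(out$report$removals), 0L)

  ## toy panel, call rates {1, 0.95, 0.40}: only the last falls below 0.95
  dos <- matrix(1L, 3, 20)
  dos[2, 1] <- NA
  dos[3, 1:12] <- NA
  pm <- manual_panel(dos)
  out <- filter_animals_by_call_rate(pm, 0.95)
  expect_equal(out$report$n_animals_out, 2L)
  expect_equal(out$report$removals$id, pm$animal_ids[3])
  expect_equal(out$report$removals$reason, "call_rate")

  ## 10% missing is below a 0.95 threshold
  dos2 <- matrix(1L, 2, 10); dos2[1, 1] <- NA
  out2 <- filter_animals_by_call_rate(manual_panel(dos2), 0.95)
  expect_equal(out2$report$n_animals_out, 1L)
})

test_that("the HWE test matches a hand-computed chi-square oracle", {
  expect_equal(hwe_test(25, 50, 25), 1)

  ## oracle: expected counts from the observed allele frequency, 1 df
  hwe_oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    p <- (2 * nAA + nAa) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((c(nAA, nAa, naa) - e)^2 / e)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  expect_equal(hwe_test(30, 30, 40), hwe_oracle(30, 30, 40), tolerance = 1e-10)
  expect_lt(hwe_test(50, 0, 50), 1e-10)
  expect_error(hwe_test(0, 0, 0), "count")
})

test_that("SNP QC removes by MAF, call rate and HWE with one primary reason each", {
  dos <- cbind(
    c(1L, rep(0L, 99)),                        # MAF 0.005 -> maf
    rep(2L, 100),                              # monomorphic -> maf
    c(rep(NA_integer_, 10), rep(1L, 90)),      # call rate 0.90 -> call_rate
    rep(c(0L, 2L), 50),                        # no hets at p = 0.5 -> hwe
    rep(c(0L, 1L, 2L, 1L), 25)                 # clean
  )
  p <- manual_panel(dos)
  out <- filter_snps(p, maf_min = 0.01, call_rate_min = 0.95, hwe_p_min = 1e-3)
  expect_equal(n_snps(out$panel), 1L)
  expect_equal(out$panel$map$snp_id, "s005")
  reasons <- out$report$removals
  expect_equal(reasons$reason[match(c("s001", "s002", "s003", "s004"), reasons$id)],
               c("maf", "maf", "call_rate", "hwe"))

  ## idempotence: filtering an already-clean panel changes nothing
  out2 <- filter_snps(out$panel, 0.01, 0.95, 1e-3)
  expect_identical(out2$panel$dosages, out$panel$dosages)
})

test_that("relatedness pruning removes one of a violating pair and nothing else", {
  G <- diag(3) + 0.01
  ids <- c("a", "b", "c")
  dimnames(G) <- list(ids, ids)
  grm <- structure(list(matrix = G, ids = ids, jitter = 0, n_snps_used = 10L),
                   class = "grm")
  out <- prune_related(grm, 0.4)
  expect_equal(out$kept_ids, ids) # near-identity: nothing removed

  G2 <- G; G2["a", "b"] <- G2["b", "a"] <- 0.6
  grm2 <- structure(list(matrix = G2, ids = ids, jitter = 0, n_snps_used = 10L),
                    class = "grm")
  out2 <- prune_related(grm2, 0.4)
  expect_equal(length(out2$kept_ids), 2L)
  expect_true("c" %in% out2$kept_ids)
  expect_equal(sum(c("a", "b") %in% out2$kept_ids), 1L)
})

test_that("pruning is near-optimal against an exhaustive vertex-cover oracle", {
  min_vertex_cover <- function(A) {
    n <- nrow(A)
    pairs <- which(A & upper.tri(A), arr.ind = TRUE)
    if (!nrow(pairs)) return(0L)
    for (k in 0:n) {
      for (set in utils::combn(n, k, simplify = FALSE)) {
        covered <- apply(pairs, 1, function(pr) any(pr %in% set))
        if (all(covered)) return(k)
      }
    }
    n
  }
  n_components <- function(A) {
    n <- nrow(A); seen <- rep(FALSE, n); comp <- 0L
    for (v in seq_len(n)) {
      if (seen[v]) next
      comp <- comp + 1L
      queue <- v
      while (length(queue)) {
        u <- queue[[1]]; queue <- queue[-1]
        if (seen[u]) next
        seen[u] <- TRUE
        queue <- c(queue, which(A[u, ] & !seen))
      }
    }
    comp
  }
  set.seed(99)
  for (trial in 1:10) {
    n <- sample(4:6, 1)
    G <- diag(n)
    ij <- which(upper.tri(G), arr.ind = TRUE)
    vals <- sample(c(0.1, 0.5), nrow(ij), replace = TRUE, prob = c(0.6, 0.4))
    G[ij] <- vals; G[ij[, c(2, 1)]] <- vals
    ids <- letters[seq_len(n)]
    dimnames(G) <- list(ids, ids)
    grm <- structure(list(matrix = G, ids = ids, jitter = 0, n_snps_used = 1L),
                     class = "grm")
    out <- prune_related(grm, 0.4)
    keep_idx <- match(out$kept_ids, ids)
    sub <- G[keep_idx, keep_idx, drop = FALSE]
    diag(sub) <- 0
    expect_true(all(sub <= 0.4)) # no violating pair survives
    A <- G > 0.4; diag(A) <- FALSE
    removed <- n - length(keep_idx)
    expect_lte(removed, min_vertex_cover(A) + n_components(A))
  }
})

test_that("phenotype trimming applies the 3-SD rule in a single pass", {
  ## note a 3-SD outlier needs n > 10 when the SD includes the outlier itself
  ## (max |z| in a table of n rows is (n-1)/sqrt(n))
  set.seed(31)
  n <- 30L
  tab <- data.frame(animal_id = sprintf("a%02d", 1:n),
                    t1 = rnorm(n), t2 = rnorm(n))
  out <- trim_phenotypes(tab, n_sd = 3)
  expect_equal(nrow(out$table), n) # nothing extreme yet

  tab2 <- tab
  m <- mean(tab2$t2); s <- sd(tab2$t2)
  tab2$t2[4] <- m + 15 * s # plant one gross outlier
  out2 <- trim_phenotypes(tab2, n_sd = 3)
  expect_equal(nrow(out2$table), n - 1L)
  expect_equal(out2$report$removals$id, "a04")
  expect_equal(out2$report$removals$reason, "phenotype_outlier")

  ## all-identical trait: zero variance is skipped with a warning, no removals
  tab3 <- data.frame(animal_id = c("x", "y", "z"), t1 = c(5, 5, 5))
  expect_warning(out3 <- trim_phenotypes(tab3), "zero variance")
  expect_equal(nrow(out3$table), 3L)

  ## idempotence
  out4 <- trim_phenotypes(out2$table, n_sd = 3)
  expect_equal(nrow(out4$table), nrow(out2$table))
})
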