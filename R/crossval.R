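#' Nested reference/test cross-validation design
#'
#' Per replicate, a test set of `n_test` animals is drawn, then a reference
#' pool of `max(ref_sizes)` animals is drawn from the remainder; the
#' reference set of size s is the first s animals of that pool, so smaller
#' reference populations are always contained in larger ones (incremental
#' augmentation). Test and reference sets are disjoint by construction.
#'
#' @param animal_ids character vector of available animals.
#' @param n_test test-set size per replicate.
#' @param ref_sizes strictly increasing reference-population sizes.
#' @param n_replicates number of replicates.
#' @param seed integer seed (the design is fully determined by it).
#' @return an object of class `cv_design`.
#' @export
make_design <- function(animal_ids, n_test, ref_sizes, n_replicates,
                        seed = NULL) {
  ref_sizes <- as.integer(ref_sizes)
  if (any(diff(ref_sizes) <= 0)) stop_config("ref_sizes must be strictly increasing")
  need <- n_test + max(ref_sizes)
  if (need > length(animal_ids)) {
    stop_config("design needs %d animals but only %d available (short by %d)",
                need, length(animal_ids), need - length(animal_ids))
  }
  with_seed(seed, {
    test_ids <- vector("list", n_replicates)
    ref_ids <- vector("list", n_replicates)
    for (j in seq_len(n_replicates)) {
      test_ids[[j]] <- sample(animal_ids, n_test)
      pool <- setdiff(animal_ids, test_ids[[j]])
      ref_ids[[j]] <- sample(pool, max(ref_sizes))
    }
    structure(
      list(test_ids = test_ids, ref_ids = ref_ids, ref_sizes = ref_sizes,
           n_test = as.integer(n_test), n_replicates = as.integer(n_replicates),
           seed = seed),
      class = "cv_design"
    )
  })
}

#' @export
print.cv_design <- function(x, ...) {
  cat(sprintf("CV design: %d replicates, test n = %d, reference sizes %s (nested)\n",
              x$n_replicates, x$n_test, paste(x$ref_sizes, collapse = "/")))
  invisible(x)
}

## Shared CV engine. Model (1): y = 1 mu + g + e with fixed variances.
## For each replicate one Cholesky factorisation of
## V = sigma_g2 G_ref + sigma_e2 I at the largest reference size is computed;
## because reference sets are nested and ordered, the factor of every smaller
## V is its leading block, so smaller sizes cost only triangular solves.
## accuracy(i, j) = cor(target_test, ghat_test) / scale.
.cv_engine <- function(response, target, design, grm, sigma_g2, sigma_e2,
                       scale = 1) {
  sizes <- design$ref_sizes
  r <- matrix(NA_real_, length(sizes), design$n_replicates,
              dimnames = list(size = sizes, replicate = seq_len(design$n_replicates)))
  G <- grm$matrix
  any_degenerate <- FALSE
  for (j in seq_len(design$n_replicates)) {
    ref <- match(design$ref_ids[[j]], grm$ids)
    test <- match(design$test_ids[[j]], grm$ids)
    if (anyNA(ref) || anyNA(test)) stop_config("design ids missing from GRM")
    V <- sigma_g2 * G[ref, ref]
    diag(V) <- diag(V) + sigma_e2
    R <- chol(V)
    Gtr <- sigma_g2 * G[test, ref, drop = FALSE]
    yref <- response[ref]
    tt <- target[test]
    for (i in seq_along(sizes)) {
      s <- sizes[i]
      Rs <- R[seq_len(s), seq_len(s), drop = FALSE]
      u <- backsolve(Rs, yref[seq_len(s)], transpose = TRUE)
      v <- backsolve(Rs, rep(1, s), transpose = TRUE)
      mu <- sum(v * u) / sum(v * v)
      alpha <- backsolve(Rs, u - mu * v)
      ghat <- as.vector(Gtr[, seq_len(s), drop = FALSE] %*% alpha)
      if (stats::sd(ghat) == 0 || stats::sd(tt) == 0) {
        any_degenerate <- TRUE
      } else {
        r[i, j] <- stats::cor(tt, ghat) / scale
      }
    }
  }
  if (any_degenerate) {
    warning("zero-variance GEBV or target in some test sets; accuracies recorded as NA")
  }
  r
}

#' Cross-validated GEBV accuracy for a simulated trait
#'
#' For every replicate and reference size: test phenotypes are masked, GBLUP
#' (intercept-only model) is solved with the scenario's *setting* variances
#' (never re-estimated per replicate), and accuracy is the Pearson
#' correlation between true and estimated breeding values in the test set.
#'
#' @param trait a [simulate_trait()] result.
#' @param design a [make_design()] result.
#' @param grm GRM over all animals (built once, subset per replicate).
#' @param sigma_g2,sigma_e2 fixed variances; default to the trait's setting
#'   values 100 h2 and 100 (1 - h2).
#' @param scenario optional label stored on the result.
#' @return an `accuracy_table` (sizes x replicates matrix of correlations
#'   plus metadata).
#' @export
run_cv_simulated <- function(trait, design, grm,
                             sigma_g2 = trait$sigma_g2,
                             sigma_e2 = trait$sigma_e2,
                             scenario = NULL) {
  stopifnot(inherits(trait, "trait_realization"))
  y <- stats::setNames(trait$phenotypes, trait$animal_ids)[grm$ids]
  tbv <- stats::setNames(trait$tbv, trait$animal_ids)[grm$ids]
  if (anyNA(y)) stop_config("trait does not cover all GRM animals")
  r <- .cv_engine(y, tbv, design, grm, sigma_g2, sigma_e2, scale = 1)
  new_accuracy_table(r, design$ref_sizes, h2 = trait$h2,
                     n_qtl = trait$architecture$n_qtl,
                     scenario = scenario %||% trait$architecture$scenario_id)
}

#' Cross-validated GEBV accuracy for an adjusted real-style phenotype
#'
#' As [run_cv_simulated()], but the response and validation target are the
#' adjusted phenotypes (y_adj = ghat + ehat from the fixed-effects model) and
#' accuracy is cor(y_adj, GEBV) / sqrt(h2). Values can exceed 1 and are
#' reported as computed (flagged, not clipped).
#'
#' @param y_adj named vector of adjusted phenotypes covering all GRM animals.
#' @param h2 genomic heritability used for the scaling; must be > 0.
#' @param design,grm,sigma_g2,sigma_e2 as in [run_cv_simulated()]; the
#'   variances should be full-data REML estimates.
#' @param scenario optional label.
#' @return an `accuracy_table`.
#' @export
run_cv_real_style <- function(y_adj, h2, design, grm, sigma_g2, sigma_e2,
                              scenario = NULL) {
  if (is.null(h2) || is.na(h2) || h2 <= 0) {
    stop_config("run_cv_real_style: h2 must be > 0")
  }
  y <- y_adj[grm$ids]
  if (anyNA(y)) stop_config("y_adj does not cover all GRM animals")
  r <- .cv_engine(y, y, design, grm, sigma_g2, sigma_e2, scale = sqrt(h2))
  out <- new_accuracy_table(r, design$ref_sizes, h2 = h2, n_qtl = NA_integer_,
                            scenario = scenario)
  out$exceeds_one <- any(r > 1, na.rm = TRUE)
  out
}

#' Construct an accuracy table from a matrix of replicate accuracies
#'
#' For accuracies produced outside [run_cv_simulated()] (e.g. published
#' curves or external software): rows are reference sizes, columns are
#' replicates.
#'
#' @param r_values numeric matrix, sizes x replicates.
#' @param ref_sizes reference sizes, one per row.
#' @param h2 heritability of the validated trait.
#' @param n_qtl,scenario optional metadata.
#' @return an `accuracy_table`.
#' @export
as_accuracy_table <- function(r_values, ref_sizes, h2, n_qtl = NA_integer_,
                              scenario = NULL) {
  r_values <- as.matrix(r_values)
  if (nrow(r_values) != length(ref_sizes)) {
    stop_config("r_values must have one row per reference size")
  }
  new_accuracy_table(r_values, ref_sizes, h2, n_qtl, scenario)
}

new_accuracy_table <- function(r_values, ref_sizes, h2, n_qtl, scenario) {
  structure(
    list(r_values = r_values, ref_sizes = as.integer(ref_sizes), h2 = h2,
         n_qtl = n_qtl, scenario = scenario, exceeds_one = FALSE),
    class = "accuracy_table"
  )
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat(sprintf("Accuracy table: %d sizes x %d replicates (h2 = %s, nQTL = %s)\n",
              nrow(x$r_values), ncol(x$r_values),
              format(x$h2), format(x$n_qtl)))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' Per-size mean and SD of cross-validated accuracies
#'
#' @param object an `accuracy_table`.
#' @param ... unused.
#' @return data.frame with size, mean, sd and the number of non-missing
#'   replicates entering each summary.
#' @export
summary.accuracy_table <- function(object, ...) {
  r <- object$r_values
  data.frame(
    size = object$ref_sizes,
    mean = apply(r, 1, mean, na.rm = TRUE),
    sd = apply(r, 1, stats::sd, na.rm = TRUE),
    n = apply(r, 1, function(z) sum(!is.na(z))),
    row.names = NULL
  )
}

#' @export
plot.accuracy_table <- function(x, ...) {
  s <- summary(x)
  graphics::plot(s$size, s$mean, ylim = range(c(s$mean - s$sd, s$mean + s$sd)),
                 xlab = "reference population size", ylab = "GEBV accuracy",
                 pch = 19, ...)
  graphics::arrows(s$size, s$mean - s$sd, s$size, s$mean + s$sd,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Long-format accuracies
#'
#' @param table an `accuracy_table`.
#' @return data.frame (scenario, h2, n_qtl, size, replicate, accuracy).
#' @export
accuracy_long <- function(table) {
  r <- table$r_values
  data.frame(
    scenario = table$scenario %||% NA_character_,
    h2 = table$h2, n_qtl = table$n_qtl,
    size = rep(table$ref_sizes, ncol(r)),
    replicate = rep(seq_len(ncol(r)), each = nrow(r)),
    accuracy = as.vector(r)
  )
}
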