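#' Expected GEBV accuracy for a given reference population size
#'
#' Deterministic accuracy of genomic prediction:
#' r = w * sqrt(N h2 / (N h2 + Me)), where N is the reference population
#' size, h2 the trait heritability, Me the number of independently
#' segregating chromosome segments and w the asymptotic accuracy as N grows
#' without bound (0 <= w <= 1).
#'
#' @param N reference population size(s), >= 0 (vectorised).
#' @param h2 heritability in (0, 1].
#' @param w asymptotic accuracy in [0, 1].
#' @param Me number of independent chromosome segments, > 0.
#' @return expected accuracy (same length as `N`).
#' @export
expected_accuracy <- function(N, h2, w, Me) {
  if (any(N < 0)) stop_config("N must be >= 0")
  if (h2 <= 0 || h2 > 1) stop_config("h2 must be in (0, 1]")
  if (w < 0 || w > 1) stop_config("w must be in [0, 1]")
  if (Me <= 0) stop_config("Me must be > 0")
  w * sqrt(N * h2 / (N * h2 + Me))
}

#' Log-likelihood (up to a constant) of (w, Me) given an accuracy table
#'
#' Replicate accuracies r_ij at reference size N_i are modelled as normal
#' around the deterministic expectation E(r_i) with per-size variance
#' sigma_i^2, giving the objective
#' L(w, Me) = - sum_ij (r_ij - E(r_i))^2 / (2 sigma_i^2).
#' It is zero when every residual vanishes and negative otherwise.
#'
#' @param w,Me parameters of [expected_accuracy()].
#' @param table an `accuracy_table`.
#' @param h2 heritability (defaults to the table's).
#' @param sigma_i2 per-size variances; default: the empirical variance of
#'   the replicates within each size. Values below `sigma_floor` are
#'   replaced by it with a warning.
#' @param sigma_floor variance floor guarding degenerate replicate sets.
#' @return the objective value (<= 0).
#' @export
loglik_w_me <- function(w, Me, table, h2 = table$h2, sigma_i2 = NULL,
                        sigma_floor = 1e-6) {
  r <- table$r_values
  if (is.null(sigma_i2)) {
    sigma_i2 <- apply(r, 1, stats::var, na.rm = TRUE)
  }
  if (any(!is.finite(sigma_i2) | sigma_i2 < sigma_floor)) {
    warning(sprintf("per-size variance below %g floored", sigma_floor))
    sigma_i2[!is.finite(sigma_i2) | sigma_i2 < sigma_floor] <- sigma_floor
  }
  E <- expected_accuracy(table$ref_sizes, h2, w, Me)
  -sum(sweep((r - E)^2, 1, 2 * sigma_i2, "/"), na.rm = TRUE)
}

#' Fit the asymptote w and segment number Me to an accuracy table
#'
#' Maximum-likelihood estimation of (w, Me) under the normal model of
#' [loglik_w_me()], with w restricted to [0, 1]. The search runs bounded
#' quasi-Newton (L-BFGS-B) over (w, log Me) from a grid of starting points
#' (log-parameterising Me conditions the 2-D search), keeping the best
#' optimum.
#'
#' @param table an `accuracy_table` with >= 2 sizes and >= 2 replicates.
#' @param h2 heritability (defaults to the table's).
#' @param me_max upper bound for Me.
#' @param sigma_floor variance floor passed to the objective.
#' @return an object of class `erbe_fit` with components `w`, `Me`,
#'   `loglik`, `h2`, `sigma_i2`, `table`, `identifiable` and
#'   `optimizer_trace` (one row per start).
#' @export
fit_w_me <- function(table, h2 = table$h2, me_max = 1e8, sigma_floor = 1e-6) {
  r <- table$r_values
  if (nrow(r) < 2L || ncol(r) < 2L) {
    stop_config("fit_w_me: need >= 2 sizes and >= 2 replicates")
  }
  sigma_i2 <- apply(r, 1, stats::var, na.rm = TRUE)
  floored <- !is.finite(sigma_i2) | sigma_i2 < sigma_floor
  if (any(floored)) {
    warning(sprintf("empirical variance floored at %g for %d size(s)",
                    sigma_floor, sum(floored)))
    sigma_i2[floored] <- sigma_floor
  }
  identifiable <- stats::sd(r, na.rm = TRUE) > 1e-12
  sizes <- table$ref_sizes
  negll <- function(par) {
    E <- par[1] * sqrt(sizes * h2 / (sizes * h2 + exp(par[2])))
    sum(sweep((r - E)^2, 1, 2 * sigma_i2, "/"), na.rm = TRUE)
  }
  starts <- expand.grid(w = seq(0.2, 1, length.out = 5),
                        logme = log(c(10, 100, 1e3, 1e4, 1e5)))
  trace <- data.frame(w0 = starts$w, me0 = exp(starts$logme),
                      w = NA_real_, me = NA_real_, value = NA_real_,
                      convergence = NA_integer_)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(c(starts$w[k], starts$logme[k]), negll,
                      method = "L-BFGS-B",
                      lower = c(0, log(1e-3)), upper = c(1, log(me_max)),
                      control = list(factr = 1e4, maxit = 500))
    trace$w[k] <- o$par[1]; trace$me[k] <- exp(o$par[2])
    trace$value[k] <- -o$value; trace$convergence[k] <- o$convergence
    if (is.null(best) || o$value < best$value) best <- o
  }
  ## polish from the best start with a tighter tolerance
  o <- stats::optim(best$par, negll, method = "L-BFGS-B",
                    lower = c(0, log(1e-3)), upper = c(1, log(me_max)),
                    control = list(factr = 10, maxit = 1000))
  if (o$value <= best$value) best <- o
  structure(
    list(w = best$par[1], Me = exp(best$par[2]), loglik = -best$value,
         h2 = h2, sigma_i2 = sigma_i2, table = table,
         identifiable = identifiable, optimizer_trace = trace),
    class = "erbe_fit"
  )
}

#' @export
print.erbe_fit <- function(x, ...) {
  cat(sprintf("Deterministic-accuracy fit: w = %.3f, Me = %.1f (loglik %.3f)\n",
              x$w, x$Me, x$loglik))
  if (!x$identifiable) cat("  warning: flat likelihood (constant accuracies)\n")
  invisible(x)
}

#' @export
coef.erbe_fit <- function(object, ...) c(w = object$w, Me = object$Me)

#' @export
logLik.erbe_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, class = "logLik")
}

#' @export
summary.erbe_fit <- function(object, ...) {
  s <- summary(object$table)
  s$fitted <- expected_accuracy(s$size, object$h2, object$w, object$Me)
  structure(list(coef = coef(object), h2 = object$h2, by_size = s,
                 loglik = object$loglik),
            class = "summary.erbe_fit")
}

#' @export
print.summary.erbe_fit <- function(x, ...) {
  cat(sprintf("w = %.3f, Me = %.1f, h2 = %.2f, loglik = %.3f\n",
              x$coef["w"], x$coef["Me"], x$h2, x$loglik))
  print(x$by_size, row.names = FALSE)
  invisible(x)
}

#' Predict expected accuracy at new reference sizes
#'
#' @param object an `erbe_fit`.
#' @param N reference population sizes.
#' @param h2 heritability (defaults to the fit's).
#' @param ... unused.
#' @export
predict.erbe_fit <- function(object, N, h2 = object$h2, ...) {
  expected_accuracy(N, h2, object$w, object$Me)
}

#' @export
plot.erbe_fit <- function(x, n_max = NULL, ...) {
  s <- summary(x$table)
  n_max <- n_max %||% max(s$size)
  grid <- seq(0, n_max, length.out = 200)
  graphics::plot(grid, predict(x, grid), type = "l", ylim = c(0, 1),
                 xlab = "reference population size",
                 ylab = "GEBV accuracy", ...)
  graphics::points(s$size, s$mean, pch = 19)
  graphics::arrows(s$size, s$mean - s$sd, s$size, s$mean + s$sd,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Expected-accuracy curve over a grid of reference sizes
#'
#' @param h2,w,Me parameters of [expected_accuracy()].
#' @param n_max largest reference size (default 50000).
#' @param step grid step (default 100).
#' @return data.frame with columns `N` and `accuracy` (non-decreasing in N).
#' @export
accuracy_curve <- function(h2, w, Me, n_max = 50000, step = 100) {
  N <- seq(0, n_max, by = step)
  data.frame(N = N, accuracy = expected_accuracy(N, h2, w, Me))
}

#' Number of independent chromosome segments from effective population size
#'
#' Me = 2 Ne L / ln(4 Ne L), with L the genome length in morgans.
#'
#' @param ne effective population size (> 0).
#' @param L genome length in morgans (default 31.6, a cattle-genome value).
#' @return Me (vectorised over `ne`).
#' @export
me_from_ne <- function(ne, L = 31.6) {
  if (any(ne <= 0) || L <= 0 || any(4 * ne * L <= 1)) {
    stop_config("me_from_ne: need ne > 0, L > 0 and 4*ne*L > 1")
  }
  2 * ne * L / log(4 * ne * L)
}

#' Progeny-test EBV accuracy
#'
#' Accuracy of a sire's conventional EBV from n half-sib progeny records:
#' r = sqrt(n h2 / (4 + (n - 1) h2)).
#'
#' @param n_progeny number of progeny per candidate (>= 1, vectorised).
#' @param h2 trait heritability in (0, 1].
#' @return EBV accuracy.
#' @export
ebv_accuracy <- function(n_progeny, h2) {
  if (any(n_progeny < 1)) stop_config("n_progeny must be >= 1")
  if (any(h2 <= 0 | h2 > 1)) stop_config("h2 must be in (0, 1]")
  sqrt(n_progeny * h2 / (4 + (n_progeny - 1) * h2))
}
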