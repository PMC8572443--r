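#' REML variance components for the single-GRM animal model
#'
#' Estimates (sigma_g2, sigma_e2) in y = Xb + g + e, g ~ N(0, G sigma_g2),
#' e ~ N(0, I sigma_e2), for fully phenotyped animals. The GRM is
#' eigendecomposed once (G = U D U'); in the rotated basis the covariance is
#' diagonal, so the restricted likelihood profiles analytically over
#' sigma_e2 and reduces to a one-dimensional search over the variance ratio
#' lambda = sigma_g2 / sigma_e2. That search is exact up to the optimiser's
#' bracketing tolerance - no iterative REML updates that can leave the
#' parameter space.
#'
#' The heritability is h2 = sigma_g2 / (sigma_g2 + sigma_e2); its standard
#' error comes from the inverse observed information of the restricted
#' likelihood in (sigma_g2, sigma_e2) via the delta method.
#'
#' @param y numeric phenotype vector aligned with (or named by) `grm$ids`;
#'   must be complete.
#' @param grm a [compute_grm()] result.
#' @param fixed_design optional fixed-effect design matrix (rownames = ids);
#'   intercept-only when omitted.
#' @return an object of class `varcomp`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `se_h2`, `converged`, `identifiable`, `n_iterations`, `loglik`
#'   (restricted, up to an additive constant), and `fit` - a `gblup_fit`
#'   with BLUEs/BLUPs evaluated at the estimates.
#' @export
estimate_varcomp <- function(y, grm, fixed_design = NULL) {
  n <- length(grm$ids)
  if (!is.null(names(y))) y <- y[grm$ids]
  if (length(y) != n || anyNA(y)) {
    stop_config("estimate_varcomp: y must be complete and aligned with grm$ids")
  }
  X <- if (is.null(fixed_design)) {
    matrix(1, n, 1, dimnames = list(grm$ids, "(Intercept)"))
  } else {
    fixed_design[grm$ids, , drop = FALSE]
  }
  p <- qr(X)$rank
  if (p < ncol(X)) stop_config("fixed-effect design is rank deficient")
  if (n <= p + 2L) stop_config("need more animals than fixed-effect columns + 2")

  ed <- eigen(grm$matrix, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  U <- ed$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  ## the variance split is identified only through spread in the spectrum
  identifiable <- (max(d) - min(d)) > 1e-8 * max(mean(d), 1)

  n_eval <- 0L
  neg2l_lambda <- function(loglam) {
    n_eval <<- n_eval + 1L
    delta <- exp(loglam) * d + 1
    wi <- 1 / delta
    XtWiX <- crossprod(Xs, Xs * wi)
    XtWiy <- crossprod(Xs, ys * wi)
    b <- solve(XtWiX, XtWiy)
    Q <- sum(ys^2 * wi) - sum(b * XtWiy)
    se2 <- Q / (n - p)
    (n - p) * log(se2) + sum(log(delta)) +
      determinant(XtWiX, logarithm = TRUE)$modulus + (n - p)
  }

  lo <- -25; hi <- 25
  opt <- stats::optimize(neg2l_lambda, c(lo, hi), tol = 1e-9)
  loglam <- opt$minimum
  converged <- identifiable && (loglam > lo + 0.5) && (loglam < hi - 0.5)

  lambda <- exp(loglam)
  delta <- lambda * d + 1
  wi <- 1 / delta
  XtWiX <- crossprod(Xs, Xs * wi)
  b <- solve(XtWiX, crossprod(Xs, ys * wi))
  Q <- sum((ys - Xs %*% b)^2 * wi)
  sigma_e2 <- Q / (n - p)
  sigma_g2 <- lambda * sigma_e2
  h2 <- sigma_g2 / (sigma_g2 + sigma_e2)

  ## restricted -2 log-likelihood as a function of (sg2, se2), for the SE
  neg2l_vc <- function(th) {
    sg <- th[1]; se <- th[2]
    if (se <= 0 || sg < 0) return(Inf)
    delta <- sg * d + se
    wi <- 1 / delta
    XtWiX <- crossprod(Xs, Xs * wi)
    bb <- solve(XtWiX, crossprod(Xs, ys * wi))
    Q <- sum((ys - Xs %*% bb)^2 * wi)
    sum(log(delta)) + determinant(XtWiX, logarithm = TRUE)$modulus[1] + Q
  }
  se_h2 <- NA_real_
  if (identifiable) {
    th <- c(sigma_g2, sigma_e2)
    eps <- pmax(1e-4 * th, 1e-6)
    H <- matrix(NA_real_, 2, 2)
    f0 <- neg2l_vc(th)
    for (i in 1:2) for (j in i:2) {
      ei <- ej <- c(0, 0); ei[i] <- eps[i]; ej[j] <- eps[j]
      H[i, j] <- H[j, i] <-
        (neg2l_vc(th + ei + ej) - neg2l_vc(th + ei - ej) -
           neg2l_vc(th - ei + ej) + neg2l_vc(th - ei - ej)) / (4 * eps[i] * eps[j])
    }
    info <- H / 2
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(cov)) {
      gr <- c(sigma_e2, -sigma_g2) / (sigma_g2 + sigma_e2)^2
      v <- drop(t(gr) %*% cov %*% gr)
      if (is.finite(v) && v >= 0) se_h2 <- sqrt(v)
    }
  }

  ## BLUEs / BLUPs at the estimates: ghat = sigma_g2 G V^{-1} (y - X bhat)
  r <- ys - Xs %*% b
  gebv <- as.vector(U %*% (lambda * d * wi * r)) # sg2 D / (sg2 D + se2 I) in rotated basis
  names(gebv) <- grm$ids
  bhat <- stats::setNames(as.vector(b), colnames(X))
  resid <- y - as.vector(X %*% b) - gebv
  fit <- structure(
    list(fixed = bhat, gebv = gebv, residuals = stats::setNames(resid, grm$ids),
         mu = if (ncol(X) == 1L) unname(bhat[1]) else NA_real_,
         y = stats::setNames(y, grm$ids), obs = seq_len(n), X = X,
         sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
    class = "gblup_fit"
  )
  structure(
    list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, h2 = h2, se_h2 = se_h2,
         converged = converged, identifiable = identifiable,
         n_iterations = n_eval, loglik = -opt$objective / 2, fit = fit),
    class = "varcomp"
  )
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("REML variance components: sigma_g2 = %.3f, sigma_e2 = %.3f\n",
              x$sigma_g2, x$sigma_e2))
  cat(sprintf("  h2 = %.3f (SE %.3f), %s after %d likelihood evaluations\n",
              x$h2, x$se_h2,
              if (x$converged) "converged" else "NOT converged (flat or boundary)",
              x$n_iterations))
  if (!x$identifiable) {
    cat("  warning: variance split not identifiable (GRM spectrum is flat)\n")
  }
  invisible(x)
}
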