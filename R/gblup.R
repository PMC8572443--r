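#' Solve GBLUP mixed-model equations with fixed variances
#'
#' Fits y = Xb + Zg + e with g ~ N(0, G sigma_g2) over *all* animals in the
#' GRM and e ~ N(0, I sigma_e2) over the phenotyped ones, the variance
#' components held fixed. Unphenotyped animals (NA in `y`) receive predicted
#' breeding values through their genomic covariances with the phenotyped
#' set - this is how a test population is evaluated. Solved by the standard
#' Henderson mixed-model equations with G inverted once (the GRM's diagonal
#' jitter keeps that stable).
#'
#' @param y numeric vector of phenotypes aligned with `grm$ids` (or named by
#'   them); `NA` marks unphenotyped animals.
#' @param grm a [compute_grm()] result covering all animals.
#' @param sigma_g2,sigma_e2 additive-genetic and residual variances
#'   (trait units squared); `sigma_e2` must be positive.
#' @param fixed_design optional fixed-effect design matrix with rownames
#'   matching animal ids (an intercept-only model is used when omitted,
#'   matching routine evaluation).
#' @return an object of class `gblup_fit`: `fixed` (BLUEs), `gebv` (named,
#'   all animals), `residuals` (phenotyped animals), `mu` (intercept when
#'   the design is intercept-only), plus the inputs needed to reconstruct
#'   the fit. For phenotyped animals, fixed part + gebv + residual
#'   reconstructs y exactly.
#' @export
solve_gblup <- function(y, grm, sigma_g2, sigma_e2, fixed_design = NULL) {
  n <- length(grm$ids)
  if (!is.null(names(y))) y <- y[grm$ids]
  if (length(y) != n) stop_config("y must align with grm$ids")
  if (sigma_e2 <= 0) stop_config("sigma_e2 must be > 0")
  if (sigma_g2 < 0) stop_config("sigma_g2 must be >= 0")
  obs <- which(!is.na(y))
  if (!length(obs)) stop_config("no phenotyped animals")
  X <- if (is.null(fixed_design)) {
    matrix(1, length(obs), 1, dimnames = list(grm$ids[obs], "(Intercept)"))
  } else {
    if (is.null(rownames(fixed_design))) stop_config("fixed_design needs rownames")
    fixed_design[grm$ids[obs], , drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_config("fixed-effect design is rank deficient; aliased column(s): %s",
                paste(aliased, collapse = ", "))
  }
  yo <- y[obs]
  if (sigma_g2 == 0) { # no genetic variance: BLUE only, all gebv zero
    b <- qr.coef(qrX, yo)
    gebv <- stats::setNames(rep(0, n), grm$ids)
    resid <- yo - as.vector(X %*% b)
    return(structure(
      list(fixed = b, gebv = gebv, residuals = stats::setNames(resid, grm$ids[obs]),
           mu = if (ncol(X) == 1L) unname(b[1]) else NA_real_,
           y = y, obs = obs, X = X, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
      class = "gblup_fit"
    ))
  }
  Ginv <- solve(grm$matrix)
  k <- sigma_e2 / sigma_g2
  p <- ncol(X)
  ## MME coefficient matrix; Z is the 0/1 incidence of records on animals
  XtX <- crossprod(X)
  XtZ <- matrix(0, p, n)
  XtZ[, obs] <- t(X)
  ZtZ <- matrix(0, n, n)
  ZtZ[cbind(obs, obs)] <- 1
  C <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ + k * Ginv))
  rhs <- c(crossprod(X, yo), stats::setNames(replace(rep(0, n), obs, yo), NULL))
  sol <- solve(C, rhs)
  b <- stats::setNames(sol[seq_len(p)], colnames(X))
  gebv <- stats::setNames(sol[-seq_len(p)], grm$ids)
  resid <- yo - as.vector(X %*% b) - gebv[obs]
  structure(
    list(fixed = b, gebv = gebv,
         residuals = stats::setNames(resid, grm$ids[obs]),
         mu = if (ncol(X) == 1L) unname(b[1]) else NA_real_,
         y = y, obs = obs, X = X, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
    class = "gblup_fit"
  )
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("GBLUP fit: %d phenotyped of %d animals, sigma_g2 = %.3g, sigma_e2 = %.3g\n",
              length(x$obs), length(x$gebv), x$sigma_g2, x$sigma_e2))
  cat(sprintf("  fixed effects: %d column(s); gebv sd = %.3f\n",
              ncol(x$X), stats::sd(x$gebv)))
  invisible(x)
}

#' @export
coef.gblup_fit <- function(object, ...) object$fixed

#' @export
fitted.gblup_fit <- function(object, ...) {
  as.vector(object$X %*% object$fixed) + object$gebv[object$obs]
}

#' @export
residuals.gblup_fit <- function(object, ...) object$residuals

#' Adjusted phenotypes (ghat + ehat)
#'
#' The phenotype with the fitted fixed part removed:
#' y_adj = ghat + ehat = y - X bhat for every phenotyped animal. Used as the
#' validation response when true breeding values are unknown.
#'
#' @param fit a `gblup_fit` (typically from a model with fixed effects, e.g.
#'   the one embedded in [estimate_varcomp()]).
#' @return named numeric vector over phenotyped animals.
#' @export
adjusted_phenotypes <- function(fit) {
  stopifnot(inherits(fit, "gblup_fit"))
  fit$gebv[fit$obs] + fit$residuals
}
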