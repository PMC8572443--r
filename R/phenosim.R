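#' Select candidate QTLs from the dense panel
#'
#' QTLs are sampled uniformly without replacement from SNPs that are on the
#' dense panel but *not* on the sparse LD panel and whose minor allele
#' frequency exceeds `maf_min`, so that markers used for prediction never
#' coincide with causal loci.
#'
#' @param panel a `genotype_panel` with an LD mask set.
#' @param n_qtl number of QTLs.
#' @param maf_min minimum MAF of a candidate QTL (default 0.05, strictly
#'   exceeded).
#' @param h2 optional QTL heritability carried as metadata and used as the
#'   default by [simulate_trait()].
#' @param scenario_id optional label.
#' @param seed optional seed.
#' @return an object of class `qtl_architecture` with effects unset.
#' @export
select_qtl <- function(panel, n_qtl, maf_min = 0.05, h2 = NULL,
                       scenario_id = NULL, seed = NULL) {
  stopifnot(n_qtl >= 1)
  if (!is.null(h2) && (h2 <= 0 || h2 > 1)) stop_config("h2 must be in (0, 1]")
  pool <- which(!panel$ld_mask & panel_maf(panel) > maf_min)
  if (length(pool) < n_qtl) {
    stop_config("select_qtl: only %d candidate QTLs (non-LD-panel SNPs with MAF > %g), need %d",
                length(pool), maf_min, n_qtl)
  }
  with_seed(seed, {
    idx <- if (length(pool) == n_qtl) pool else sort(sample(pool, n_qtl))
    structure(
      list(qtl_indices = idx, effects = NULL, n_qtl = as.integer(n_qtl),
           h2 = h2, scenario_id = scenario_id),
      class = "qtl_architecture"
    )
  })
}

#' Draw allele-substitution effects for a QTL architecture
#'
#' Effect magnitudes are i.i.d. gamma (default shape 0.4, scale 1.66, so a
#' few QTLs are large and most are small); signs are independent fair coin
#' flips applied after the gamma draw.
#'
#' @param arch a `qtl_architecture`.
#' @param shape,scale gamma parameters for the effect magnitudes.
#' @param seed optional seed.
#' @return the architecture with `effects` set.
#' @export
sample_effects <- function(arch, shape = 0.4, scale = 1.66, seed = NULL) {
  stopifnot(inherits(arch, "qtl_architecture"), arch$n_qtl >= 1)
  with_seed(seed, {
    mag <- stats::rgamma(arch$n_qtl, shape = shape, scale = scale)
    sgn <- sample(c(-1, 1), arch$n_qtl, replace = TRUE)
    arch$effects <- mag * sgn
    arch
  })
}

#' Simulate a quantitative trait from a QTL architecture
#'
#' The true breeding value of animal i is the dosage-weighted sum of QTL
#' effects. Effects are rescaled multiplicatively so the empirical variance
#' of the TBVs equals exactly `100 * h2`; residuals are i.i.d. normal with
#' variance `100 * (1 - h2)`, i.e. `sigma_g2 * (1/h2 - 1)` at the
#' post-rescaling genetic variance. The phenotypic variance is therefore set
#' to 100 in expectation with the genetic part exact.
#'
#' @param panel a `genotype_panel` covering all QTL indices.
#' @param arch a `qtl_architecture` with effects set.
#' @param h2 QTL heritability in (0, 1]; defaults to `arch$h2`.
#' @param seed optional seed.
#' @return an object of class `trait_realization` with elements
#'   `animal_ids`, `tbv`, `residuals`, `phenotypes`, `sigma_g2`, `sigma_e2`,
#'   `h2`, and the rescaled architecture.
#' @export
simulate_trait <- function(panel, arch, h2 = arch$h2, seed = NULL) {
  stopifnot(inherits(arch, "qtl_architecture"))
  if (is.null(arch$effects)) stop_config("simulate_trait: effects not set")
  if (is.null(h2) || h2 <= 0 || h2 > 1) stop_config("h2 must be in (0, 1]")
  if (max(arch$qtl_indices) > n_snps(panel)) {
    stop_config("panel does not cover all QTL indices")
  }
  with_seed(seed, {
    W <- panel$dosages[, arch$qtl_indices, drop = FALSE]
    storage.mode(W) <- "double"
    if (anyNA(W)) { # mean-impute at 2p (simulated panels normally have none)
      p2 <- colMeans(W, na.rm = TRUE)
      for (j in which(colSums(is.na(W)) > 0)) W[is.na(W[, j]), j] <- p2[j]
    }
    tbv <- as.vector(W %*% arch$effects)
    v <- stats::var(tbv)
    if (v <= 0) {
      stop_config("simulate_trait: zero TBV variance (all QTLs monomorphic?)")
    }
    k <- sqrt(100 * h2 / v)
    arch$effects <- arch$effects * k
    arch$h2 <- h2
    tbv <- tbv * k
    sigma_g2 <- 100 * h2
    sigma_e2 <- 100 * (1 - h2)
    res <- if (sigma_e2 > 0) stats::rnorm(length(tbv), 0, sqrt(sigma_e2)) else
      numeric(length(tbv))
    structure(
      list(animal_ids = panel$animal_ids, tbv = tbv, residuals = res,
           phenotypes = tbv + res, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
           h2 = h2, architecture = arch, fixed_part = NULL),
      class = "trait_realization"
    )
  })
}

#' @export
print.trait_realization <- function(x, ...) {
  cat(sprintf("Trait realization: %d animals, h2 = %.2f (var TBV = %.2f, sigma_e2 = %.2f)\n",
              length(x$tbv), x$h2, stats::var(x$tbv), x$sigma_e2))
  if (!is.null(x$fixed_part)) cat("  includes simulated fixed effects\n")
  invisible(x)
}

#' Simulate carcass-style covariates and fixed effects
#'
#' Builds a covariate table emulating the recording structure of a national
#' beef-carcass dataset: feedlot prefecture (18 classes), sex (2 classes),
#' slaughter year (13 classes) and age at slaughter in months (used as
#' centred linear and quadratic covariates). Class effects are drawn once
#' from normal distributions whose spread is a few trait SD units, so fixed
#' effects explain a visible share of phenotypic variance.
#'
#' @param animal_ids character vector of ids.
#' @param n_prefecture,n_sex,n_year numbers of classes.
#' @param age_range age range in months (uniform).
#' @param seed optional seed.
#' @return a data.frame (`animal_id`, `prefecture`, `sex`, `year`, `age`)
#'   with the realised per-animal fixed part in `attr(, "fixed_part")`.
#' @export
simulate_covariates <- function(animal_ids, n_prefecture = 18L, n_sex = 2L,
                                n_year = 13L, age_range = c(24, 36),
                                seed = NULL) {
  n <- length(animal_ids)
  with_seed(seed, {
    pref <- factor(sample.int(n_prefecture, n, replace = TRUE),
                   levels = seq_len(n_prefecture))
    sex <- factor(sample.int(n_sex, n, replace = TRUE), levels = seq_len(n_sex))
    year <- factor(sample.int(n_year, n, replace = TRUE), levels = seq_len(n_year))
    age <- stats::runif(n, age_range[1], age_range[2])
    eff_pref <- stats::rnorm(n_prefecture, 0, 3)
    eff_sex <- c(0, 4)[seq_len(n_sex)]
    eff_year <- stats::rnorm(n_year, 0, 2)
    age_c <- age - mean(age)
    fixed <- eff_pref[pref] + eff_sex[sex] + eff_year[year] +
      0.8 * age_c - 0.05 * age_c^2
    out <- data.frame(animal_id = animal_ids, prefecture = pref, sex = sex,
                      year = year, age = age, stringsAsFactors = FALSE)
    attr(out, "fixed_part") <- fixed
    out
  })
}

#' Add simulated fixed effects to a trait realization
#'
#' @param trait a `trait_realization`.
#' @param covariates output of [simulate_covariates()] for the same animals.
#' @return the trait with `phenotypes = fixed + tbv + residuals` and the
#'   fixed part stored.
#' @export
add_fixed_effects <- function(trait, covariates) {
  stopifnot(inherits(trait, "trait_realization"))
  fixed <- attr(covariates, "fixed_part")
  if (is.null(fixed) || length(fixed) != length(trait$tbv)) {
    stop_config("covariates do not match the trait's animals")
  }
  trait$fixed_part <- fixed
  trait$phenotypes <- fixed + trait$tbv + trait$residuals
  trait
}

#' Fixed-effect design matrix for the carcass-style model
#'
#' Full-rank treatment coding (first level as reference) for prefecture, sex
#' and slaughter year, plus centred linear and quadratic age covariates.
#'
#' @param covariates a covariate data.frame as from [simulate_covariates()]
#'   (columns `prefecture`, `sex`, `year`, `age`).
#' @return a numeric design matrix with an intercept, rownames = animal ids.
#' @export
make_fixed_design <- function(covariates) {
  stopifnot(all(c("prefecture", "sex", "year", "age") %in% names(covariates)))
  d <- covariates
  d$age_c <- d$age - mean(d$age)
  X <- stats::model.matrix(~ prefecture + sex + year + age_c + I(age_c^2),
                           data = d)
  rownames(X) <- as.character(covariates$animal_id)
  X
}
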