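#' Binned linkage-disequilibrium profile
#'
#' Computes r-squared (squared Pearson correlation of dosage vectors) for
#' all intra-chromosomal SNP pairs closer than `max_dist_bp`, averages it in
#' half-open distance bins of width `bin_bp` ([0, bin), [bin, 2 bin), ...;
#' a pair at exactly one bin width falls in the second bin), per chromosome,
#' and then averages the bins across chromosomes without weighting.
#' Monomorphic SNPs are skipped. The short-range profile of routine use is
#' the default (50-kb bins to 1 Mb); long-range profiles for effective-size
#' estimation use wide bins to tens of Mb with `thin_step` > 1 to keep the
#' pair count manageable.
#'
#' @param panel a `genotype_panel`.
#' @param max_dist_bp maximum pair distance in bp (default 1e6).
#' @param bin_bp bin width in bp (default 5e4).
#' @param ld_panel_only restrict to the sparse LD panel.
#' @param thin_step keep every `thin_step`-th SNP (per chromosome) before
#'   pairing; 1 keeps all.
#' @return an object of class `ld_profile`: `bin_edges` (length bins + 1),
#'   `mean_r2` (across-chromosome means), `mean_r2_by_chrom`, `n_pairs`
#'   (bins x chromosomes), `bin_bp`, `max_dist_bp`.
#' @export
ld_profile <- function(panel, max_dist_bp = 1e6, bin_bp = 5e4,
                       ld_panel_only = FALSE, thin_step = 1L) {
  chrs <- unique(panel$map$chr)
  nb <- as.integer(ceiling(max_dist_bp / bin_bp))
  s_mat <- matrix(0, nb, length(chrs))
  n_mat <- matrix(0, nb, length(chrs))
  for (ci in seq_along(chrs)) {
    sel <- panel$map$chr == chrs[ci]
    if (ld_panel_only) sel <- sel & panel$ld_mask
    idx <- which(sel)
    if (thin_step > 1L) idx <- idx[seq(1L, length(idx), by = thin_step)]
    if (length(idx) < 2L) next
    W <- panel$dosages[, idx, drop = FALSE]
    storage.mode(W) <- "double"
    p <- colMeans(W, na.rm = TRUE) / 2
    poly <- p > 0 & p < 1
    if (sum(poly) < 2L) next
    W <- W[, poly, drop = FALSE]
    pos <- panel$map$pos[idx][poly]
    if (anyNA(W)) { # mean-impute before correlating
      for (j in which(colSums(is.na(W)) > 0)) {
        W[is.na(W[, j]), j] <- mean(W[, j], na.rm = TRUE)
      }
    }
    Ws <- scale(W)
    n_an <- nrow(Ws)
    m <- ncol(Ws)
    blk <- 256L
    i <- 1L
    while (i <= m - 1L) {
      j <- min(i + blk - 1L, m)
      jmax <- j
      while (jmax < m && pos[jmax + 1L] - pos[j] < max_dist_bp) jmax <- jmax + 1L
      R <- crossprod(Ws[, i:j, drop = FALSE], Ws[, i:jmax, drop = FALSE]) /
        (n_an - 1)
      d <- outer(pos[i:j], pos[i:jmax], function(a, b) b - a)
      ok <- d > 0 & d < max_dist_bp &
        outer(i:j, i:jmax, function(a, b) b > a)
      if (any(ok)) {
        bins <- d[ok] %/% bin_bp + 1L
        acc <- rowsum(cbind(R[ok]^2, 1), group = bins)
        bi <- as.integer(rownames(acc))
        s_mat[bi, ci] <- s_mat[bi, ci] + acc[, 1]
        n_mat[bi, ci] <- n_mat[bi, ci] + acc[, 2]
      }
      i <- j + 1L
    }
  }
  by_chrom <- s_mat / ifelse(n_mat > 0, n_mat, NA)
  mean_r2 <- rowMeans(by_chrom, na.rm = TRUE)
  mean_r2[is.nan(mean_r2)] <- NA_real_
  structure(
    list(bin_edges = seq(0, nb * bin_bp, by = bin_bp),
         mean_r2 = mean_r2, mean_r2_by_chrom = by_chrom, n_pairs = n_mat,
         bin_bp = bin_bp, max_dist_bp = max_dist_bp),
    class = "ld_profile"
  )
}

#' @export
print.ld_profile <- function(x, ...) {
  nb <- length(x$mean_r2)
  cat(sprintf("LD profile: %d bins of %g kb (to %g Mb), %d pairs\n",
              nb, x$bin_bp / 1e3, x$max_dist_bp / 1e6, sum(x$n_pairs)))
  show <- utils::head(which(!is.na(x$mean_r2)), 5)
  for (b in show) {
    cat(sprintf("  [%g, %g) kb: mean r2 = %.3f\n",
                x$bin_edges[b] / 1e3, x$bin_edges[b + 1] / 1e3, x$mean_r2[b]))
  }
  invisible(x)
}

#' @export
plot.ld_profile <- function(x, ...) {
  mid <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(mid / 1e6, x$mean_r2, type = "b", pch = 19,
                 xlab = "distance (Mb)", ylab = expression(mean ~ r^2), ...)
  invisible(x)
}

#' Effective population size from long-range LD
#'
#' For each t in `t_values`, the chromosome-segment length is c = 1/(2t)
#' morgans and the effective size t generations ago is
#' N_t = (1/r2 - 1) / (4c), with r2 read from the profile bin whose midpoint
#' (converted to morgans with `cm_per_mb`) is nearest to c. The estimate Ne
#' is the arithmetic mean of the N_t. The distance-to-morgan map is a
#' configurable constant because array data carry no genetic map; 1 cM/Mb is
#' the conventional cattle average.
#'
#' @param profile an [ld_profile()] covering the required distances (for
#'   t = 1 and 1 cM/Mb, 50 Mb).
#' @param t_values generations ago (default 1:5).
#' @param cm_per_mb genetic-map constant (default 1).
#' @param genome_length genome length in morgans carried as metadata for the
#'   downstream [me_from_ne()] step.
#' @return an object of class `ne_estimate`: `per_t` (t, c, r2, Nt), `ne`,
#'   `genome_length`, `cm_per_mb`.
#' @export
ne_from_ld <- function(profile, t_values = 1:5, cm_per_mb = 1,
                       genome_length = 31.6) {
  stopifnot(inherits(profile, "ld_profile"))
  mid <- (profile$bin_edges[-1] +
            profile$bin_edges[-length(profile$bin_edges)]) / 2
  per_t <- data.frame(t = t_values, c = 1 / (2 * t_values),
                      r2 = NA_real_, Nt = NA_real_)
  for (k in seq_along(t_values)) {
    cc <- per_t$c[k]
    target_bp <- cc * 1e8 / cm_per_mb # morgans -> bp under the linear map
    if (target_bp > profile$bin_edges[length(profile$bin_edges)]) {
      stop_config("ne_from_ld: profile does not cover c = %.3f M (%.1f Mb); extend max_dist_bp",
                  cc, target_bp / 1e6)
    }
    b <- which.min(abs(mid - target_bp))
    r2 <- profile$mean_r2[b]
    per_t$r2[k] <- r2
    if (is.na(r2) || r2 <= 0) {
      warning(sprintf("t = %d: r2 missing or zero in the matched bin; excluded",
                      t_values[k]))
    } else {
      per_t$Nt[k] <- (1 / r2 - 1) / (4 * cc)
    }
  }
  structure(
    list(per_t = per_t, ne = mean(per_t$Nt, na.rm = TRUE),
         genome_length = genome_length, cm_per_mb = cm_per_mb),
    class = "ne_estimate"
  )
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Effective population size from LD: Ne = %.1f (mean over t = %s)\n",
              x$ne, paste(x$per_t$t, collapse = ",")))
  print(x$per_t, row.names = FALSE)
  invisible(x)
}
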