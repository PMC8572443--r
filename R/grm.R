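#' VanRaden genomic relationship matrix
#'
#' G = ZZ' / sum_j 2 p_j (1 - p_j), where Z has columns w_ij - 2 p_j (w_ij
#' the A2 dosage, p_j the current-sample A2 frequency). Missing dosages are
#' mean-imputed at 2 p_j before centring, so they contribute zero. A small
#' constant is added to the diagonal to keep the matrix comfortably positive
#' definite.
#'
#' @param panel a `genotype_panel`.
#' @param use_ld_panel_only build G from the sparse LD panel only (the
#'   default, matching routine evaluation on the low-density array).
#' @param jitter value added to every diagonal element (default 1e-5).
#' @return an object of class `grm`: `matrix` (with jitter applied), `ids`,
#'   `jitter`, `n_snps_used`.
#' @export
compute_grm <- function(panel, use_ld_panel_only = TRUE, jitter = 1e-5) {
  sel <- if (use_ld_panel_only) which(panel$ld_mask) else seq_len(n_snps(panel))
  if (!length(sel)) stop_config("compute_grm: no SNPs selected")
  W <- panel$dosages[, sel, drop = FALSE]
  storage.mode(W) <- "double"
  p <- colMeans(W, na.rm = TRUE) / 2
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop_config("compute_grm: all selected SNPs are monomorphic")
  Z <- sweep(W, 2L, 2 * p)
  if (anyNA(Z)) Z[is.na(Z)] <- 0 # missing = mean-imputed at 2p after centring
  G <- tcrossprod(Z) / denom
  diag(G) <- diag(G) + jitter
  dimnames(G) <- list(panel$animal_ids, panel$animal_ids)
  structure(
    list(matrix = G, ids = panel$animal_ids, jitter = jitter,
         n_snps_used = length(sel)),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d animals, %d SNPs, diagonal mean %.3f (jitter %g)\n",
              nrow(x$matrix), x$n_snps_used, mean(diag(x$matrix)), x$jitter))
  invisible(x)
}

#' Subset a GRM to a set of animals
#' @param grm a `grm`.
#' @param ids animal ids or indices to keep.
#' @export
subset_grm <- function(grm, ids) {
  idx <- if (is.character(ids)) match(ids, grm$ids) else ids
  if (anyNA(idx)) stop_config("subset_grm: unknown ids")
  structure(
    list(matrix = grm$matrix[idx, idx, drop = FALSE], ids = grm$ids[idx],
         jitter = grm$jitter, n_snps_used = grm$n_snps_used),
    class = "grm"
  )
}

#' Write / read a GRM
#'
#' `format = "gcta"` writes the GCTA binary triple (`.grm.bin` float lower
#' triangle including the diagonal, `.grm.N.bin` per-pair SNP counts,
#' `.grm.id` two-column id file); the stored matrix (jitter included) is
#' written as-is. `format = "tsv"` writes a plain long-format table
#' (id1, id2, value) of the lower triangle.
#'
#' @param grm a `grm`.
#' @param prefix file prefix (extensions are appended).
#' @param format "gcta" or "tsv".
#' @export
write_grm <- function(grm, prefix, format = c("gcta", "tsv")) {
  format <- match.arg(format)
  G <- grm$matrix
  n <- nrow(G)
  if (format == "gcta") {
    ## GCTA order: row-major over pairs (i, j <= i), diagonal included
    vals <- unlist(lapply(seq_len(n), function(i) G[i, seq_len(i)]))
    con <- file(paste0(prefix, ".grm.bin"), "wb")
    writeBin(as.numeric(vals), con, size = 4L)
    close(con)
    con <- file(paste0(prefix, ".grm.N.bin"), "wb")
    writeBin(rep(as.numeric(grm$n_snps_used), length(vals)), con, size = 4L)
    close(con)
    utils::write.table(data.frame(fid = grm$ids, iid = grm$ids),
                       paste0(prefix, ".grm.id"), quote = FALSE,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  } else {
    ij <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
    utils::write.table(
      data.frame(id1 = grm$ids[ij[, 1]], id2 = grm$ids[ij[, 2]],
                 value = G[ij]),
      paste0(prefix, ".grm.tsv"), quote = FALSE, sep = "\t", row.names = FALSE
    )
  }
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix, format = c("gcta", "tsv")) {
  format <- match.arg(format)
  if (format == "gcta") {
    ids <- utils::read.table(paste0(prefix, ".grm.id"),
                             stringsAsFactors = FALSE)[[2]]
    n <- length(ids)
    npair <- n * (n + 1) / 2
    con <- file(paste0(prefix, ".grm.bin"), "rb")
    vals <- readBin(con, "numeric", n = npair, size = 4L)
    close(con)
    con <- file(paste0(prefix, ".grm.N.bin"), "rb")
    nsnp <- readBin(con, "numeric", n = npair, size = 4L)
    close(con)
    G <- matrix(0, n, n)
    k <- 1L
    for (i in seq_len(n)) {
      G[i, seq_len(i)] <- vals[k:(k + i - 1L)]
      k <- k + i
    }
    G[upper.tri(G)] <- t(G)[upper.tri(G)]
    dimnames(G) <- list(ids, ids)
    structure(list(matrix = G, ids = ids, jitter = NA_real_,
                   n_snps_used = as.integer(nsnp[1])), class = "grm")
  } else {
    d <- utils::read.table(paste0(prefix, ".grm.tsv"), header = TRUE,
                           stringsAsFactors = FALSE)
    ids <- unique(c(d$id1, d$id2))
    n <- length(ids)
    G <- matrix(0, n, n, dimnames = list(ids, ids))
    G[cbind(match(d$id1, ids), match(d$id2, ids))] <- d$value
    G[upper.tri(G)] <- t(G)[upper.tri(G)]
    structure(list(matrix = G, ids = ids, jitter = NA_real_,
                   n_snps_used = NA_integer_), class = "grm")
  }
}
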