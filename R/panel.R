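#' Genotype panel container
#'
#' A `genotype_panel` holds an animals-by-SNPs dosage matrix (counts of the
#' A2 allele, coded 0/1/2 with `NA` for missing), a SNP map (chromosome,
#' 1-based bp position, allele labels), a logical mask flagging membership in
#' the sparse "LD" genotyping panel nested inside the dense panel, and the
#' per-SNP A2 allele frequencies (always recomputed from the dosages, so the
#' stored values can never drift from the data). Phased haplotypes, when the
#' panel came out of the simulator, ride along so the population can be
#' evolved further.
#'
#' @param dosages integer matrix, animals x SNPs, entries in \{0, 1, 2, NA\}.
#' @param map data.frame with columns `snp_id`, `chr`, `pos`, `a1`, `a2`;
#'   positions must be strictly increasing within each chromosome.
#' @param ld_mask logical vector flagging SNPs in the sparse LD panel.
#' @param animal_ids character vector of animal identifiers.
#' @param haplotypes optional list (one entry per chromosome) of phased 0/1
#'   haplotype matrices with 2 rows per animal.
#' @return an object of class `genotype_panel`.
#' @export
new_genotype_panel <- function(dosages, map, ld_mask = NULL,
                               animal_ids = NULL, haplotypes = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(map) != ncol(dosages)) {
    stop_config("map has %d SNPs but dosages has %d columns",
                nrow(map), ncol(dosages))
  }
  need <- c("snp_id", "chr", "pos", "a1", "a2")
  if (!all(need %in% names(map))) {
    stop_config("map must have columns %s", paste(need, collapse = ", "))
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop_config("dosages must be 0, 1, 2 or NA")
  }
  for (cc in unique(map$chr)) {
    p <- map$pos[map$chr == cc]
    if (any(diff(p) <= 0)) {
      stop_config("positions not strictly increasing on chromosome %s", cc)
    }
  }
  if (is.null(animal_ids)) {
    animal_ids <- rownames(dosages) %||% sprintf("an%05d", seq_len(nrow(dosages)))
  }
  if (anyDuplicated(animal_ids)) stop_config("duplicated animal ids")
  if (is.null(ld_mask)) ld_mask <- rep(FALSE, ncol(dosages))
  stopifnot(length(ld_mask) == ncol(dosages))
  dimnames(dosages) <- list(animal_ids, map$snp_id)
  structure(
    list(
      dosages = dosages,
      map = map,
      ld_mask = as.logical(ld_mask),
      animal_ids = as.character(animal_ids),
      allele_freqs = unname(colMeans(dosages, na.rm = TRUE) / 2),
      haplotypes = haplotypes
    ),
    class = "genotype_panel"
  )
}

#' Number of animals / SNPs in a panel
#' @param panel a `genotype_panel`.
#' @export
n_animals <- function(panel) nrow(panel$dosages)

#' @rdname n_animals
#' @export
n_snps <- function(panel) ncol(panel$dosages)

#' A2 allele frequencies of a panel
#'
#' Recomputed from the dosage matrix (missing entries excluded).
#' @param panel a `genotype_panel`.
#' @return numeric vector of per-SNP A2 frequencies.
#' @export
allele_freqs <- function(panel) {
  unname(colMeans(panel$dosages, na.rm = TRUE) / 2)
}

#' Minor allele frequencies of a panel
#' @param panel a `genotype_panel`.
#' @export
panel_maf <- function(panel) {
  p <- allele_freqs(panel)
  pmin(p, 1 - p)
}

#' Per-SNP and per-animal genotype call rates
#' @param panel a `genotype_panel`.
#' @export
snp_call_rates <- function(panel) unname(colMeans(!is.na(panel$dosages)))

#' @rdname snp_call_rates
#' @export
animal_call_rates <- function(panel) unname(rowMeans(!is.na(panel$dosages)))

#' Subset a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @param animals indices, logical mask or ids of animals to keep.
#' @param snps indices or logical mask of SNPs to keep.
#' @return a new `genotype_panel` (allele frequencies recomputed; phased
#'   haplotypes do not survive subsetting and are dropped).
#' @export
subset_panel <- function(panel, animals = NULL, snps = NULL) {
  ai <- seq_len(n_animals(panel))
  si <- seq_len(n_snps(panel))
  if (!is.null(animals)) {
    ai <- if (is.character(animals)) match(animals, panel$animal_ids) else ai[animals]
    if (anyNA(ai)) stop_config("unknown animal ids in subset")
  }
  if (!is.null(snps)) si <- si[snps]
  new_genotype_panel(panel$dosages[ai, si, drop = FALSE],
                     panel$map[si, , drop = FALSE],
                     ld_mask = panel$ld_mask[si],
                     animal_ids = panel$animal_ids[ai])
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", n_animals(x), "animals x", n_snps(x), "SNPs on",
      length(unique(x$map$chr)), "chromosome(s)\n")
  cat("  LD-panel SNPs:", sum(x$ld_mask),
      sprintf("(%.1f%%)", 100 * mean(x$ld_mask)), "\n")
  cat("  missing dosages:", sum(is.na(x$dosages)), "\n")
  mafs <- panel_maf(x)
  cat(sprintf("  MAF: mean %.3f, %d monomorphic\n",
              mean(mafs, na.rm = TRUE), sum(mafs == 0, na.rm = TRUE)))
  invisible(x)
}
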