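#' QC report constructor
#' @noRd
new_qc_report <- function(n_snps_in, n_snps_out, n_animals_in, n_animals_out,
                          removals) {
  structure(
    list(n_snps_in = n_snps_in, n_snps_out = n_snps_out,
         n_animals_in = n_animals_in, n_animals_out = n_animals_out,
         removals = removals),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: animals %d -> %d, SNPs %d -> %d\n",
              x$n_animals_in, x$n_animals_out, x$n_snps_in, x$n_snps_out))
  if (nrow(x$removals)) print(table(x$removals$reason))
  invisible(x)
}

.removal_df <- function(id = character(), axis = character(),
                        reason = character()) {
  id <- as.character(id)
  if (!length(id)) {
    return(data.frame(id = character(), axis = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  data.frame(id = id, axis = axis, reason = reason, stringsAsFactors = FALSE)
}

#' Remove animals with low genotype call rate
#'
#' @param panel a `genotype_panel`.
#' @param min_rate minimum fraction of non-missing genotypes (default 0.95);
#'   animals strictly below it are removed.
#' @return list with the filtered `panel` and a `qc_report`.
#' @export
filter_animals_by_call_rate <- function(panel, min_rate = 0.95) {
  if (n_animals(panel) == 0L) stop_config("empty panel")
  cr <- animal_call_rates(panel)
  drop <- cr < min_rate
  if (all(drop)) stop_config("call-rate filter would remove every animal")
  rep <- new_qc_report(n_snps(panel), n_snps(panel),
                       n_animals(panel), sum(!drop),
                       .removal_df(panel$animal_ids[drop], "animal", "call_rate"))
  panel <- if (any(drop)) subset_panel(panel, animals = !drop) else panel
  list(panel = panel, report = rep)
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom asymptotic chi-square goodness-of-fit of observed
#' genotype counts against expectations from the observed allele frequency
#' (no continuity correction). Vectorised over counts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-values.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n <= 0)) stop_config("hwe_test: total genotype count must be > 0")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  eAA <- n * p^2; eAa <- 2 * n * p * q; eaa <- n * q^2
  stat <- numeric(length(n))
  poly <- eAa > 0 # monomorphic SNPs fit trivially (statistic 0)
  stat[poly] <- (n_AA[poly] - eAA[poly])^2 / eAA[poly] +
    (n_Aa[poly] - eAa[poly])^2 / eAa[poly] +
    (n_aa[poly] - eaa[poly])^2 / eaa[poly]
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' SNP quality control
#'
#' Keeps a SNP iff MAF >= `maf_min`, call rate >= `call_rate_min` and HWE
#' p-value >= `hwe_p_min`, all computed on the panel's current animal set.
#' Each removed SNP gets one primary reason, assessed in the order
#' maf, call_rate, hwe.
#'
#' @param panel a `genotype_panel`.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param call_rate_min minimum SNP call rate (default 0.95).
#' @param hwe_p_min minimum HWE p-value (default 1e-3).
#' @return list with the filtered `panel` and a `qc_report`.
#' @export
filter_snps <- function(panel, maf_min = 0.01, call_rate_min = 0.95,
                        hwe_p_min = 1e-3) {
  if (n_snps(panel) == 0L) stop_config("empty panel")
  maf <- panel_maf(panel)
  cr <- snp_call_rates(panel)
  W <- panel$dosages
  nAA <- colSums(W == 0L, na.rm = TRUE)
  nAa <- colSums(W == 1L, na.rm = TRUE)
  naa <- colSums(W == 2L, na.rm = TRUE)
  hwe_p <- hwe_test(nAA, nAa, naa)
  fail_maf <- is.na(maf) | maf < maf_min
  fail_cr <- cr < call_rate_min
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_maf | fail_cr | fail_hwe)
  if (!any(keep)) stop_config("SNP QC would remove every SNP")
  reason <- ifelse(fail_maf, "maf", ifelse(fail_cr, "call_rate", "hwe"))
  rep <- new_qc_report(n_snps(panel), sum(keep),
                       n_animals(panel), n_animals(panel),
                       .removal_df(panel$map$snp_id[!keep], "snp", reason[!keep]))
  list(panel = subset_panel(panel, snps = keep), report = rep)
}

#' Prune close relatives from a GRM
#'
#' Iteratively removes animals until no off-diagonal relationship among the
#' kept animals exceeds `cutoff`. At each step the animal involved in the
#' most violating pairs is removed; ties are broken by the lowest position in
#' `grm$ids` (a fixed, documented rule - the removal order is otherwise
#' arbitrary).
#'
#' @param grm a [compute_grm()] result.
#' @param cutoff maximum allowed off-diagonal relationship (default 0.4).
#' @return list with `kept_ids` and a `qc_report`.
#' @export
prune_related <- function(grm, cutoff = 0.4) {
  G <- grm$matrix
  if (!isTRUE(all.equal(G, t(G), tolerance = 1e-8))) {
    stop_config("prune_related: GRM is not symmetric")
  }
  n <- nrow(G)
  A <- G > cutoff
  diag(A) <- FALSE
  deg <- rowSums(A)
  keep <- rep(TRUE, n)
  while (TRUE) {
    mx <- max(deg[keep], 0L)
    if (mx == 0) break
    drop <- which(keep & deg == mx)[1L] # ties: lowest index in grm$ids
    keep[drop] <- FALSE
    nb <- which(A[drop, ] & keep)
    deg[nb] <- deg[nb] - 1L
    deg[drop] <- 0L
  }
  rep <- new_qc_report(NA_integer_, NA_integer_, n, sum(keep),
                       .removal_df(grm$ids[!keep], "animal", "relatedness"))
  list(kept_ids = grm$ids[keep], report = rep)
}

#' Trim multi-trait phenotype outliers
#'
#' Removes an animal if any trait value lies strictly outside
#' mean +/- `n_sd` * SD, with means and SDs computed once on the input table
#' (a single pass, not re-iterated). Zero-variance traits are skipped with a
#' warning and cause no removals.
#'
#' @param table data.frame with an `animal_id` column and numeric trait
#'   columns.
#' @param n_sd number of SDs defining the trimming band (default 3).
#' @return list with the trimmed `table` and a `qc_report`.
#' @export
trim_phenotypes <- function(table, n_sd = 3) {
  stopifnot("animal_id" %in% names(table))
  traits <- names(table)[vapply(table, is.numeric, logical(1))]
  traits <- setdiff(traits, "animal_id")
  if (nrow(table) < 2L) stop_config("trim_phenotypes: need >= 2 animals")
  out <- rep(FALSE, nrow(table))
  for (tr in traits) {
    y <- table[[tr]]
    s <- stats::sd(y, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning(sprintf("trait '%s' has zero variance; skipped in trimming", tr))
      next
    }
    m <- mean(y, na.rm = TRUE)
    out <- out | (!is.na(y) & abs(y - m) > n_sd * s)
  }
  rep <- new_qc_report(NA_integer_, NA_integer_, nrow(table), sum(!out),
                       .removal_df(table$animal_id[out], "animal",
                                   "phenotype_outlier"))
  list(table = table[!out, , drop = FALSE], report = rep)
}
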