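## Single-threaded BLAS keeps the linear algebra bit-reproducible and avoids
## thread contention on small machines.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")

## Tiny deterministic panel used across module tests: 2 chromosomes,
## moderate drift, small enough that everything downstream is instant.
tiny_panel <- function(seed = 11L, n_final = 60L) {
  cfg <- sim_config(n_founders = 20L, n_generations = 6L,
                    pop_size_per_gen = 20L, final_expansion = n_final,
                    n_chromosomes = 2L, chrom_length_bp = 1e7,
                    snps_per_chromosome = 150L, seed = seed)
  simulate_population(cfg)
}

## Hand-constructed panel from an explicit dosage matrix.
manual_panel <- function(dosages, chr = NULL, pos = NULL, ld_mask = NULL) {
  m <- ncol(dosages)
  map <- data.frame(
    snp_id = sprintf("s%03d", seq_len(m)),
    chr = chr %||% rep(1L, m),
    pos = pos %||% (seq_len(m) * 1000L),
    a1 = "A", a2 = "B", stringsAsFactors = FALSE
  )
  new_genotype_panel(dosages, map, ld_mask = ld_mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
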