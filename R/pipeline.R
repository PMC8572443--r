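#' Pipeline configuration
#'
#' Collects the parameters of every stage of the end-to-end analysis:
#' genotype simulation, trait-scenario grid, QC thresholds, GRM, nested
#' cross-validation and the deterministic-accuracy fits. Either pass the
#' pieces directly or read them from a YAML file with
#' [read_pipeline_config()]. All stage parameters are validated up front,
#' before any stage runs.
#'
#' @param seed root seed; each stage derives its own stream from it, so
#'   stages re-run reproducibly.
#' @param popsim list of [sim_config()] arguments.
#' @param scenarios list with `h2` and `n_qtl` vectors; the grid of trait
#'   scenarios is their cross product.
#' @param qc list: `maf`, `snp_call_rate`, `ind_call_rate`, `hwe_p`,
#'   `grm_cutoff`.
#' @param grm list: `jitter`.
#' @param crossval list: `n_test`, `ref_sizes`, `n_replicates`.
#' @param detacc list: `bin_bp`, `max_dist_bp`, `ne_bin_bp`,
#'   `ne_max_dist_bp`, `ne_thin_step`, `t_values`, `cm_per_mb`, `curve_n_max`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            popsim = list(),
                            scenarios = list(h2 = c(0.1, 0.3, 0.5),
                                             n_qtl = c(100L, 500L, 2000L)),
                            qc = list(),
                            grm = list(),
                            crossval = list(),
                            detacc = list()) {
  qc_def <- list(maf = 0.01, snp_call_rate = 0.95, ind_call_rate = 0.95,
                 hwe_p = 1e-3, grm_cutoff = 0.4)
  cv_def <- list(n_test = 500L, ref_sizes = c(500L, 1000L, 2000L, 3000L),
                 n_replicates = 10L)
  det_def <- list(bin_bp = 5e4, max_dist_bp = 1e6,
                  ne_bin_bp = 1e6, ne_max_dist_bp = 5.1e7, ne_thin_step = 20L,
                  t_values = 1:5, cm_per_mb = 1, curve_n_max = 50000L)
  pop_full <- do.call(sim_config, popsim[setdiff(names(popsim), "seed")])
  cfg <- list(seed = as.integer(seed),
              popsim = unclass(pop_full)[setdiff(names(pop_full), "seed")],
              scenarios = scenarios,
              qc = utils::modifyList(qc_def, qc),
              grm = utils::modifyList(list(jitter = 1e-5), grm),
              crossval = utils::modifyList(cv_def, crossval),
              detacc = utils::modifyList(det_def, detacc))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' @export
validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  do.call(sim_config, cfg$popsim) # validates the popsim stage
  sc <- cfg$scenarios
  if (!length(sc$h2) || any(sc$h2 <= 0 | sc$h2 > 1)) {
    stop_config("scenarios$h2 must be in (0, 1]")
  }
  if (!length(sc$n_qtl) || any(sc$n_qtl < 1)) {
    stop_config("scenarios$n_qtl must be positive counts")
  }
  cv <- cfg$crossval
  if (any(diff(as.integer(cv$ref_sizes)) <= 0)) {
    stop_config("crossval$ref_sizes must be strictly increasing")
  }
  if (cv$n_test < 1 || cv$n_replicates < 2) {
    stop_config("crossval needs n_test >= 1 and n_replicates >= 2")
  }
  with(cfg$qc, stopifnot(maf >= 0, snp_call_rate <= 1, ind_call_rate <= 1,
                         hwe_p >= 0, grm_cutoff > 0))
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

#' Run the complete analysis pipeline
#'
#' Stages, in order: genotype simulation, QC (animal call rate, SNP QC,
#' GRM-based relatedness pruning), GRM construction, the trait-scenario grid
#' with nested reference/test cross-validation, per-scenario ML fits of
#' (w, Me), LD profiling, Ne-from-LD and Me-from-Ne, and expected-accuracy
#' curves. Writes tidy CSVs plus a JSON run manifest into `out_dir`; outputs
#' are namespaced per stage and inputs are never overwritten.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(k) derive_seed(config$seed, k)

  ## 1. genotypes
  scfg <- do.call(sim_config, c(config$popsim, list(seed = stage(1L))))
  panel <- simulate_population(scfg)

  ## 2. QC
  qc <- config$qc
  reports <- list()
  st <- filter_animals_by_call_rate(panel, qc$ind_call_rate)
  panel <- st$panel; reports$animal_call_rate <- st$report
  st <- filter_snps(panel, qc$maf, qc$snp_call_rate, qc$hwe_p)
  panel <- st$panel; reports$snp_qc <- st$report
  g0 <- compute_grm(panel, jitter = config$grm$jitter)
  pr <- prune_related(g0, qc$grm_cutoff)
  reports$relatedness <- pr$report
  panel <- subset_panel(panel, animals = pr$kept_ids)

  ## 3. GRM on the QC'd panel
  grm <- compute_grm(panel, jitter = config$grm$jitter)

  ## 4. CV design shared by all scenarios
  design <- make_design(panel$animal_ids, config$crossval$n_test,
                        config$crossval$ref_sizes,
                        config$crossval$n_replicates, seed = stage(2L))

  ## 5. scenario grid
  grid <- expand.grid(h2 = config$scenarios$h2,
                      n_qtl = config$scenarios$n_qtl)
  tables <- vector("list", nrow(grid))
  fits <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    lab <- sprintf("h2_%g_nqtl_%d", grid$h2[k], grid$n_qtl[k])
    arch <- select_qtl(panel, grid$n_qtl[k], h2 = grid$h2[k],
                       scenario_id = lab, seed = stage(10L + k))
    arch <- sample_effects(arch, seed = stage(100L + k))
    trait <- simulate_trait(panel, arch, seed = stage(200L + k))
    tables[[k]] <- run_cv_simulated(trait, design, grm)
    fits[[k]] <- fit_w_me(tables[[k]])
  }

  ## 6. LD, Ne, Me
  prof <- ld_profile(panel, config$detacc$max_dist_bp, config$detacc$bin_bp)
  ne <- tryCatch(
    ne_from_ld(
      ld_profile(panel, config$detacc$ne_max_dist_bp, config$detacc$ne_bin_bp,
                 thin_step = config$detacc$ne_thin_step),
      t_values = config$detacc$t_values, cm_per_mb = config$detacc$cm_per_mb,
      genome_length = with(config$popsim,
                           n_chromosomes * chrom_length_bp * recombination_rate)
    ),
    error = function(e) { warning(conditionMessage(e)); NULL }
  )

  ## 7. write results
  acc <- do.call(rbind, lapply(tables, accuracy_long))
  summaries <- do.call(rbind, lapply(tables, function(tb) {
    s <- summary(tb); s$scenario <- tb$scenario; s$h2 <- tb$h2
    s$n_qtl <- tb$n_qtl; s
  }))
  fit_df <- data.frame(
    scenario = vapply(fits, function(f) f$table$scenario, character(1)),
    h2 = grid$h2, n_qtl = grid$n_qtl,
    w = vapply(fits, `[[`, numeric(1), "w"),
    Me = vapply(fits, `[[`, numeric(1), "Me"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik")
  )
  curves <- do.call(rbind, lapply(seq_len(nrow(fit_df)), function(k) {
    cv <- accuracy_curve(fit_df$h2[k], fit_df$w[k], fit_df$Me[k],
                         n_max = config$detacc$curve_n_max, step = 500)
    cv$scenario <- fit_df$scenario[k]
    cv
  }))
  ld_df <- data.frame(bin_start = prof$bin_edges[-length(prof$bin_edges)],
                      bin_end = prof$bin_edges[-1], mean_r2 = prof$mean_r2,
                      n_pairs = rowSums(prof$n_pairs))
  out <- list(accuracies = acc, summaries = summaries, fits = fit_df,
              curves = curves, ld = ld_df)
  if (!is.null(ne)) {
    out$ne <- cbind(ne$per_t,
                    ne = ne$ne,
                    me_from_ne = me_from_ne(ne$ne, L = ne$genome_length))
  }
  write_results(out, out_dir, config)
  qc_df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]$removals
    if (nrow(r)) cbind(stage = nm, r) else NULL
  }))
  if (!is.null(qc_df)) {
    utils::write.table(qc_df, file.path(out_dir, "qc_removals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(panel = panel, grm = grm, design = design, tables = tables,
                 fits = fits, ld = prof, ne = ne, reports = reports,
                 out_dir = out_dir))
}

#' Write result tables and a run manifest
#'
#' Each data.frame in `tables` is written as `<name>.csv` with its column
#' order preserved; `manifest.json` records the configuration, the root
#' seed and package/R versions, which is enough to reproduce every
#' stochastic output bit-identically.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory.
#' @param config the `pipeline_config` used (stored in the manifest).
#' @return file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    seed = if (!is.null(config)) config$seed else NA,
    config = if (!is.null(config)) unclass(config) else NULL,
    package_version = as.character(utils::packageVersion("gpacc")),
    r_version = R.version.string
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, mp))
}
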