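## The desk-scale experiment shared by the acceptance and property tests:
## the default calibrated demography (~5000 animals before QC), the
## 500/1000/2000/3000 nested cross-validation with 10 replicates, five trait
## scenarios (h2 0.1/0.3/0.5 at 100 QTLs; 500 and 2000 QTLs at h2 0.3), the
## per-scenario (w, Me) fits, and the LD-based Ne. Built once per test run
## and cached.
.experiment_cache <- new.env(parent = emptyenv())

desk_experiment <- function() {
  if (!is.null(.experiment_cache$exp)) return(.experiment_cache$exp)
  seed <- 42L

  panel <- simulate_population(sim_config(seed = seed))
  panel <- filter_animals_by_call_rate(panel, 0.95)$panel
  panel <- filter_snps(panel, maf_min = 0.01, call_rate_min = 0.95,
                       hwe_p_min = 1e-3)$panel
  pruned <- prune_related(compute_grm(panel), cutoff = 0.4)
  panel <- subset_panel(panel, animals = pruned$kept_ids)
  grm <- compute_grm(panel)

  design <- make_design(panel$animal_ids, n_test = 500L,
                        ref_sizes = c(500L, 1000L, 2000L, 3000L),
                        n_replicates = 10L, seed = seed + 1L)

  scen <- data.frame(h2 = c(0.1, 0.3, 0.5, 0.3, 0.3),
                     n_qtl = c(100L, 100L, 100L, 500L, 2000L))
  traits <- tables <- fits <- vector("list", nrow(scen))
  for (k in seq_len(nrow(scen))) {
    arch <- select_qtl(panel, scen$n_qtl[k], maf_min = 0.05, h2 = scen$h2[k],
                       scenario_id = sprintf("h2=%g nQTL=%d",
                                             scen$h2[k], scen$n_qtl[k]),
                       seed = seed + 10L + k)
    arch <- sample_effects(arch, seed = seed + 20L + k)
    traits[[k]] <- simulate_trait(panel, arch, seed = seed + 30L + k)
    tables[[k]] <- run_cv_simulated(traits[[k]], design, grm)
    fits[[k]] <- fit_w_me(tables[[k]])
  }

  ## 25-kb bins so the 125-175 kb window is covered exactly by bins 6-7
  prof_short <- ld_profile(panel, max_dist_bp = 1e6, bin_bp = 2.5e4)
  prof_long <- ld_profile(panel, max_dist_bp = 5.1e7, bin_bp = 1e6,
                          thin_step = 20L)
  genome_length_m <- 5 * 1e8 * 1e-8 # 5 chromosomes of 1 morgan
  ne <- ne_from_ld(prof_long, t_values = 1:5, cm_per_mb = 1,
                   genome_length = genome_length_m)

  .experiment_cache$exp <- list(
    panel = panel, grm = grm, design = design, scen = scen, traits = traits,
    tables = tables, fits = fits, prof_short = prof_short,
    prof_long = prof_long, ne = ne, genome_length_m = genome_length_m,
    seed = seed
  )
  .experiment_cache$exp
}

## Smaller companion experiment with fixed effects for the REML /
## adjusted-phenotype / real-style validation path (2000 animals).
real_style_experiment <- function() {
  if (!is.null(.experiment_cache$real)) return(.experiment_cache$real)
  exp <- desk_experiment()
  seed <- 142L
  ids <- exp$panel$animal_ids[seq_len(2000L)]
  panel <- subset_panel(exp$panel, animals = ids)
  grm <- compute_grm(panel)
  arch <- sample_effects(select_qtl(panel, 100L, h2 = 0.4, seed = seed),
                         seed = seed + 1L)
  trait <- simulate_trait(panel, arch, seed = seed + 2L)
  covs <- simulate_covariates(panel$animal_ids, seed = seed + 3L)
  trait <- add_fixed_effects(trait, covs)
  X <- make_fixed_design(covs)
  y <- stats::setNames(trait$phenotypes, panel$animal_ids)
  vc <- estimate_varcomp(y, grm, fixed_design = X)
  y_adj <- adjusted_phenotypes(vc$fit)
  design <- make_design(panel$animal_ids, n_test = 200L,
                        ref_sizes = c(300L, 1000L), n_replicates = 20L,
                        seed = seed + 4L)
  cv <- run_cv_real_style(y_adj, vc$h2, design, grm,
                          sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2)
  .experiment_cache$real <- list(panel = panel, grm = grm, trait = trait,
                                 covariates = covs, X = X, y = y, vc = vc,
                                 y_adj = y_adj, design = design, cv = cv)
  .experiment_cache$real
}
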