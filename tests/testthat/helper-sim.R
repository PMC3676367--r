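# Shared simulation shorthands for the tests.

# One-day observation set under the default scenario.
sim_day_obs <- function(seed, n_genotypes = 192, n_reps = 2,
                        plots_per_row = 16, sigma_g = 0.4, ...) {
  design <- generate_layout(n_genotypes, n_reps, plots_per_row, 8, seed = seed)
  plan <- plan_acquisition(design, seed = seed + 1L)
  scenario <- simulation_scenario(design, n_images = max(plan$capture_index),
                                  sigma_g = sigma_g, seed = seed + 2L, ...)
  list(design = design, plan = plan, scenario = scenario,
       obs = simulate_plot_observations(design, plan, scenario))
}

# Genotype x day matrix of normalised genotype means over n_days.
sim_means_matrix <- function(seed, n_genotypes = 48, n_days = 3, sigma_g = 0.4,
                             ...) {
  design <- generate_layout(n_genotypes, 2, 16, 8, seed = seed)
  plan <- plan_acquisition(design, seed = seed + 1L)
  scenario <- simulation_scenario(design, n_images = max(plan$capture_index),
                                  sigma_g = sigma_g, seed = seed + 2L, ...)
  genotypes <- sort(unique(design$assignments$genotype))
  means <- sapply(seq_len(n_days), function(day) {
    obs <- simulate_plot_observations(design, plan, scenario, day = day)
    gm <- genotype_means(compute_npt(compute_iinpt(obs)), design)
    gm$mean_npt[match(genotypes, gm$genotype)]
  })
  rownames(means) <- genotypes
  colnames(means) <- paste0("day", seq_len(n_days))
  means
}

# Differencing and additive-model genotype estimates for one day.
estimate_both <- function(obs, design) {
  gm <- genotype_means(compute_npt(compute_iinpt(obs)), design)
  diff_est <- stats::setNames(gm$mean_npt - mean(gm$mean_npt), gm$genotype)
  add_est <- fit_additive_model(obs, design)$genotype_effects[names(diff_est)]
  list(diff = diff_est, add = add_est)
}
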