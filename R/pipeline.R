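#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the simulate - extract - normalise -
#' analyse chain with the defaults used throughout the package: a
#' 192-genotype, 2-replicate trial laid out 24 rows x 16 plots with
#' incomplete blocks of 8, imaged on 3 days with an overlapping 8 x 3
#' plot footprint advancing 4 plots / 2 rows between images.
#'
#' @param n_genotypes,n_reps,plots_per_row,block_size trial layout, see
#'   [generate_layout()].
#' @param n_days measurement days.
#' @param footprint_cols,footprint_rows,advance_cols,advance_rows,jitter
#'   acquisition geometry, see [plan_acquisition()].
#' @param sigma_g,sigma_plot,sigma_obs,sigma_day,base_temp,drift_sd,cloud_step_prob,cloud_step_size
#'   generative parameters, see [simulation_scenario()].
#' @param qc_k QC outlier window (deg C), see [qc_outlier_mask()].
#' @param n_mc_reps Monte-Carlo randomisation replicates.
#' @param alpha significance level for LSDs and the randomisation test.
#' @param k_extreme genotypes per extreme in the rank-consistency
#'   analysis.
#' @param trial_id trial identifier.
#' @param seed integer seed; mandatory, drives every stochastic stage.
#' @return A validated `run_config` list.
#' @export
run_config <- function(n_genotypes = 192, n_reps = 2, plots_per_row = 16,
                       block_size = 8, n_days = 3,
                       footprint_cols = 8, footprint_rows = 3,
                       advance_cols = 4, advance_rows = 2, jitter = 1,
                       sigma_g = 0.4, sigma_plot = 0.1, sigma_obs = 0.3,
                       sigma_day = 0, base_temp = 20, drift_sd = 0.2,
                       cloud_step_prob = 0.05, cloud_step_size = 4,
                       qc_k = 3, n_mc_reps = 1000, alpha = 0.05,
                       k_extreme = 20, trial_id = "trial1", seed) {
  check_seed(seed)
  check_number(alpha, "alpha", min = 0, max = 1)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; keys match the arguments of [run_config()].
#' Unknown keys are an error, and `seed` must be present.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!"seed" %in% names(vals)) stop("config must set `seed`", call. = FALSE)
  do.call(run_config, vals)
}

#' Run the full thermal-phenotyping pipeline
#'
#' Orchestrates every stage on synthetic data: trial layout, per-day
#' overlapping image acquisition and plot observations, per-image
#' normalisation (IINPT), plot pooling (NPT), genotype means by
#' differencing and by the additive model, the ANOVA suite, Monte-Carlo
#' randomisation, rank-consistency and correlation analyses, and forward
#' stepwise regression of simulated yield. All tables are written as CSV
#' into `out_dir` along with a config snapshot and a run log; a rerun
#' with the same configuration reproduces every file byte for byte.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with every intermediate and result object.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  note("canopynorm %s pipeline, seed %d",
       as.character(utils::packageVersion("canopynorm")), config$seed)

  design <- generate_layout(config$n_genotypes, config$n_reps,
                            config$plots_per_row, config$block_size,
                            seed = config$seed, trial_id = config$trial_id)
  violations <- validate_design(design)
  if (length(violations) > 0) {
    stop("generated design violates invariants: ",
         paste(violations, collapse = "; "), call. = FALSE)
  }
  write_design(design, file.path(out_dir, "design.csv"))
  note("design: %d genotypes x %d reps, %d x %d plots",
       design$n_genotypes, design$n_reps, design$n_rows, design$plots_per_row)

  # one scenario fixes the genotype effects; baselines are redrawn per day
  plan1 <- plan_acquisition(design, config$footprint_cols, config$footprint_rows,
                            config$advance_cols, config$advance_rows,
                            config$jitter, seed = config$seed + 201L)
  scenario <- simulation_scenario(
    design, n_images = max(plan1$capture_index),
    sigma_g = config$sigma_g, sigma_plot = config$sigma_plot,
    sigma_obs = config$sigma_obs, sigma_day = config$sigma_day,
    base_temp = config$base_temp, drift_sd = config$drift_sd,
    cloud_step_prob = config$cloud_step_prob,
    cloud_step_size = config$cloud_step_size, seed = config$seed)

  occasions <- list()
  all_summaries <- list()
  plot_npt <- list()
  for (day in seq_len(config$n_days)) {
    plan <- plan_acquisition(design, config$footprint_cols, config$footprint_rows,
                             config$advance_cols, config$advance_rows,
                             config$jitter, seed = config$seed + 200L + day)
    sc_day <- scenario
    sc_day$image_baselines <- simulate_baselines(
      max(plan$capture_index), drift_sd = config$drift_sd,
      cloud_step_prob = config$cloud_step_prob,
      cloud_step_size = config$cloud_step_size,
      base_temp = config$base_temp, seed = config$seed + 300L + day)
    obs <- simulate_plot_observations(design, plan, sc_day, day = day)
    write_observations(obs, file.path(out_dir, sprintf("observations_day%d.csv", day)))
    norm <- compute_iinpt(obs)
    npt <- compute_npt(norm)
    occ <- sprintf("%s_day%d", config$trial_id, day)
    gm <- genotype_means(npt, design, occasion = occ)
    note("day %d: %d images, %d observations, mean coverage %.2f",
         day, max(plan$capture_index), nrow(obs), nrow(obs) / nrow(npt))
    occasions[[occ]] <- gm
    all_summaries[[occ]] <- gm
    npt$day <- day
    plot_npt[[day]] <- npt
  }
  summaries <- do.call(rbind, all_summaries)
  rownames(summaries) <- NULL
  write_genotype_summaries(summaries, file.path(out_dir, "genotype_summaries.csv"))

  genotypes <- sort(unique(design$assignments$genotype))
  means <- sapply(occasions, function(gm) gm$mean_npt[match(genotypes, gm$genotype)])
  rownames(means) <- genotypes
  utils::write.csv(data.frame(genotype = genotypes, means, check.names = FALSE),
                   file.path(out_dir, "genotype_means_matrix.csv"),
                   row.names = FALSE, quote = FALSE)

  # method agreement on day 1
  obs1 <- read_observations(file.path(out_dir, "observations_day1.csv"))
  diff_est <- genotype_means(compute_npt(compute_iinpt(obs1)), design)
  add_fit <- fit_additive_model(obs1, design)
  d_vec <- stats::setNames(diff_est$mean_npt - mean(diff_est$mean_npt),
                           diff_est$genotype)
  agreement <- compare_estimators(d_vec, add_fit$genotype_effects[names(d_vec)])
  note("method agreement (day 1): Pearson r = %.4f, mean difference = %.4g",
       agreement$pearson_r, agreement$mean_difference)

  # plot-level two-way ANOVA (replicates within genotype x day cells)
  plot_df <- do.call(rbind, lapply(plot_npt, function(npt) {
    data.frame(genotype = npt$genotype, day = npt$day, value = npt$npt)
  }))
  aov2 <- anova_twoway(plot_df)
  utils::write.csv(aov2, file.path(out_dir, "anova_plot.csv"),
                   row.names = FALSE, quote = FALSE)

  aovm <- anova_on_means(means)
  utils::write.csv(aovm$table, file.path(out_dir, "anova_means.csv"),
                   row.names = FALSE, quote = FALSE)
  note("genotypes explain %.1f%% of variation in daily means",
       aovm$variance_explained)

  mc <- monte_carlo_randomization(means, n_reps = config$n_mc_reps,
                                  alpha = config$alpha,
                                  seed = config$seed + 999L)
  utils::write.csv(
    data.frame(statistic = c("observed_f", "p_value", "observed_range",
                             "apparent_lsd"),
               value = c(mc$observed_f, mc$p_value, mc$observed_range,
                         mc$apparent_lsd)),
    file.path(out_dir, "randomization.csv"), row.names = FALSE, quote = FALSE)
  note("randomisation: p = %.4f, observed range %.3f vs apparent LSD %.3f",
       mc$p_value, mc$observed_range, mc$apparent_lsd)

  cm <- correlation_matrix(means)
  utils::write.csv(data.frame(occasion = rownames(cm), cm, check.names = FALSE),
                   file.path(out_dir, "correlation_matrix.csv"),
                   row.names = FALSE, quote = FALSE)

  ext <- extreme_subset_rho(means, k = config$k_extreme)
  utils::write.csv(
    data.frame(occasion = rownames(ext$rho), ext$rho, check.names = FALSE),
    file.path(out_dir, "extreme_subset_rho.csv"),
    row.names = FALSE, quote = FALSE)

  traits <- simulate_harvest_traits(scenario$genotype_effects,
                                    seed = config$seed + 400L)
  write_harvest_traits(traits, file.path(out_dir, "harvest_traits.csv"))
  temp_mean <- rowMeans(means)[traits$genotype]
  sw <- forward_stepwise(traits$yield,
                         data.frame(temperature = temp_mean,
                                    maturity = traits$maturity,
                                    height = traits$height))
  sw_txt <- utils::capture.output(print(sw))
  writeLines(sw_txt, file.path(out_dir, "stepwise.txt"))
  note("stepwise: %s", paste(sw$steps$term, collapse = " + "))

  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  invisible(list(design = design, scenario = scenario, summaries = summaries,
                 means = means, agreement = agreement, anova_plot = aov2,
                 anova_means = aovm, randomization = mc,
                 correlations = cm, extremes = ext, traits = traits,
                 stepwise = sw, out_dir = out_dir))
}
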