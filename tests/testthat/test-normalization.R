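obs_df <- function(image_id, temperature, row = seq_along(temperature),
                   col = 1) {
  data.frame(image_id = image_id, trial_id = "t", row = row, col = col,
             temperature = temperature)
}

test_that("IINPT subtracts the per-image mean and sums to zero per image", {
  o <- compute_iinpt(obs_df("i1", c(20, 22, 24)))
  expect_equal(o$iinpt, c(-2, 0, 2))
  o1 <- compute_iinpt(obs_df("i2", 18.5))
  expect_equal(o1$iinpt, 0)

  sim <- sim_day_obs(seed = 101, n_genotypes = 48)
  n <- compute_iinpt(sim$obs)
  sums <- tapply(n$iinpt, n$image_id, sum)
  expect_true(all(abs(sums) < 1e-9))
})

test_that("IINPT is independent of the image baselines", {
  sim <- sim_day_obs(seed = 55, n_genotypes = 48)
  sc0 <- sim$scenario
  sc0$image_baselines <- sc0$image_baselines * 0
  obs0 <- simulate_plot_observations(sim$design, sim$plan, sc0)
  expect_equal(compute_iinpt(sim$obs)$iinpt, compute_iinpt(obs0)$iinpt,
               tolerance = 1e-12)
})

test_that("QC-flagged observations are dropped before the image mean", {
  o <- obs_df("i1", c(20, 22, 30))
  o$qc_flag <- c(FALSE, FALSE, TRUE)
  expect_message(n <- compute_iinpt(o), "QC-flagged")
  expect_equal(nrow(n), 2)
  expect_equal(n$iinpt, c(-1, 1))   # mean over the two clean plots
})

test_that("NPT averages a plot's IINPTs across images", {
  n <- rbind(obs_df("i1", c(0, 0)), obs_df("i2", c(0, 0)))
  n$iinpt <- c(-1, 0.3, -0.6, 0.3)
  n$row <- c(1, 2, 1, 2); n$col <- 1
  class(n) <- c("normalized_observations", "data.frame")
  s <- compute_npt(n)
  expect_equal(s$npt[s$row == 1], -0.8)
  expect_equal(s$npt[s$row == 2], 0.3)
  expect_equal(s$n_images, c(2L, 2L))
})

test_that("genotype means, SEs and replicate counts follow the plot summaries", {
  s <- data.frame(trial_id = "t", row = c(1, 1, 2), col = c(1, 2, 1),
                  genotype = c("A", "A", "B"), npt = c(0.4, 0.6, 0.2))
  g <- genotype_means(s)
  expect_equal(g$mean_npt[g$genotype == "A"], 0.5)
  expect_equal(g$se[g$genotype == "A"], stats::sd(c(0.4, 0.6)) / sqrt(2))
  expect_equal(g$n_plots, c(2L, 1L))
  # single surviving replicate: mean kept, SE reported missing
  expect_true(is.na(g$se[g$genotype == "B"]))
})

test_that("per-image constant shifts change no IINPT, NPT or genotype mean", {
  sim <- sim_day_obs(seed = 77, n_genotypes = 48)
  obs <- sim$obs
  shifted <- obs
  images <- unique(obs$image_id)
  shifts <- stats::setNames(stats::runif(length(images), -30, 30), images)
  shifted$temperature <- obs$temperature + shifts[obs$image_id]

  n0 <- compute_iinpt(obs);      n1 <- compute_iinpt(shifted)
  expect_lt(max(abs(n0$iinpt - n1$iinpt)), 1e-9)
  p0 <- compute_npt(n0);         p1 <- compute_npt(n1)
  expect_lt(max(abs(p0$npt - p1$npt)), 1e-9)
  g0 <- genotype_means(p0, sim$design)
  g1 <- genotype_means(p1, sim$design)
  expect_lt(max(abs(g0$mean_npt - g1$mean_npt)), 1e-9)
})

test_that("with one whole-trial image and no noise, genotype means equal centred effects", {
  d <- generate_layout(12, 2, 6, 3, seed = 9)
  plan <- plan_acquisition(d, footprint_cols = 6, footprint_rows = 4,
                           advance_cols = 6, advance_rows = 4, jitter = 0,
                           seed = 1)
  expect_equal(max(plan$capture_index), 1)
  sc <- simulation_scenario(d, n_images = 1, sigma_plot = 0, sigma_obs = 0,
                            seed = 2)
  obs <- simulate_plot_observations(d, plan, sc)
  g <- genotype_means(compute_npt(compute_iinpt(obs)), d)
  truth <- sc$genotype_effects - mean(sc$genotype_effects)
  expect_equal(stats::setNames(g$mean_npt, g$genotype), truth[g$genotype],
               tolerance = 1e-12)
})

test_that("the additive model recovers noiseless data exactly", {
  d <- generate_layout(12, 2, 6, 3, seed = 4)
  plan <- plan_acquisition(d, footprint_cols = 4, footprint_rows = 2,
                           advance_cols = 2, advance_rows = 1, jitter = 1,
                           seed = 5)
  sc <- simulation_scenario(d, n_images = max(plan$capture_index),
                            sigma_plot = 0, sigma_obs = 0, seed = 6)
  obs <- simulate_plot_observations(d, plan, sc)
  fit <- fit_additive_model(obs, d)
  truth <- sc$genotype_effects - mean(sc$genotype_effects)
  expect_equal(fit$genotype_effects[names(truth)], truth, tolerance = 1e-9)
  expect_lt(fit$residual_ss, 1e-18)
})

test_that("a single image with two genotypes splits the difference", {
  obs <- data.frame(image_id = "i1", genotype = c("A", "B"),
                    temperature = c(20, 22))
  fit <- fit_additive_model(obs)
  expect_equal(unname(fit$genotype_effects[c("A", "B")]), c(-1, 1))
})

test_that("the additive fit matches a dense generalised-inverse solve", {
  # small overlapping instance: 3 genotypes, 3 images
  obs <- data.frame(
    image_id = c("i1", "i1", "i2", "i2", "i3", "i3", "i3"),
    genotype = c("A", "B", "B", "C", "A", "B", "C"),
    temperature = c(20.1, 20.9, 23.2, 24.1, 18.0, 18.8, 19.9)
  )
  fit <- fit_additive_model(obs)
  oracle <- oracle_additive_effects(obs)
  expect_equal(fit$genotype_effects[names(oracle)], oracle,
               tolerance = 1e-9)
})

test_that("a disconnected plot-image graph triggers an identifiability warning", {
  obs <- data.frame(
    image_id = c("i1", "i1", "i2", "i2"),
    genotype = c("A", "B", "C", "D"),
    temperature = c(20, 21, 25, 26)
  )
  expect_warning(fit_additive_model(obs), "disconnected")
})

test_that("differencing and the additive model coincide for replicate-per-image designs", {
  # each image covers one complete replicate: genotype and image effects
  # are orthogonal, so the two estimators agree exactly
  d <- generate_layout(12, 2, 6, 3, seed = 5)
  plan <- plan_acquisition(d, footprint_cols = 6, footprint_rows = 2,
                           advance_cols = 6, advance_rows = 2, jitter = 0,
                           seed = 1)
  sc <- simulation_scenario(d, n_images = max(plan$capture_index), seed = 7)
  obs <- simulate_plot_observations(d, plan, sc)
  est <- estimate_both(obs, d)
  expect_equal(est$diff, est$add, tolerance = 1e-9)
})

test_that("estimator comparison reports r, bias and major-axis slope", {
  a <- stats::setNames(stats::rnorm(10), letters[1:10])
  expect_equal(compare_estimators(a, a)$pearson_r, 1)
  expect_equal(compare_estimators(a, a)$mean_difference, 0)
  expect_equal(abs(compare_estimators(a, a)$slope), 1)
  expect_equal(compare_estimators(a, -a)$pearson_r, -1)
  expect_error(compare_estimators(a[1:2], a[1:2]), "at least 3")
})

test_that("genotype-effect recovery is reliable across many default scenarios", {
  # full trial size; the additive model is the package's best estimator
  # of the true genotype effects
  r <- vapply(1:200, function(i) {
    sim <- sim_day_obs(seed = 3000 + i)
    truth <- sim$scenario$genotype_effects
    fit <- fit_additive_model(sim$obs, sim$design)
    stats::cor(fit$genotype_effects[names(truth)], truth)
  }, numeric(1))
  expect_gte(mean(r > 0.9), 0.95)
})

test_that("genotype-mean error shrinks as image coverage rises", {
  err <- function(advance_rows, seeds) {
    vapply(seeds, function(s) {
      d <- generate_layout(48, 2, 16, 8, seed = s)
      plan <- plan_acquisition(d, footprint_cols = 8, footprint_rows = 3,
                               advance_cols = 8, advance_rows = advance_rows,
                               jitter = 0, seed = s + 1L)
      sc <- simulation_scenario(d, n_images = max(plan$capture_index),
                                seed = s + 2L)
      est <- genotype_means(compute_npt(compute_iinpt(
        simulate_plot_observations(d, plan, sc))), d)
      truth <- sc$genotype_effects[est$genotype]
      mean((est$mean_npt - (truth - mean(truth)))^2)
    }, numeric(1))
  }
  seeds <- 500 + 1:8
  e_single <- err(advance_rows = 3, seeds)   # tiling, coverage 1
  e_triple <- err(advance_rows = 1, seeds)   # coverage ~3
  expect_lt(mean(e_triple), mean(e_single))
})
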