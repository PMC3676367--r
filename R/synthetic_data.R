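#' Simulation scenario for a thermally imaged field trial
#'
#' Bundles the generative parameters the simulator uses: per-genotype
#' temperature offsets, per-image environmental baselines, and the noise
#' standard deviations. The generative model for a plot observed in an
#' image is additive:
#'
#'   temperature = image baseline + genotype effect
#'                 + plot effect + observation noise
#'
#' matching the assumption under which per-image mean subtraction removes
#' the environmental signal exactly.
#'
#' @param design a `trial_design`; genotype effects are drawn for its
#'   genotypes.
#' @param n_images number of planned images (baselines are drawn per
#'   image).
#' @param sigma_g SD (deg C) of genotype effects; the default 0.4 gives a
#'   genotype range of roughly 2 deg C across 192 genotypes.
#' @param sigma_plot SD (deg C) of the per-plot effect shared by all
#'   images of one plot (persistent soil and canopy heterogeneity).
#' @param sigma_obs SD (deg C) of independent per-observation noise;
#'   the dominant noise term, since wind gusts, viewing geometry and
#'   sensor noise change from image to image of the same plot.
#' @param sigma_day SD (deg C) of a genotype-by-day interaction effect;
#'   0 by default (genotype ranking perfectly stable across days).
#' @param base_temp mean canopy temperature (deg C) around which image
#'   baselines drift.
#' @param drift_sd per-image SD (deg C) of the baseline random walk.
#' @param cloud_step_prob per-image probability of an abrupt irradiance
#'   step (cloud cover arriving or clearing).
#' @param cloud_step_size magnitude (deg C) of such a step.
#' @param seed integer seed; fixes genotype effects and baselines.
#' @return A `sim_scenario` list with elements `genotype_effects` (named
#'   numeric), `image_baselines`, the noise SDs and the seed.
#' @export
simulation_scenario <- function(design, n_images,
                                sigma_g = 0.4, sigma_plot = 0.1,
                                sigma_obs = 0.3, sigma_day = 0,
                                base_temp = 20, drift_sd = 0.2,
                                cloud_step_prob = 0.05, cloud_step_size = 4,
                                seed) {
  stopifnot(inherits(design, "trial_design"))
  n_images <- check_count(n_images, "n_images", 1L)
  for (nm in c("sigma_g", "sigma_plot", "sigma_obs", "sigma_day")) {
    check_number(get(nm), nm, min = 0)
  }
  check_seed(seed)
  genotypes <- sort(unique(design$assignments$genotype))
  effects <- with_seed(seed, stats::rnorm(length(genotypes), 0, sigma_g))
  names(effects) <- genotypes
  baselines <- simulate_baselines(n_images, drift_sd = drift_sd,
                                  cloud_step_prob = cloud_step_prob,
                                  cloud_step_size = cloud_step_size,
                                  base_temp = base_temp, seed = seed + 1L)
  structure(
    list(genotype_effects = effects, image_baselines = baselines,
         sigma_g = sigma_g, sigma_plot = sigma_plot, sigma_obs = sigma_obs,
         sigma_day = sigma_day, base_temp = base_temp, seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Simulate per-image environmental baselines
#'
#' Models the image-to-image drift of mean canopy temperature during an
#' imaging session as a Gaussian random walk with occasional abrupt steps
#' of magnitude `cloud_step_size` (sign drawn at random: cloud cover
#' arriving depresses temperatures by several degrees, clearing restores
#' them).
#'
#' @param n_images number of baselines to generate.
#' @param drift_sd SD (deg C) of the per-image random-walk increment.
#' @param cloud_step_prob probability, per image transition, of a step
#'   event.
#' @param cloud_step_size step magnitude (deg C), must be >= 0.
#' @param base_temp starting temperature (deg C).
#' @param seed integer seed.
#' @return Numeric vector of length `n_images`; attribute `"steps"` is a
#'   data frame (`index`, `step`) logging the step events.
#' @export
simulate_baselines <- function(n_images, drift_sd = 0.2,
                               cloud_step_prob = 0.05, cloud_step_size = 4,
                               base_temp = 20, seed) {
  n_images <- check_count(n_images, "n_images", 1L)
  check_number(drift_sd, "drift_sd", min = 0)
  check_number(cloud_step_prob, "cloud_step_prob", min = 0, max = 1)
  check_number(cloud_step_size, "cloud_step_size", min = 0)
  with_seed(seed, {
    incr <- stats::rnorm(n_images - 1L, 0, drift_sd)
    event <- stats::runif(n_images - 1L) < cloud_step_prob
    sign <- ifelse(stats::runif(n_images - 1L) < 0.5, -1, 1)
    steps <- ifelse(event, sign * cloud_step_size, 0)
    b <- base_temp + c(0, cumsum(incr + steps))
    attr(b, "steps") <- data.frame(index = which(event) + 1L,
                                   step = steps[event])
    b
  })
}

#' Plan an overlapping image-acquisition sequence
#'
#' Emulates imaging a trial from a raised platform: each image covers a
#' rectangular footprint of plots (at most 9 plots across and 4 rows, the
#' practical footprint of a 320x240 thermal camera at canopy scale), and
#' the camera advances by fewer plots than the footprint so that
#' successive images overlap deliberately but, through a random jitter of
#' each image origin, not systematically. Every plot is covered at least
#' once; with `advance < footprint` most plots are covered two or more
#' times, which is what gives the per-image normalisation its extra
#' replication. If jitter opens a coverage gap, patch images are appended
#' so the guarantee holds.
#'
#' @param design a `trial_design`.
#' @param footprint_cols,footprint_rows image footprint in plots
#'   (`footprint_cols <= 9`, `footprint_rows <= 4`).
#' @param advance_cols,advance_rows camera advance between successive
#'   images, in plots (>= 1).
#' @param jitter maximum absolute deviation (plots) added to each image
#'   origin.
#' @param seed integer seed for the jitter.
#' @return An `acquisition_plan`: a data frame with one row per
#'   (image, plot) pair — columns `image_id`, `capture_index`, `row`,
#'   `col` — plus footprint metadata in attributes.
#' @export
plan_acquisition <- function(design, footprint_cols = 8, footprint_rows = 3,
                             advance_cols = 4, advance_rows = 2,
                             jitter = 1, seed) {
  stopifnot(inherits(design, "trial_design"))
  footprint_cols <- check_count(footprint_cols, "footprint_cols", 1L)
  footprint_rows <- check_count(footprint_rows, "footprint_rows", 1L)
  if (footprint_cols > 9L || footprint_rows > 4L) {
    stop("camera footprint is at most 9 plots x 4 rows", call. = FALSE)
  }
  if (footprint_cols > design$plots_per_row || footprint_rows > design$n_rows) {
    stop("footprint exceeds the trial dimensions", call. = FALSE)
  }
  advance_cols <- check_count(advance_cols, "advance_cols", 1L)
  advance_rows <- check_count(advance_rows, "advance_rows", 1L)
  jitter <- check_count(jitter, "jitter", 0L)

  origin_seq <- function(n, fp, adv) {
    s <- seq(1L, max(1L, n - fp + 1L), by = adv)
    if (s[length(s)] + fp - 1L < n) s <- c(s, n - fp + 1L)
    s
  }
  row_starts <- origin_seq(design$n_rows, footprint_rows, advance_rows)
  col_starts <- origin_seq(design$plots_per_row, footprint_cols, advance_cols)

  origins <- with_seed(seed, {
    grid <- expand.grid(c = col_starts, r = row_starts)  # row-major sweep
    jr <- if (jitter > 0) sample(seq(-jitter, jitter), nrow(grid), replace = TRUE) else 0L
    jc <- if (jitter > 0) sample(seq(-jitter, jitter), nrow(grid), replace = TRUE) else 0L
    data.frame(
      r = pmin(pmax(grid$r + jr, 1L), design$n_rows - footprint_rows + 1L),
      c = pmin(pmax(grid$c + jc, 1L), design$plots_per_row - footprint_cols + 1L)
    )
  })

  covered <- function(r0, c0) {
    expand.grid(row = seq(r0, r0 + footprint_rows - 1L),
                col = seq(c0, c0 + footprint_cols - 1L))
  }
  plots <- Map(function(r0, c0) covered(r0, c0), origins$r, origins$c)

  # guarantee full coverage: patch any plot jitter left unimaged
  seen <- unique(do.call(rbind, plots))
  all_cells <- expand.grid(row = seq_len(design$n_rows),
                           col = seq_len(design$plots_per_row))
  missing <- all_cells[!paste(all_cells$row, all_cells$col) %in%
                         paste(seen$row, seen$col), , drop = FALSE]
  while (nrow(missing) > 0) {
    r0 <- min(max(missing$row[1] - footprint_rows %/% 2L, 1L),
              design$n_rows - footprint_rows + 1L)
    c0 <- min(max(missing$col[1] - footprint_cols %/% 2L, 1L),
              design$plots_per_row - footprint_cols + 1L)
    patch <- covered(r0, c0)
    plots <- c(plots, list(patch))
    missing <- missing[!paste(missing$row, missing$col) %in%
                         paste(patch$row, patch$col), , drop = FALSE]
  }

  plan <- do.call(rbind, Map(function(p, i) {
    cbind(image_id = sprintf("%s_img%03d", design$trial_id, i),
          capture_index = i, p)
  }, plots, seq_along(plots)))
  rownames(plan) <- NULL
  structure(plan,
            class = c("acquisition_plan", "data.frame"),
            footprint = c(rows = footprint_rows, cols = footprint_cols),
            trial_id = design$trial_id)
}

#' Simulate plot-temperature observations under a scenario
#'
#' Applies the additive generative model to every (image, plot) pair in
#' an acquisition plan: observed temperature = image baseline + genotype
#' effect (+ genotype-by-day effect when `sigma_day > 0`) + per-plot
#' effect + independent observation noise.
#'
#' @param design a `trial_design`.
#' @param plan an `acquisition_plan` over the same design.
#' @param scenario a `sim_scenario` whose `image_baselines` cover every
#'   image in the plan.
#' @param day day index; with `sigma_day > 0` each day redraws the
#'   genotype-by-day effects (seeded deterministically from the scenario
#'   seed and the day).
#' @return A `plot_observations` data frame: `image_id`, `trial_id`,
#'   `row`, `col`, `genotype`, `replicate`, `temperature` (deg C).
#' @export
simulate_plot_observations <- function(design, plan, scenario, day = 1L) {
  stopifnot(inherits(design, "trial_design"),
            inherits(plan, "acquisition_plan"),
            inherits(scenario, "sim_scenario"))
  day <- check_count(day, "day", 1L)
  a <- design$assignments
  idx <- match(paste(plan$row, plan$col), paste(a$row, a$col))
  if (anyNA(idx)) {
    stop("plan covers plots absent from the design", call. = FALSE)
  }
  n_images <- max(plan$capture_index)
  if (length(scenario$image_baselines) < n_images) {
    stop(sprintf("scenario has %d image baselines but the plan needs %d",
                 length(scenario$image_baselines), n_images), call. = FALSE)
  }
  genotype <- a$genotype[idx]
  if (!all(genotype %in% names(scenario$genotype_effects))) {
    stop("scenario lacks effects for some genotypes in the design", call. = FALSE)
  }

  # day-specific draws: plot effects are redrawn per day (plants grow,
  # soil dries), genotype-by-day effects model ranking instability
  day_seed <- (scenario$seed + 97L * day) %% .Machine$integer.max
  plots <- unique(a[c("row", "col")])
  pk_all <- paste(plots$row, plots$col)
  draws <- with_seed(day_seed, {
    g_ids <- names(scenario$genotype_effects)
    list(
      plot_eff = stats::setNames(
        stats::rnorm(nrow(plots), 0, scenario$sigma_plot), pk_all),
      day_eff = stats::setNames(
        if (scenario$sigma_day > 0) {
          stats::rnorm(length(g_ids), 0, scenario$sigma_day)
        } else rep(0, length(g_ids)), g_ids),
      obs_noise = stats::rnorm(nrow(plan), 0, scenario$sigma_obs)
    )
  })

  temperature <- scenario$image_baselines[plan$capture_index] +
    scenario$genotype_effects[genotype] +
    draws$day_eff[genotype] +
    draws$plot_eff[paste(plan$row, plan$col)] +
    draws$obs_noise

  obs <- data.frame(
    image_id = plan$image_id,
    trial_id = design$trial_id,
    row = plan$row, col = plan$col,
    genotype = genotype,
    replicate = a$replicate[idx],
    temperature = as.numeric(temperature),
    stringsAsFactors = FALSE
  )
  class(obs) <- c("plot_observations", "data.frame")
  obs
}

#' Render a synthetic thermal frame for one image
#'
#' Produces a pixel-level temperature matrix for the plots covered by one
#' image, with a sampling polygon per plot. The covered plots tile the
#' frame as a grid of cells; each polygon is an axis-aligned rectangle
#' eroded inwards from its cell (sampling canopy while avoiding plot
#' edges and bare ground). Background pixels are sunlit soil, hotter than
#' the canopy by default.
#'
#' @param covered data frame with `row`, `col`, `temperature`: the plots
#'   in the image and their true canopy temperatures (deg C).
#' @param width,height frame dimensions in pixels (camera native
#'   320 x 240 by default).
#' @param soil_temp background soil temperature (deg C).
#' @param pixel_noise_sd per-pixel noise SD (deg C).
#' @param margin_frac fraction of each cell eroded from every side to
#'   form the sampling polygon.
#' @param seed integer seed for the pixel noise.
#' @return A `thermal_frame` list: `pixels` (height x width matrix, deg
#'   C), `polygons` (named list of 4-vertex data frames in 0-based pixel
#'   coordinates, x = column, y = row), and `plots` (the `covered` input
#'   with a `polygon_id` column).
#' @export
render_thermal_frame <- function(covered, width = 320L, height = 240L,
                                 soil_temp = 30, pixel_noise_sd = 0.5,
                                 margin_frac = 0.2, seed) {
  stopifnot(is.data.frame(covered),
            all(c("row", "col", "temperature") %in% names(covered)))
  width <- check_count(width, "width", 1L)
  height <- check_count(height, "height", 1L)
  check_number(pixel_noise_sd, "pixel_noise_sd", min = 0)
  check_number(margin_frac, "margin_frac", min = 0, max = 0.45)
  if (anyDuplicated(paste(covered$row, covered$col))) {
    stop("covered plots must be distinct", call. = FALSE)
  }

  rows <- sort(unique(covered$row))
  cols <- sort(unique(covered$col))
  cell_h <- height / length(rows)
  cell_w <- width / length(cols)

  with_seed(seed, {
    pixels <- matrix(stats::rnorm(width * height, soil_temp, pixel_noise_sd),
                     nrow = height, ncol = width)
    polygons <- vector("list", nrow(covered))
    ids <- character(nrow(covered))
    for (i in seq_len(nrow(covered))) {
      ri <- match(covered$row[i], rows) - 1L
      ci <- match(covered$col[i], cols) - 1L
      x0 <- ci * cell_w + margin_frac * cell_w
      x1 <- (ci + 1) * cell_w - margin_frac * cell_w
      y0 <- ri * cell_h + margin_frac * cell_h
      y1 <- (ri + 1) * cell_h - margin_frac * cell_h
      poly <- data.frame(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
      ids[i] <- sprintf("p_r%02d_c%02d", covered$row[i], covered$col[i])
      polygons[[i]] <- poly
      # interior pixels: centres at (col - 0.5, row - 0.5) in 0-based coords
      pc <- which(seq_len(width) - 0.5 > x0 & seq_len(width) - 0.5 < x1)
      pr <- which(seq_len(height) - 0.5 > y0 & seq_len(height) - 0.5 < y1)
      pixels[pr, pc] <- covered$temperature[i] +
        stats::rnorm(length(pr) * length(pc), 0, pixel_noise_sd)
    }
    names(polygons) <- ids
    plots <- covered
    plots$polygon_id <- ids
    structure(list(pixels = pixels, polygons = polygons, plots = plots),
              class = "thermal_frame")
  })
}

#' Simulate harvest traits correlated with canopy temperature
#'
#' Generates per-genotype yield, plant height and a 1-9 maturity score
#' from the genotype temperature effects. Yield and height decline
#' linearly with genotype temperature (cooler canopies indicate higher
#' stomatal conductance and assimilation); the maturity score increases
#' with temperature (warmer genotypes mature later; 9 = least mature),
#' rounded and clipped to the 1-9 scale.
#'
#' @param genotype_effects named numeric vector of genotype temperature
#'   offsets (deg C).
#' @param slope_yield kg per deg C (negative by default).
#' @param slope_height cm per deg C.
#' @param slope_maturity score units per deg C.
#' @param base_yield,base_height,base_maturity trait values at genotype
#'   effect 0; yield in kg per 5-plant plot, height in cm.
#' @param noise_yield,noise_height,noise_maturity residual SDs.
#' @param seed integer seed.
#' @return A `harvest_traits` data frame: `genotype`, `yield`, `height`,
#'   `maturity`.
#' @export
simulate_harvest_traits <- function(genotype_effects,
                                    slope_yield = -1.5, slope_height = -6,
                                    slope_maturity = 2,
                                    base_yield = 8, base_height = 60,
                                    base_maturity = 5,
                                    noise_yield = 0.9, noise_height = 8,
                                    noise_maturity = 1.2,
                                    seed) {
  stopifnot(is.numeric(genotype_effects), !is.null(names(genotype_effects)))
  for (nm in c("noise_yield", "noise_height", "noise_maturity")) {
    check_number(get(nm), nm, min = 0)
  }
  n <- length(genotype_effects)
  with_seed(seed, {
    yield <- pmax(0, base_yield + slope_yield * genotype_effects +
                    stats::rnorm(n, 0, noise_yield))
    height <- base_height + slope_height * genotype_effects +
      stats::rnorm(n, 0, noise_height)
    maturity <- round(base_maturity + slope_maturity * genotype_effects +
                        stats::rnorm(n, 0, noise_maturity))
    maturity <- pmin(pmax(maturity, 1L), 9L)
    out <- data.frame(genotype = names(genotype_effects),
                      yield = as.numeric(yield),
                      height = as.numeric(height),
                      maturity = as.integer(maturity),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("harvest_traits", "data.frame")
    out
  })
}
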