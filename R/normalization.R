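#' Per-image normalisation of plot temperatures (IINPT)
#'
#' Canopy temperatures drift by several degrees between images as cloud
#' cover, irradiance and wind change, so raw individual-image plot
#' temperatures (IPTs) from different images are not comparable. The
#' individual-image normalised plot temperature (IINPT) removes the
#' image effect by subtracting, from every plot in an image, the
#' unweighted mean of all plot temperatures in that same image. IINPTs
#' therefore sum to zero within each image, and are invariant to adding
#' any constant to all of an image's observations.
#'
#' Observations carrying a `qc_flag` of `TRUE` (soil-contaminated
#' polygons) are dropped before the image mean is computed — a flagged
#' plot would bias the normaliser for every other plot in its image.
#'
#' @param observations a `plot_observations` data frame with at least
#'   `image_id` and `temperature`; an optional logical `qc_flag` column
#'   marks observations to exclude.
#' @return The QC-passing observations with an added `iinpt` column
#'   (class `normalized_observations`).
#' @examples
#' obs <- data.frame(image_id = "i1", row = 1, col = 1:3,
#'                   temperature = c(20, 22, 24))
#' compute_iinpt(obs)$iinpt   # -2 0 2
#' @export
compute_iinpt <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("image_id", "temperature") %in% names(observations)))
  if (nrow(observations) == 0) stop("no observations", call. = FALSE)
  obs <- observations
  if ("qc_flag" %in% names(obs)) {
    n_bad <- sum(obs$qc_flag)
    if (n_bad > 0) {
      message(sprintf("dropping %d QC-flagged observation(s)", n_bad))
      obs <- obs[!obs$qc_flag, , drop = FALSE]
    }
  }
  img_mean <- tapply(obs$temperature, obs$image_id, mean)
  obs$iinpt <- obs$temperature - as.numeric(img_mean[obs$image_id])
  rownames(obs) <- NULL
  class(obs) <- unique(c("normalized_observations", class(obs)))
  obs
}

#' Normalised plot temperature (NPT)
#'
#' Plots covered by more than one image have several IINPTs; the
#' normalised plot temperature is their unweighted mean, pooling the
#' replication created by deliberate image overlap. NPTs are the unit of
#' all downstream statistics.
#'
#' @param normalized a `normalized_observations` data frame from
#'   [compute_iinpt()].
#' @return A `plot_summaries` data frame with one row per plot:
#'   `trial_id`, `row`, `col`, carried `genotype`/`replicate` when
#'   present, `npt` and `n_images`.
#' @export
compute_npt <- function(normalized) {
  stopifnot(is.data.frame(normalized), "iinpt" %in% names(normalized))
  key_cols <- intersect(c("trial_id", "row", "col"), names(normalized))
  if (!all(c("row", "col") %in% key_cols)) {
    stop("observations must carry plot coordinates `row` and `col`", call. = FALSE)
  }
  key <- do.call(paste, c(normalized[key_cols], sep = ":"))
  first <- !duplicated(key)
  carry <- intersect(c("genotype", "replicate"), names(normalized))
  out <- normalized[first, c(key_cols, carry), drop = FALSE]
  out$npt <- as.numeric(tapply(normalized$iinpt, key, mean)[key[first]])
  out$n_images <- as.integer(table(key)[key[first]])
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("plot_summaries", "data.frame")
  out
}

#' Genotype means of normalised plot temperatures
#'
#' Averages NPTs over each genotype's replicate plots, giving the
#' normalised genotype temperature for one measurement occasion, with
#' its standard error and the number of surviving replicate plots. A
#' genotype reduced to a single plot keeps its mean but has no standard
#' error (`NA`).
#'
#' @param summaries a `plot_summaries` data frame; if it lacks a
#'   `genotype` column, `design` must be supplied to map plots to
#'   genotypes.
#' @param design optional `trial_design` used to resolve genotypes.
#' @param occasion optional label (for example `"trial4_day1"`) stamped
#'   on each row.
#' @return A `genotype_summaries` data frame: `genotype`, `occasion`,
#'   `mean_npt`, `se`, `n_plots`.
#' @export
genotype_means <- function(summaries, design = NULL, occasion = NA_character_) {
  stopifnot(is.data.frame(summaries), "npt" %in% names(summaries))
  s <- summaries
  if (!"genotype" %in% names(s)) {
    if (is.null(design)) {
      stop("no `genotype` column and no design to resolve plots", call. = FALSE)
    }
    a <- design$assignments
    idx <- match(paste(s$row, s$col), paste(a$row, a$col))
    if (anyNA(idx)) {
      stop("plot not present in the design: cannot resolve genotype", call. = FALSE)
    }
    s$genotype <- a$genotype[idx]
  }
  mean_npt <- tapply(s$npt, s$genotype, mean)
  n_plots <- tapply(s$npt, s$genotype, length)
  se <- tapply(s$npt, s$genotype, function(v) {
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  out <- data.frame(
    genotype = names(mean_npt),
    occasion = occasion,
    mean_npt = as.numeric(mean_npt),
    se = as.numeric(se),
    n_plots = as.integer(n_plots),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("genotype_summaries", "data.frame")
  out
}

#' Additive genotype-plus-image least-squares model
#'
#' The model-based alternative to image-mean differencing: ordinary
#' least squares on
#'
#'   temperature ~ genotype effect + image effect + residual
#'
#' with sum-to-zero constraints on both effect sets, so genotype effects
#' are deviations from the grand mean and directly comparable with
#' centred differencing estimates. QC-flagged observations are dropped.
#'
#' Genotype contrasts are only identifiable within a connected component
#' of the bipartite plot-image graph; if the graph is disconnected a
#' warning reports the components.
#'
#' @param observations a `plot_observations` data frame with `image_id`,
#'   `temperature` and either a `genotype` column or plot coordinates
#'   resolvable through `design`.
#' @param design optional `trial_design` to resolve genotypes.
#' @return An `additive_fit` list: `genotype_effects` and
#'   `image_effects` (named, centred to mean zero), `sigma`,
#'   `df_residual`, `residual_ss`, `n_components`.
#' @export
fit_additive_model <- function(observations, design = NULL) {
  stopifnot(is.data.frame(observations),
            all(c("image_id", "temperature") %in% names(observations)))
  obs <- observations
  if ("qc_flag" %in% names(obs)) obs <- obs[!obs$qc_flag, , drop = FALSE]
  if (!"genotype" %in% names(obs)) {
    if (is.null(design)) {
      stop("no `genotype` column and no design to resolve plots", call. = FALSE)
    }
    a <- design$assignments
    idx <- match(paste(obs$row, obs$col), paste(a$row, a$col))
    if (anyNA(idx)) stop("plot not present in the design", call. = FALSE)
    obs$genotype <- a$genotype[idx]
  }

  g <- factor(obs$genotype)
  img <- factor(obs$image_id)
  n_comp <- n_graph_components(as.integer(g), as.integer(img), nlevels(g), nlevels(img))
  if (n_comp > 1) {
    warning(sprintf(
      "plot-image graph has %d disconnected components; only within-component genotype contrasts are identifiable",
      n_comp), call. = FALSE)
  }

  if (nlevels(img) > 1 && nlevels(g) > 1) {
    fit <- stats::lm(temperature ~ g + img, data = obs,
                     contrasts = list(g = "contr.sum", img = "contr.sum"))
    cf <- stats::coef(fit)
    gc <- cf[grep("^g[0-9]+$", names(cf))]
    ic <- cf[grep("^img[0-9]+$", names(cf))]
    gc[is.na(gc)] <- 0
    ic[is.na(ic)] <- 0
    g_eff <- c(gc, -sum(gc))
    i_eff <- c(ic, -sum(ic))
  } else if (nlevels(g) > 1) {
    fit <- stats::lm(temperature ~ g, data = obs,
                     contrasts = list(g = "contr.sum"))
    cf <- stats::coef(fit)
    gc <- cf[grep("^g[0-9]+$", names(cf))]
    g_eff <- c(gc, -sum(gc))
    i_eff <- 0
  } else {
    stop("need at least 2 genotypes", call. = FALSE)
  }
  names(g_eff) <- levels(g)
  names(i_eff) <- levels(img)
  g_eff <- g_eff - mean(g_eff)

  res <- stats::residuals(fit)
  structure(
    list(genotype_effects = g_eff, image_effects = i_eff - mean(i_eff),
         sigma = stats::sigma(fit), df_residual = fit$df.residual,
         residual_ss = sum(res^2), n_components = n_comp),
    class = "additive_fit"
  )
}

# Union-find count of connected components of the bipartite
# genotype/plot-image incidence graph.
n_graph_components <- function(g_idx, img_idx, n_g, n_img) {
  parent <- seq_len(n_g + n_img)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(g_idx)) {
    a <- find(g_idx[k]); b <- find(n_g + img_idx[k])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_along(parent), find, integer(1))))
}

#' Compare two sets of genotype estimates
#'
#' Agreement diagnostics between genotype temperature estimates from two
#' methods (typically image-mean differencing vs the additive model):
#' Pearson correlation, mean difference (systematic bias), and the
#' major-axis slope (first principal axis — appropriate when both sets
#' carry estimation error).
#'
#' @param a,b named numeric vectors over the same genotype set (at least
#'   3 genotypes).
#' @return List with `pearson_r`, `mean_difference`, `slope`, `n`.
#' @export
compare_estimators <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) != length(a) || length(common) != length(b)) {
      stop("`a` and `b` must cover the same genotype set", call. = FALSE)
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length", call. = FALSE)
  }
  if (length(a) < 3) stop("need at least 3 genotypes", call. = FALSE)
  ev <- eigen(stats::cov(cbind(a, b)), symmetric = TRUE)$vectors[, 1]
  slope <- ev[2] / ev[1]
  list(pearson_r = stats::cor(a, b),
       mean_difference = mean(a - b),
       slope = slope,
       n = length(a))
}
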