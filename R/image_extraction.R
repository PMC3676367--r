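#' Outlier mask for polygon pixel temperatures
#'
#' Automates the histogram check used when sampling canopy pixels: any
#' pixel further than `k` deg C from the polygon median is excluded.
#' Hot outliers are typically bare soil seen through the canopy; cold
#' outliers can be sky reflections or shadowed ground. The cut moves with
#' the median, so the mask is invariant to adding a constant to every
#' pixel.
#'
#' @param pixels numeric vector of pixel temperatures (deg C).
#' @param k half-width of the inclusion window (deg C), strictly
#'   positive.
#' @return List with `mask` (logical, TRUE = keep) and
#'   `fraction_excluded`.
#' @examples
#' qc_outlier_mask(c(rep(20, 50), 35, 35), k = 3)$fraction_excluded
#' @export
qc_outlier_mask <- function(pixels, k = 3) {
  if (length(pixels) == 0) stop("empty pixel list", call. = FALSE)
  check_number(k, "k", min = 0, strict_min = TRUE)
  med <- stats::median(pixels)
  mask <- pixels >= med - k & pixels <= med + k
  if (!any(mask)) stop("QC excluded every pixel in the polygon", call. = FALSE)
  list(mask = mask, fraction_excluded = mean(!mask))
}

# Even-odd (crossing number) point-in-polygon test on pixel centres.
# Points and vertices are in 0-based pixel coordinates, x = column,
# y = row; a pixel at matrix position [r, c] has centre (c-0.5, r-0.5).
points_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly$x[i]; yi <- poly$y[i]
    xj <- poly$x[j]; yj <- poly$y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Estimate a plot's canopy temperature from a thermal frame
#'
#' The individual-image plot temperature (IPT) is the arithmetic mean of
#' the pixels whose centres fall inside the sampling polygon, after the
#' median +/- `qc_k` outlier exclusion of [qc_outlier_mask()]. The
#' observation is QC-flagged when the excluded fraction exceeds
#' `qc_flag_threshold`, signalling a polygon that likely includes ground.
#'
#' @param frame numeric matrix of pixel temperatures (rows = image rows),
#'   or a `thermal_frame` (its `pixels` matrix is used).
#' @param polygon data frame of vertices (`x`, `y`) in 0-based pixel
#'   coordinates; at least 3 vertices, all within the frame.
#' @param qc_k outlier window half-width (deg C) passed to
#'   [qc_outlier_mask()].
#' @param qc_flag_threshold excluded-fraction threshold above which the
#'   observation is flagged.
#' @return One-row data frame: `ipt`, `n_pixels` (pixels retained),
#'   `n_excluded`, `qc_flag`.
#' @export
extract_plot_temperature <- function(frame, polygon, qc_k = 3,
                                     qc_flag_threshold = 0.2) {
  if (inherits(frame, "thermal_frame")) frame <- frame$pixels
  stopifnot(is.matrix(frame), is.data.frame(polygon),
            all(c("x", "y") %in% names(polygon)))
  if (nrow(polygon) < 3) {
    stop("degenerate polygon: need at least 3 vertices", call. = FALSE)
  }
  w <- ncol(frame); h <- nrow(frame)
  if (any(polygon$x < 0 | polygon$x > w | polygon$y < 0 | polygon$y > h)) {
    stop("polygon vertex outside the frame bounds", call. = FALSE)
  }
  # restrict the test to the polygon's bounding box
  cs <- max(1L, floor(min(polygon$x) + 0.5)):min(w, ceiling(max(polygon$x) + 0.5))
  rs <- max(1L, floor(min(polygon$y) + 0.5)):min(h, ceiling(max(polygon$y) + 0.5))
  grid <- expand.grid(c = cs, r = rs)
  inside <- points_in_polygon(grid$c - 0.5, grid$r - 0.5, polygon)
  if (!any(inside)) {
    stop("polygon encloses no pixel centres", call. = FALSE)
  }
  px <- frame[cbind(grid$r[inside], grid$c[inside])]
  qc <- qc_outlier_mask(px, k = qc_k)
  data.frame(
    ipt = mean(px[qc$mask]),
    n_pixels = sum(qc$mask),
    n_excluded = sum(!qc$mask),
    qc_flag = qc$fraction_excluded > qc_flag_threshold
  )
}

#' Extract observations for every plot in a rendered frame
#'
#' Convenience wrapper applying [extract_plot_temperature()] to each
#' polygon of a [render_thermal_frame()] result, yielding rows in the
#' same layout as [simulate_plot_observations()].
#'
#' @param rendered a `thermal_frame`.
#' @param image_id,trial_id identifiers stamped on each observation.
#' @inheritParams extract_plot_temperature
#' @return A `plot_observations` data frame with columns `image_id`,
#'   `trial_id`, `row`, `col`, `temperature`, `n_pixels`, `n_excluded`,
#'   `qc_flag`.
#' @export
extract_frame_observations <- function(rendered, image_id = "img001",
                                       trial_id = "trial1", qc_k = 3,
                                       qc_flag_threshold = 0.2) {
  stopifnot(inherits(rendered, "thermal_frame"))
  res <- do.call(rbind, lapply(rendered$plots$polygon_id, function(id) {
    extract_plot_temperature(rendered$pixels, rendered$polygons[[id]],
                             qc_k = qc_k, qc_flag_threshold = qc_flag_threshold)
  }))
  out <- data.frame(
    image_id = image_id, trial_id = trial_id,
    row = rendered$plots$row, col = rendered$plots$col,
    temperature = res$ipt, n_pixels = res$n_pixels,
    n_excluded = res$n_excluded, qc_flag = res$qc_flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("plot_observations", "data.frame")
  out
}
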