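#' Read and write plot-observation CSVs
#'
#' The observations dialect has columns
#' `image_id,trial_id,row,col,genotype,replicate,temperature_C` (the
#' in-memory column is `temperature`); extraction bookkeeping columns
#' (`n_pixels`, `n_excluded`, `qc_flag`) are carried when present. Round
#' trips are lossless for these columns.
#'
#' @param observations a `plot_observations` data frame.
#' @param path file path.
#' @return `read_observations()` returns a `plot_observations` data
#'   frame; writers return `path` invisibly.
#' @export
write_observations <- function(observations, path) {
  stopifnot(is.data.frame(observations))
  out <- observations
  names(out)[names(out) == "temperature"] <- "temperature_C"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(obs)[names(obs) == "temperature_C"] <- "temperature"
  need <- c("image_id", "trial_id", "row", "col", "temperature")
  if (!all(need %in% names(obs))) {
    stop("observations CSV must have columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  class(obs) <- c("plot_observations", "data.frame")
  obs
}

#' Read and write genotype-summary CSVs
#'
#' Columns `genotype,occasion,mean_npt,se,n_plots`.
#'
#' @param summaries a `genotype_summaries` data frame.
#' @param path file path.
#' @export
write_genotype_summaries <- function(summaries, path) {
  stopifnot(is.data.frame(summaries))
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_summaries
#' @export
read_genotype_summaries <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(s) <- c("genotype_summaries", "data.frame")
  s
}

#' Read and write harvest-trait CSVs
#'
#' Columns `genotype,yield,height,maturity`.
#'
#' @param traits a `harvest_traits` data frame.
#' @param path file path.
#' @export
write_harvest_traits <- function(traits, path) {
  stopifnot(is.data.frame(traits))
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_harvest_traits
#' @export
read_harvest_traits <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "yield", "height", "maturity")
  if (!all(need %in% names(t))) {
    stop("traits CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  class(t) <- c("harvest_traits", "data.frame")
  t
}

#' Read and write thermal frames as plain-text matrices
#'
#' Frames are stored as whitespace-separated numeric matrices (one image
#' row per line); polygons as CSV with columns
#' `polygon_id,vertex_index,x,y` (0-based pixel coordinates, x = column,
#' y = row).
#'
#' @param frame numeric matrix of pixel temperatures.
#' @param polygons named list of vertex data frames (`x`, `y`).
#' @param path file path.
#' @export
write_frame_matrix <- function(frame, path) {
  stopifnot(is.matrix(frame))
  utils::write.table(frame, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_matrix
#' @export
read_frame_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname write_frame_matrix
#' @export
write_polygons <- function(polygons, path) {
  stopifnot(is.list(polygons), !is.null(names(polygons)))
  rows <- do.call(rbind, lapply(names(polygons), function(id) {
    p <- polygons[[id]]
    data.frame(polygon_id = id, vertex_index = seq_len(nrow(p)) - 1L,
               x = p$x, y = p$y, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frame_matrix
#' @export
read_polygons <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(rows, rows$polygon_id), function(p) {
    p <- p[order(p$vertex_index), ]
    data.frame(x = p$x, y = p$y)
  })
}
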