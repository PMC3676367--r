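#' Generate a resolvable incomplete-block field layout
#'
#' Builds a randomised field layout of the kind used for replicated
#' phenotyping trials: replicates form contiguous superblocks, and within
#' each replicate the genotypes are partitioned into incomplete blocks of
#' `block_size` plots, in the spirit of an alpha design. Block membership
#' and plot order are randomised under `seed`. The construction is a
#' resolvable randomised incomplete-block layout; it does not optimise the
#' concurrence pattern, so it is not guaranteed alpha-optimal — only the
#' randomisation structure matters for the downstream temperature analysis.
#'
#' Plots are laid out row-major: a trial with `n_genotypes * n_reps` plots
#' at `plots_per_row` plots per field row occupies
#' `n_genotypes * n_reps / plots_per_row` rows. Rows and columns are
#' 1-based throughout (field-book convention).
#'
#' @param n_genotypes number of distinct genotypes.
#' @param n_reps complete replicates per genotype.
#' @param plots_per_row plots in one field row.
#' @param block_size plots per incomplete block; must divide `n_genotypes`
#'   and be at least 2.
#' @param seed integer seed controlling the randomisation.
#' @param trial_id identifier carried into all downstream records.
#' @param genotype_ids optional character vector of genotype identifiers
#'   (defaults to `G001`, `G002`, ...).
#' @return A `trial_design` object: a list with the layout dimensions and
#'   an `assignments` data frame (`row`, `col`, `genotype`, `replicate`,
#'   `block`).
#' @examples
#' d <- generate_layout(192, 2, 16, 8, seed = 1)
#' d$n_rows              # 24
#' validate_design(d)    # character(0)
#' @export
generate_layout <- function(n_genotypes, n_reps = 2, plots_per_row = 16,
                            block_size = 8, seed, trial_id = "trial1",
                            genotype_ids = NULL) {
  n_genotypes <- check_count(n_genotypes, "n_genotypes", 1L)
  n_reps <- check_count(n_reps, "n_reps", 1L)
  plots_per_row <- check_count(plots_per_row, "plots_per_row", 1L)
  block_size <- check_count(block_size, "block_size", 1L)
  if (block_size < 2L) {
    stop("`block_size` must be at least 2", call. = FALSE)
  }
  n_plots <- n_genotypes * n_reps
  if (n_plots %% plots_per_row != 0L) {
    stop(sprintf(
      "dimension error: %d genotypes x %d replicates is not divisible by %d plots per row",
      n_genotypes, n_reps, plots_per_row), call. = FALSE)
  }
  if (n_genotypes %% block_size != 0L) {
    stop(sprintf(
      "dimension error: block_size %d must divide n_genotypes %d for a resolvable layout",
      block_size, n_genotypes), call. = FALSE)
  }
  if (is.null(genotype_ids)) {
    genotype_ids <- sprintf("G%03d", seq_len(n_genotypes))
  }
  if (length(genotype_ids) != n_genotypes || anyDuplicated(genotype_ids)) {
    stop("`genotype_ids` must supply one distinct id per genotype", call. = FALSE)
  }
  n_rows <- n_plots %/% plots_per_row
  n_blocks <- n_genotypes %/% block_size

  sequence <- with_seed(seed, {
    unlist(lapply(seq_len(n_reps), function(rep) {
      perm <- sample(genotype_ids)                       # genotypes into blocks
      blocks <- split(perm, rep(seq_len(n_blocks), each = block_size))
      blocks <- blocks[sample(n_blocks)]                 # block order in the field
      unlist(blocks, use.names = FALSE)
    }), use.names = FALSE)
  })

  idx <- seq_len(n_plots)
  assignments <- data.frame(
    row = (idx - 1L) %/% plots_per_row + 1L,
    col = (idx - 1L) %% plots_per_row + 1L,
    genotype = sequence,
    replicate = (idx - 1L) %/% n_genotypes + 1L,
    block = paste0("R", (idx - 1L) %/% n_genotypes + 1L, "B",
                   ((idx - 1L) %% n_genotypes) %/% block_size + 1L),
    stringsAsFactors = FALSE
  )

  structure(
    list(trial_id = trial_id, n_rows = n_rows, plots_per_row = plots_per_row,
         n_genotypes = n_genotypes, n_reps = n_reps, block_size = block_size,
         assignments = assignments),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "Trial design '%s': %d genotypes x %d replicates, %d rows x %d plots/row, block size %d\n",
    x$trial_id, x$n_genotypes, x$n_reps, x$n_rows, x$plots_per_row, x$block_size))
  invisible(x)
}

#' Validate a trial design against its structural invariants
#'
#' Checks genotype replication counts, grid completeness, duplicate plot
#' assignments, and incomplete-block sizes. Violations are reported, not
#' raised, so a partially corrupted design (for example after manual
#' editing of a field book) can be diagnosed in one pass.
#'
#' @param design a `trial_design` object.
#' @return Character vector of human-readable violations; empty when the
#'   design satisfies every invariant.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  a <- design$assignments
  bad <- character(0)

  counts <- table(a$genotype)
  wrong <- counts[counts != design$n_reps]
  if (length(wrong) > 0) {
    bad <- c(bad, sprintf("genotype %s appears %d times (expected %d)",
                          names(wrong), as.integer(wrong), design$n_reps))
  }
  if (length(counts) != design$n_genotypes) {
    bad <- c(bad, sprintf("design has %d distinct genotypes (expected %d)",
                          length(counts), design$n_genotypes))
  }

  cell <- paste(a$row, a$col, sep = ",")
  dup <- unique(cell[duplicated(cell)])
  if (length(dup) > 0) {
    bad <- c(bad, sprintf("plot (%s) assigned more than once", dup))
  }
  want <- as.vector(outer(seq_len(design$n_rows), seq_len(design$plots_per_row),
                          paste, sep = ","))
  miss <- setdiff(want, cell)
  if (length(miss) > 0) {
    bad <- c(bad, sprintf("plot (%s) has no assignment", miss))
  }

  bsz <- table(a$block)
  badblk <- bsz[bsz != design$block_size]
  if (length(badblk) > 0) {
    bad <- c(bad, sprintf("block %s has %d plots (expected %d)",
                          names(badblk), as.integer(badblk), design$block_size))
  }
  bad
}

#' Write / read a trial design as CSV
#'
#' Columns `trial_id,row,col,genotype,replicate,block` with 1-based row
#' and column indices. The round trip is lossless.
#'
#' @param design a `trial_design` object.
#' @param path file path.
#' @return `read_design()` returns a `trial_design`; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  out <- cbind(trial_id = design$trial_id, design$assignments)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(trial_id = "character", row = "integer",
                                      col = "integer", genotype = "character",
                                      replicate = "integer", block = "character"))
  need <- c("trial_id", "row", "col", "genotype", "replicate", "block")
  if (!all(need %in% names(a))) {
    stop("design CSV must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  trial_id <- unique(a$trial_id)
  if (length(trial_id) != 1L) stop("design CSV mixes trial ids", call. = FALSE)
  n_rows <- max(a$row)
  plots_per_row <- max(a$col)
  counts <- table(a$genotype)
  structure(
    list(trial_id = trial_id, n_rows = n_rows, plots_per_row = plots_per_row,
         n_genotypes = length(counts), n_reps = as.integer(max(counts)),
         block_size = as.integer(max(table(a$block))),
         assignments = a[order(a$row, a$col),
                         c("row", "col", "genotype", "replicate", "block")]),
    class = "trial_design"
  )
}
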