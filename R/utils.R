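# Internal helpers shared across modules.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  check_seed(seed)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed) || abs(seed) >= 2^31) {
    stop("`seed` must be a single integer (|seed| < 2^31)", call. = FALSE)
  }
  invisible(as.integer(seed))
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Key a plot by position within a trial.
plot_key <- function(trial_id, row, col) {
  paste(trial_id, row, col, sep = ":")
}
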