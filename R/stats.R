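#' Two-way ANOVA of normalised plot temperatures
#'
#' Tests the consistency of genotype differences across measurement
#' days: sources Genotype, Days, Days x Genotype interaction, and Error,
#' with F ratios against the error mean square. A non-significant
#' interaction indicates stable genotype ranking over the season.
#'
#' For balanced data (equal replicates in every genotype-by-day cell)
#' the orthogonal decomposition is computed directly from cell and
#' marginal means. Unbalanced data fall back to sequential (Type I) sums
#' of squares in the order Genotype, Days, Interaction, and a note is
#' emitted.
#'
#' @param data data frame with columns `genotype`, `day`, `value` (one
#'   row per replicate plot measurement).
#' @return An `anova_table` data frame: `source`, `df`, `ss`, `ms`, `f`,
#'   `p`.
#' @export
anova_twoway <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("genotype", "day", "value") %in% names(data)))
  g <- factor(data$genotype)
  d <- factor(data$day)
  y <- data$value
  if (nlevels(g) < 2) stop("need at least 2 genotypes", call. = FALSE)
  if (nlevels(d) < 2) stop("need at least 2 days", call. = FALSE)
  cells <- table(g, d)
  if (any(cells == 0)) {
    stop("empty genotype x day cell: design not analysable", call. = FALSE)
  }
  if (all(cells == 1)) {
    stop("one replicate per cell leaves no error term", call. = FALSE)
  }

  if (length(unique(as.vector(cells))) == 1L) {
    # balanced: orthogonal decomposition from marginal and cell means
    r <- as.vector(cells)[1]
    grand <- mean(y)
    mg <- tapply(y, g, mean)
    md <- tapply(y, d, mean)
    mc <- tapply(y, list(g, d), mean)
    ss_g <- r * nlevels(d) * sum((mg - grand)^2)
    ss_d <- r * nlevels(g) * sum((md - grand)^2)
    ss_int <- r * sum((mc - outer(mg, md, "+") + grand)^2)
    ss_e <- sum((y - mc[cbind(g, d)])^2)
    df <- c(nlevels(g) - 1L, nlevels(d) - 1L,
            (nlevels(g) - 1L) * (nlevels(d) - 1L),
            nlevels(g) * nlevels(d) * (r - 1L))
    ss <- c(ss_g, ss_d, ss_int, ss_e)
  } else {
    message("unbalanced data: sequential (Type I) sums of squares in order Genotype, Days, Interaction")
    fit <- stats::lm(y ~ g * d)
    tab <- stats::anova(fit)
    df <- tab$Df
    ss <- tab$`Sum Sq`
  }
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  out <- data.frame(
    source = c("Genotype", "Days", "Days x Genotype", "Error"),
    df = as.integer(df), ss = ss, ms = ms, f = f, p = p,
    stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' One-way ANOVA on per-day genotype means
#'
#' Treats each genotype's daily means as replicates: between-genotype
#' versus within-genotype (across days) variation. The percentage of
#' total variation explained by genotypes quantifies how much of the
#' normalised temperature signal is genotypic.
#'
#' @param means numeric matrix, genotypes x days (complete).
#' @return List of class `anova_means`: `table` (an `anova_table` with
#'   Between-genotype, Within-genotype rows) and `variance_explained`
#'   (percent).
#' @export
anova_on_means <- function(means) {
  stopifnot(is.matrix(means), is.numeric(means))
  if (anyNA(means)) stop("means table must be complete", call. = FALSE)
  G <- nrow(means); D <- ncol(means)
  if (D < 2) stop("need at least 2 days", call. = FALSE)
  if (G < 2) stop("need at least 2 genotypes", call. = FALSE)
  grand <- mean(means)
  rm_ <- rowMeans(means)
  ss_b <- D * sum((rm_ - grand)^2)
  ss_w <- sum((means - rm_)^2)
  df_b <- G - 1L
  df_w <- G * (D - 1L)
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  f <- ms_b / ms_w
  tab <- data.frame(
    source = c("Between-genotype", "Within-genotype"),
    df = c(df_b, df_w), ss = c(ss_b, ss_w), ms = c(ms_b, ms_w),
    f = c(f, NA), p = c(stats::pf(f, df_b, df_w, lower.tail = FALSE), NA),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("anova_table", "data.frame")
  structure(list(table = tab,
                 variance_explained = 100 * ss_b / (ss_b + ss_w)),
            class = "anova_means")
}

#' Least significant difference between two means
#'
#' Standard t-based LSD for comparing two means estimated with `n_per_mean`
#' observations each:
#'   LSD = t(1 - alpha/2, df_error) * sqrt(2 * ms_error / n_per_mean).
#'
#' @param ms_error error mean square.
#' @param df_error error degrees of freedom.
#' @param n_per_mean observations per mean.
#' @param alpha significance level in (0, 1).
#' @return LSD in the units of the response (deg C here).
#' @export
lsd <- function(ms_error, df_error, n_per_mean, alpha = 0.05) {
  check_number(ms_error, "ms_error", min = 0, strict_min = TRUE)
  df_error <- check_count(df_error, "df_error", 1L)
  n_per_mean <- check_count(n_per_mean, "n_per_mean", 1L)
  check_number(alpha, "alpha", min = 0, max = 1)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  stats::qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / n_per_mean)
}

#' Monte-Carlo randomisation test of genotype differences
#'
#' Asks whether the observed spread of genotype means could have arisen
#' by chance: genotype labels are repeatedly re-randomised independently
#' within each day, and for each randomisation the one-way ANOVA F, the
#' range of 'genotype' means, and the apparent LSD (the LSD computed
#' from the null within-genotype mean square — the difference magnitude
#' that pure chance can generate) are recorded. The permutation p-value
#' uses the add-one correction (b + 1) / (m + 1).
#'
#' @param means numeric matrix, genotypes x days, of per-day genotype
#'   means; rownames identify genotypes.
#' @param n_reps number of label randomisations.
#' @param alpha level for the apparent LSD.
#' @param seed integer seed.
#' @return A `randomization_result` list: `observed_f`, `p_value`,
#'   `observed_range`, `apparent_lsd` (mean of the per-randomisation
#'   null LSDs), `null_ranges` (summary of null genotype-mean ranges),
#'   per-randomisation vectors `null_f`, `null_range`, `null_lsd`,
#'   `n_reps`, `seed`.
#' @export
monte_carlo_randomization <- function(means, n_reps = 1000, alpha = 0.05,
                                      seed) {
  stopifnot(is.matrix(means), is.numeric(means))
  n_reps <- check_count(n_reps, "n_reps", 1L)
  G <- nrow(means); D <- ncol(means)
  if (G < 2 || D < 2) stop("need at least 2 genotypes and 2 days", call. = FALSE)

  one_way <- function(x) {
    rm_ <- rowMeans(x)
    grand <- mean(rm_)
    ss_b <- D * sum((rm_ - grand)^2)
    ss_w <- sum((x - rm_)^2)
    ms_w <- ss_w / (G * (D - 1))
    c(f = (ss_b / (G - 1)) / ms_w, range = max(rm_) - min(rm_), ms_w = ms_w)
  }
  obs <- one_way(means)

  null_f <- null_range <- null_lsd <- numeric(n_reps)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      perm <- means
      for (j in seq_len(D)) perm[, j] <- means[sample.int(G), j]
      s <- one_way(perm)
      null_f[b] <- s["f"]
      null_range[b] <- s["range"]
      null_lsd[b] <- lsd(s[["ms_w"]], G * (D - 1L), D, alpha)
    }
  })

  structure(
    list(observed_f = unname(obs["f"]),
         p_value = (sum(null_f >= obs["f"]) + 1) / (n_reps + 1),
         observed_range = unname(obs["range"]),
         apparent_lsd = mean(null_lsd),
         null_ranges = summary(null_range),
         null_f = null_f, null_range = null_range, null_lsd = null_lsd,
         n_reps = n_reps, alpha = alpha, seed = check_seed(seed)),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo randomisation (%d reps): F = %.3f, p = %.4f\nobserved genotype-mean range = %.3f, apparent LSD (null, %d%%) = %.3f\n",
    x$n_reps, x$observed_f, x$p_value, x$observed_range,
    round(100 * (1 - x$alpha)), x$apparent_lsd))
  invisible(x)
}

#' Spearman rank correlation with average ranks for ties
#'
#' Pearson correlation of the average (midrank) ranks of the two
#' vectors.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Rank consistency of the extreme genotypes
#'
#' Selects the `k` coolest and `k` hottest genotypes by mean rank across
#' occasions (ties in mean rank broken by genotype identifier order) and
#' computes Spearman's rho between every pair of occasions on that
#' 2k-genotype subset — the screening question being whether the
#' extremes, the genotypes one would select, rank consistently.
#'
#' @param means numeric matrix, genotypes x occasions, with rownames.
#' @param k genotypes taken from each extreme; `2 * k <= nrow(means)`.
#' @return List: `genotypes` (the 2k selected ids), `low`, `high`, and
#'   `rho` (occasions x occasions Spearman matrix on the subset).
#' @export
extreme_subset_rho <- function(means, k) {
  stopifnot(is.matrix(means), !is.null(rownames(means)))
  k <- check_count(k, "k", 1L)
  G <- nrow(means)
  if (2 * k > G) stop("2k exceeds the number of genotypes", call. = FALSE)
  ranks <- apply(means, 2, rank, ties.method = "average")
  mean_rank <- rowMeans(ranks)
  ord <- order(mean_rank, rownames(means))
  low <- rownames(means)[ord[seq_len(k)]]
  high <- rownames(means)[ord[seq(G - k + 1L, G)]]
  sel <- c(low, high)
  sub <- means[sel, , drop = FALSE]
  O <- ncol(sub)
  rho <- diag(1, O)
  dimnames(rho) <- list(colnames(means), colnames(means))
  if (O > 1) {
    for (i in seq_len(O - 1)) {
      for (j in seq(i + 1, O)) {
        rho[i, j] <- rho[j, i] <- spearman_rho(sub[, i], sub[, j])
      }
    }
  }
  list(genotypes = sel, low = low, high = high, rho = rho)
}

#' Correlation matrix across measurement occasions
#'
#' Pearson correlations between normalised genotype temperatures on
#' every pair of occasions (trial-by-day combinations). When a `days`
#' mapping is supplied, per-day mean columns (the average of that day's
#' occasions) are appended before correlating, showing the replication
#' gain from repeated measurement within a day.
#'
#' @param means numeric matrix, genotypes x occasions, with column
#'   names.
#' @param days optional vector (length `ncol(means)`) assigning each
#'   occasion to a day; day-mean columns `"<day>_Mean"` are appended.
#' @return Symmetric Pearson correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(means, days = NULL) {
  stopifnot(is.matrix(means), is.numeric(means))
  if (ncol(means) < 2) stop("need at least 2 occasions", call. = FALSE)
  if (nrow(means) < 3) stop("need at least 3 genotypes per occasion", call. = FALSE)
  m <- means
  if (!is.null(days)) {
    stopifnot(length(days) == ncol(means))
    for (d in unique(days)) {
      m <- cbind(m, rowMeans(means[, days == d, drop = FALSE]))
      colnames(m)[ncol(m)] <- paste0(d, "_Mean")
    }
  }
  stats::cor(m)
}

#' Forward stepwise regression of yield on phenotypic predictors
#'
#' Forward selection: at each step the candidate predictor giving the
#' largest coefficient of determination is added if its partial-F
#' p-value is below `alpha_enter`; selection stops when no candidate
#' qualifies. Candidates that do not increase the model rank (collinear
#' with terms already entered) are skipped with a warning. Cumulative
#' r-squared is non-decreasing by construction and bounded by the full
#' model's r-squared.
#'
#' @param y numeric response (yield).
#' @param predictors data frame of numeric candidate predictors
#'   (canopy temperature, maturity, height, ...). Rows with missing
#'   values in `y` or any predictor are dropped (complete cases).
#' @param alpha_enter entry threshold for the partial-F p-value.
#' @return A `stepwise_result` list: `steps` data frame (`step`, `term`,
#'   `r2_cum`, `partial_f`, `p_value`), `full_model_r2`, `n`.
#' @export
forward_stepwise <- function(y, predictors, alpha_enter = 0.05) {
  stopifnot(is.numeric(y), is.data.frame(predictors))
  if (ncol(predictors) < 2) stop("need at least 2 candidate predictors", call. = FALSE)
  cc <- stats::complete.cases(y, predictors)
  y <- y[cc]
  X <- predictors[cc, , drop = FALSE]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response is constant", call. = FALSE)

  full <- stats::lm(y ~ ., data = X)
  full_r2 <- 1 - sum(stats::residuals(full)^2) / tss

  selected <- character(0)
  remaining <- names(X)
  rss_cur <- tss
  rank_cur <- 1L
  steps <- list()
  repeat {
    if (length(remaining) == 0) break
    cand <- lapply(remaining, function(term) {
      fit <- stats::lm(y ~ ., data = X[, c(selected, term), drop = FALSE])
      list(term = term, rss = sum(stats::residuals(fit)^2), rank = fit$rank)
    })
    ranks <- vapply(cand, `[[`, integer(1), "rank")
    degenerate <- ranks <= rank_cur
    if (any(degenerate)) {
      warning("skipping collinear predictor(s): ",
              paste(vapply(cand[degenerate], `[[`, character(1), "term"),
                    collapse = ", "), call. = FALSE)
      cand <- cand[!degenerate]
      remaining <- vapply(cand, `[[`, character(1), "term")
      if (length(cand) == 0) break
    }
    rss <- vapply(cand, `[[`, numeric(1), "rss")
    best <- which.min(rss)
    df_res <- n - (rank_cur + 1L)
    if (df_res <= 0) break
    f <- (rss_cur - rss[best]) / (rss[best] / df_res)
    p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
    if (p >= alpha_enter) break
    term <- cand[[best]]$term
    selected <- c(selected, term)
    remaining <- setdiff(remaining, term)
    rss_cur <- rss[best]
    rank_cur <- rank_cur + 1L
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, term = term,
      r2_cum = 1 - rss_cur / tss, partial_f = f, p_value = p,
      stringsAsFactors = FALSE
    )
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(0), term = character(0), r2_cum = numeric(0),
               partial_f = numeric(0), p_value = numeric(0))
  structure(list(steps = steps, full_model_r2 = full_r2, n = n),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("Forward stepwise selection (n = %d, full-model r2 = %.3f)\n",
              x$n, x$full_model_r2))
  if (nrow(x$steps) == 0) {
    cat("no predictor entered\n")
  } else {
    print(transform(x$steps, r2_pct = sprintf("%.1f%%", 100 * r2_cum)),
          row.names = FALSE)
  }
  invisible(x)
}
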