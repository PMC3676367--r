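# Independent brute-force oracles, kept deliberately naive: direct
# summation, enumeration and generalised-inverse solves, sharing no code
# with the implementation under test.

# Two-way crossed ANOVA sums of squares by explicit summation over cells.
oracle_twoway_ss <- function(df) {
  grand <- mean(df$value)
  ss_g <- 0; ss_d <- 0; ss_int <- 0; ss_e <- 0
  # per-observation decomposition (balanced designs only)
  for (i in seq_len(nrow(df))) {
    g <- df$genotype[i]; d <- df$day[i]
    mg <- mean(df$value[df$genotype == g])
    md <- mean(df$value[df$day == d])
    mc <- mean(df$value[df$genotype == g & df$day == d])
    ss_g <- ss_g + (mg - grand)^2 / 1
    ss_d <- ss_d + (md - grand)^2
    ss_int <- ss_int + (mc - mg - md + grand)^2
    ss_e <- ss_e + (df$value[i] - mc)^2
  }
  c(genotype = ss_g, days = ss_d, interaction = ss_int, error = ss_e)
}

# Midranks by counting, no call to rank().
oracle_midranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midranks(x); ry <- oracle_midranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# RSS of an OLS fit by generalised inverse of the normal equations.
oracle_rss <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  beta <- MASS::ginv(t(X) %*% X) %*% t(X) %*% y
  sum((y - X %*% beta)^2)
}

# Forward-selection path by exhaustive search: at each step evaluate the
# RSS of every candidate superset via the generalised-inverse solve.
oracle_forward_path <- function(y, X, alpha = 0.05) {
  n <- length(y)
  selected <- character(0)
  remaining <- names(X)
  rss_cur <- sum((y - mean(y))^2)
  path <- character(0)
  repeat {
    if (length(remaining) == 0) break
    rss <- vapply(remaining, function(term) {
      oracle_rss(y, X[, c(selected, term), drop = FALSE])
    }, numeric(1))
    best <- names(which.min(rss))
    df_res <- n - (length(selected) + 2L)
    if (df_res <= 0) break
    f <- (rss_cur - rss[best]) / (rss[best] / df_res)
    p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
    if (p >= alpha) break
    path <- c(path, best)
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    rss_cur <- rss[[best]]
  }
  path
}

# Centred genotype/image effects by a dense generalised-inverse solve of
# the two-factor dummy regression.
oracle_additive_effects <- function(obs) {
  g <- factor(obs$genotype); img <- factor(obs$image_id)
  X <- cbind(1,
             stats::model.matrix(~ 0 + g)[, , drop = FALSE],
             stats::model.matrix(~ 0 + img)[, , drop = FALSE])
  beta <- MASS::ginv(t(X) %*% X) %*% t(X) %*% obs$temperature
  ge <- beta[1 + seq_len(nlevels(g))]
  names(ge) <- levels(g)
  ge - mean(ge)
}

# F-distribution upper tail through the beta CDF, independent of pf().
oracle_f_p <- function(f, d1, d2) {
  1 - stats::pbeta(d1 * f / (d1 * f + d2), d1 / 2, d2 / 2)
}
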