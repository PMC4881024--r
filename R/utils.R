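# Derive a reproducible 31-bit seed for a named random substream from a
# master seed, so changing how one component draws leaves the others intact.
substream_seed <- function(master, name) {
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v)) %% 46337L
  ((as.integer(master) %% 46337L) * 46337L + h) %% 2147483647L
}

with_substream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(master, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# Vectorized two-sided Student t-test with pooled variance from group
# summaries. Zero pooled variance: p = 1 when the means agree, 0 otherwise.
# Groups with < 2 observations give NA.
pooled_t <- function(mean_a, mean_b, var_a, var_b, n_a, n_b) {
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * var_a + (n_b - 1) * var_b) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  stat <- (mean_b - mean_a) / se
  p <- 2 * stats::pt(-abs(stat), df)
  zero <- !is.na(se) & se == 0
  p[zero & mean_b == mean_a] <- 1
  p[zero & mean_b != mean_a] <- 0
  stat[zero & mean_b == mean_a] <- 0
  bad <- is.na(n_a) | is.na(n_b) | n_a < 2 | n_b < 2
  p[bad] <- NA_real_
  stat[bad] <- NA_real_
  list(statistic = stat, p.value = p, df = df, estimate = mean_b - mean_a)
}

row_means_masked <- function(vals, use) {
  out <- rowSums(ifelse(use, vals, 0)) / rowSums(use)
  out[rowSums(use) == 0] <- NA_real_
  out
}

row_vars_masked <- function(vals, use) {
  n <- rowSums(use)
  m <- row_means_masked(vals, use)
  ss <- rowSums(ifelse(use, (vals - m)^2, 0))
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  out
}
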