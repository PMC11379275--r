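# Independent oracles and fixture builders shared across the suite.

# Brute-force Theil-Sen: explicit double loop over all pairs, kept deliberately
# naive and separate from the vectorised implementation it checks.
oracle_theil_sen <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  slope <- median(slopes)
  list(slope = slope, intercept = median(y - slope * x))
}

# Hand-rolled trimmed mean by explicit order statistics.
oracle_trimmed_mean <- function(x, trim) {
  n <- length(x)
  g <- floor(trim * n)
  s <- sort(x)
  mean(s[(g + 1):(n - g)])
}

# Write a records CSV from a data frame of (possibly partial) columns.
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Whole-animal nitrogen per oyster from the printed constants, computed
# directly (independent of the registry/calculator code path).
oracle_per_oyster_g <- function(H) {
  0.0770 * (1.42e-5 * H^2.607) + 0.0019 * (0.00039 * H^2.58)
}
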