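# Robust estimation and hypothesis-testing machinery: trimmed means,
# percentile-bootstrap one-way tests for independent groups, Theil-Sen
# regression on ln-transformed data, and bootstrap comparison of two groups'
# regression slopes and intercepts. Group tests use 20% trimming by default;
# dry-weight ~ shell-height comparisons run on the ln-ln scale where the
# power relationship is linear.

# run code with a locally scoped RNG state so stochastic routines are
# reproducible for a fixed seed and never disturb the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Trimmed mean
#'
#' Mean after discarding `floor(trim * n)` smallest and largest order
#' statistics; `trim = 0` is the arithmetic mean. Group comparisons in this
#' package use 20% trimming, which keeps the estimator efficient under
#' normality while bounding the influence of outliers.
#'
#' @param x Non-empty numeric vector.
#' @param trim Trim fraction in \[0, 0.5).
#' @return The trimmed mean.
#' @examples
#' trimmed_mean(c(1, 2, 3, 4, 100), 0.2)  # 3
#' @export
trimmed_mean <- function(x, trim = 0.2) {
  if (length(x) == 0 || anyNA(x)) stop("x must be non-empty with no NA", call. = FALSE)
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)", call. = FALSE)
  mean(x, trim = trim)
}

#' Winsorized variance
#'
#' Sample variance after replacing the `floor(trim * n)` smallest values by
#' the smallest retained value and likewise in the upper tail. This is the
#' dispersion measure that pairs with the trimmed mean in the one-way test's
#' standard errors.
#'
#' @inheritParams trimmed_mean
#' @return The winsorized sample variance (denominator n - 1).
#' @export
winsorized_variance <- function(x, trim = 0.2) {
  if (length(x) < 2 || anyNA(x)) stop("need >= 2 non-NA values", call. = FALSE)
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)", call. = FALSE)
  n <- length(x)
  g <- floor(trim * n)
  s <- sort(x)
  if (g > 0) {
    s[1:g] <- s[g + 1]
    s[(n - g + 1):n] <- s[n - g]
  }
  var(s)
}

# trimmed-mean analog of the heteroscedastic one-way F statistic:
# groups weighted by inverse squared standard errors built from winsorized
# variances and effective (post-trim) sample sizes
trimmed_oneway_stat <- function(groups, trim = 0.2) {
  J <- length(groups)
  h <- vapply(groups, function(g) length(g) - 2 * floor(trim * length(g)), 0)
  tm <- vapply(groups, trimmed_mean, 0, trim = trim)
  d <- vapply(groups, function(g) {
    n <- length(g)
    (n - 1) * winsorized_variance(g, trim) /
      ((n - 2 * floor(trim * n)) * (n - 2 * floor(trim * n) - 1))
  }, 0)
  # a constant (zero winsorized variance) group must not produce 0/0: floor
  # its squared SE so separated point masses give a huge finite statistic
  w <- 1 / pmax(d, 1e-300)
  U <- sum(w)
  xt <- sum(w * tm) / U
  A <- sum(w * (tm - xt)^2) / (J - 1)
  B <- 2 * (J - 2) / (J^2 - 1) * sum((1 - w / U)^2 / (h - 1))
  A / (1 + B)
}

#' Percentile-bootstrap one-way test on trimmed means
#'
#' Robust analog of one-way ANOVA for two or more independent groups. The
#' observed statistic is the trimmed-mean version of the heteroscedastic
#' one-way F statistic (winsorized-variance weights). The null reference
#' distribution is built by centering each group at its own trimmed mean and
#' resampling with replacement within groups `B` times; the p-value is the
#' proportion of bootstrap statistics at least as large as the observed one,
#' floored at `1/(B + 1)` so it is never reported as exactly zero.
#'
#' @param groups List of >= 2 numeric vectors; each must keep at least one
#'   observation after trimming both tails.
#' @param trim Trim fraction (default 0.2).
#' @param B Number of bootstrap replicates (>= 100; default 599).
#' @param seed Integer seed; fixed seed gives identical results to all digits.
#' @return A `group_test` with `p_value`, `statistic`, `effect_size`,
#'   per-group trimmed means, `trim`, `B` and `seed`.
#' @examples
#' g <- list(rnorm(20), rnorm(20, 2))
#' bootstrap_oneway_trimmed(g, B = 599, seed = 1)
#' @export
bootstrap_oneway_trimmed <- function(groups, trim = 0.2, B = 599, seed = NULL) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  for (g in groups) {
    if (length(g) < 2 * floor(trim * length(g)) + 2) {
      stop("a group is too small to trim at trim = ", trim, call. = FALSE)
    }
  }
  obs <- trimmed_oneway_stat(groups, trim)
  centered <- lapply(groups, function(g) g - trimmed_mean(g, trim))
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      trimmed_oneway_stat(
        lapply(centered, function(g) g[sample.int(length(g), replace = TRUE)]),
        trim
      )
    }, 0)
  })
  p <- max(mean(boot >= obs), 1 / (B + 1))
  structure(list(
    p_value = p, statistic = obs,
    effect_size = explanatory_effect_size(groups, trim),
    trimmed_means = vapply(groups, trimmed_mean, 0, trim = trim),
    trim = trim, B = B, seed = seed
  ), class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat("Percentile-bootstrap one-way test on ", 100 * x$trim,
      "% trimmed means\n", sep = "")
  cat("  groups: ", length(x$trimmed_means), "; trimmed means: ",
      paste(signif(x$trimmed_means, 4), collapse = ", "), "\n", sep = "")
  cat(sprintf("  statistic = %.4g, p = %.4g (B = %d), effect size = %.3g\n",
              x$statistic, x$p_value, x$B, x$effect_size))
  invisible(x)
}

# normal-consistency constant: winsorized variance of N(0,1) at trim gamma,
# so W/ws_const estimates sigma^2 under normality
winsor_consistency <- function(trim) {
  q <- qnorm(1 - trim)
  (1 - 2 * trim) - 2 * q * dnorm(q) + 2 * trim * q^2
}

#' Explanatory effect size for a one-way trimmed-mean comparison
#'
#' Scale-free measure of how much of the total variation is between groups:
#' the square root of the between-group variance of the trimmed means over
#' that quantity plus the mean within-group winsorized variance (rescaled by
#' the normal consistency constant so it estimates the within-group variance
#' under normality). Zero when all group trimmed means coincide; grows as any
#' group moves away from the rest.
#'
#' @inheritParams bootstrap_oneway_trimmed
#' @return Non-negative effect size in \[0, 1).
#' @export
explanatory_effect_size <- function(groups, trim = 0.2) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  tm <- vapply(groups, trimmed_mean, 0, trim = trim)
  between <- mean((tm - mean(tm))^2)
  within <- mean(vapply(groups, winsorized_variance, 0, trim = trim)) /
    winsor_consistency(trim)
  if (between == 0) return(0)
  sqrt(between / (between + within))
}

#' Construct a linear fit record
#'
#' @param slope,intercept Finite coefficients.
#' @param n Number of observations behind the fit.
#' @param method Fitting method tag (e.g. `"theil-sen"`).
#' @return A `linear_fit`.
#' @export
linear_fit <- function(slope, intercept, n = NA_integer_, method = "theil-sen") {
  if (!is.finite(slope) || !is.finite(intercept)) {
    stop("slope and intercept must be finite", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, n = n, method = method),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit %s> slope = %.6g, intercept = %.6g (n = %s)\n",
              x$method, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Theil-Sen regression
#'
#' Robust line fit: the slope is the median of all pairwise slopes
#' `(y_j - y_i)/(x_j - x_i)` over pairs with distinct x (pairs with tied x
#' are skipped), and the intercept is the median of `y_i - slope * x_i`.
#' Used on ln-transformed shell height and dry weight, where the allometric
#' power law is linear, and as the initializer for the nonlinear quantile
#' fits.
#'
#' @param x,y Equal-length numeric vectors, n >= 2, at least two distinct x.
#' @return A `linear_fit` with method `"theil-sen"`.
#' @examples
#' theil_sen_fit(c(0, 1, 2), c(0, 1, 0))  # slope 0, intercept 0
#' @export
theil_sen_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA", call. = FALSE)
  n <- length(x)
  dx <- outer(x, x, "-")
  keep <- upper.tri(dx) & dx != 0
  if (!any(keep)) stop("all x values are identical", call. = FALSE)
  slopes <- (outer(y, y, "-")[keep]) / dx[keep]
  slope <- median(slopes)
  intercept <- median(y - slope * x)
  linear_fit(slope = slope, intercept = intercept, n = n, method = "theil-sen")
}

#' Bootstrap comparison of two groups' Theil-Sen regressions
#'
#' Fits a Theil-Sen line per group on (x, y), then bootstraps the difference
#' in slopes and in intercepts by resampling (x, y) pairs jointly within each
#' group `B` times and refitting. Each two-sided percentile p-value is
#' `2 * min(P*(diff <= 0), P*(diff >= 0))`, clipped to \[0, 1\] and floored at
#' `1/(B + 1)`. Used to compare ln-ln dry-weight regressions between ploidy,
#' cultivation-practice and sub-region groups.
#'
#' @param xA,yA,xB,yB Group A and group B coordinates (each pair supports
#'   [theil_sen_fit()]).
#' @param B Bootstrap replicates (>= 200; default 599).
#' @param seed Integer seed for reproducibility.
#' @return A `regression_comparison` with `slope_p`, `intercept_p`, the two
#'   `linear_fit`s, `B` and `seed`.
#' @export
compare_group_regressions <- function(xA, yA, xB, yB, B = 599, seed = NULL) {
  if (B < 200) stop("B must be >= 200", call. = FALSE)
  fitA <- theil_sen_fit(xA, yA)
  fitB <- theil_sen_fit(xB, yB)
  boot <- with_seed(seed, {
    t(vapply(seq_len(B), function(i) {
      ia <- sample.int(length(xA), replace = TRUE)
      ib <- sample.int(length(xB), replace = TRUE)
      fa <- theil_sen_fit(xA[ia], yA[ia])
      fb <- theil_sen_fit(xB[ib], yB[ib])
      c(fa$slope - fb$slope, fa$intercept - fb$intercept)
    }, c(0, 0)))
  })
  pct_p <- function(d) {
    p <- 2 * min(mean(d <= 0), mean(d >= 0))
    min(max(p, 1 / (B + 1)), 1)
  }
  structure(list(
    slope_p = pct_p(boot[, 1]), intercept_p = pct_p(boot[, 2]),
    fit_A = fitA, fit_B = fitB, B = B, seed = seed
  ), class = "regression_comparison")
}

#' @export
print.regression_comparison <- function(x, ...) {
  cat("Bootstrap Theil-Sen regression comparison (B = ", x$B, ")\n", sep = "")
  cat(sprintf("  A: slope %.4g, intercept %.4g | B: slope %.4g, intercept %.4g\n",
              x$fit_A$slope, x$fit_A$intercept, x$fit_B$slope, x$fit_B$intercept))
  cat(sprintf("  slope p = %.4g, intercept p = %.4g\n", x$slope_p, x$intercept_p))
  invisible(x)
}
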