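# Synthetic oyster record generator. Emulates the statistical structure the
# analysis assumes — power-law allometry with multiplicative lognormal noise
# (additive on the ln scale, so weights stay positive and the ln-ln
# linearization holds exactly), truncated-normal nutrient concentrations,
# factor labels with sampling weights, independent per-column missingness —
# so every fitting and testing stage runs with no external data.

#' Specify a synthetic oyster dataset
#'
#' Defaults reproduce the regional study conditions: shell heights uniform on
#' 30-150 mm, tissue allometry `a = 1.42e-5, b = 2.607`, shell allometry
#' `a = 0.00039, b = 2.58`, ln-scale weight noise sd 0.3, tissue N ~
#' truncated-normal(7.70, 1.34) and shell N ~ truncated-normal(0.19, 0.10)
#' on (0, 100) (truncation by resampling, not clipping).
#'
#' @param n Number of records.
#' @param states,state_weights Factor levels and sampling weights (weights
#'   are normalised to sum to 1).
#' @param ploidy_levels,ploidy_weights Ploidy levels and weights.
#' @param practice_levels,practice_weights Cultivation-practice levels and
#'   weights.
#' @param height_dist `"uniform"` or `"lognormal"` on `height_range` (the
#'   lognormal takes meanlog at the log-midpoint of the range, sdlog a
#'   quarter of the log-range, truncated to the range by resampling).
#' @param height_range Shell-height range in mm.
#' @param tissue_allometry,shell_allometry Named `c(a =, b =)` power-law
#'   parameters.
#' @param ln_sd_tissue,ln_sd_shell ln-scale noise sd on the dry weights.
#' @param tissue_n_mean,tissue_n_sd,shell_n_mean,shell_n_sd Nutrient percent
#'   distributions (truncated-normal on (0, 100)).
#' @param allometry_groups Optional per-level allometry overrides: a list
#'   with `factor` (one of `"state"`, `"ploidy"`, `"practice"`) and `params`,
#'   a named list (by level) of lists with `tissue` and/or `shell`
#'   `c(a =, b =)` entries.
#' @param missing_rates Named per-column missingness probabilities over
#'   `tissue_dw_g`, `shell_dw_g`, `tissue_n_pct`, `shell_n_pct`.
#' @param seed Default seed used by [generate_records()].
#' @return A `generator_spec`.
#' @export
generator_spec <- function(
    n = 2000,
    states = c("ME", "MA", "CT", "NY", "MD", "VA", "NC"),
    state_weights = rep(1, length(states)),
    ploidy_levels = c("diploid", "triploid"),
    ploidy_weights = c(0.6, 0.4),
    practice_levels = c("floating_gear", "bottom_gear", "no_gear"),
    practice_weights = c(1, 1, 1),
    height_dist = c("uniform", "lognormal"),
    height_range = c(30, 150),
    tissue_allometry = c(a = 1.42e-5, b = 2.607),
    shell_allometry = c(a = 0.00039, b = 2.58),
    ln_sd_tissue = 0.3, ln_sd_shell = 0.3,
    tissue_n_mean = 7.70, tissue_n_sd = 1.34,
    shell_n_mean = 0.19, shell_n_sd = 0.10,
    allometry_groups = NULL,
    missing_rates = c(tissue_dw_g = 0, shell_dw_g = 0,
                      tissue_n_pct = 0, shell_n_pct = 0),
    seed = 1) {
  height_dist <- match.arg(height_dist)
  spec <- list(
    n = n, states = states, state_weights = state_weights / sum(state_weights),
    ploidy_levels = ploidy_levels,
    ploidy_weights = ploidy_weights / sum(ploidy_weights),
    practice_levels = practice_levels,
    practice_weights = practice_weights / sum(practice_weights),
    height_dist = height_dist, height_range = height_range,
    tissue_allometry = tissue_allometry, shell_allometry = shell_allometry,
    ln_sd_tissue = ln_sd_tissue, ln_sd_shell = ln_sd_shell,
    tissue_n_mean = tissue_n_mean, tissue_n_sd = tissue_n_sd,
    shell_n_mean = shell_n_mean, shell_n_sd = shell_n_sd,
    allometry_groups = allometry_groups,
    missing_rates = missing_rates, seed = seed
  )
  validate_generator_spec(spec)
  structure(spec, class = "generator_spec")
}

validate_generator_spec <- function(spec) {
  if (spec$n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(c(spec$ln_sd_tissue, spec$ln_sd_shell,
            spec$tissue_n_sd, spec$shell_n_sd) < 0)) {
    stop("noise sds must be >= 0", call. = FALSE)
  }
  if (any(spec$height_range <= 0) || diff(spec$height_range) < 0) {
    stop("height_range must be positive and ordered", call. = FALSE)
  }
  for (w in list(spec$state_weights, spec$ploidy_weights,
                 spec$practice_weights)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop("factor weights must be non-negative and sum to 1", call. = FALSE)
    }
  }
  for (p in list(spec$tissue_allometry, spec$shell_allometry)) {
    if (any(p[c("a", "b")] <= 0)) stop("allometry a, b must be > 0", call. = FALSE)
  }
  if (!is.null(spec$allometry_groups)) {
    ag <- spec$allometry_groups
    if (!ag$factor %in% c("state", "ploidy", "practice")) {
      stop("allometry_groups$factor must be state/ploidy/practice", call. = FALSE)
    }
  }
  if (any(spec$missing_rates < 0) || any(spec$missing_rates > 1)) {
    stop("missing rates must be in [0, 1]", call. = FALSE)
  }
  invisible(spec)
}

# truncated-normal draws on (lo, hi) by rejection, so the distribution is the
# conditional normal (clipping would pile mass at the bounds)
rnorm_trunc <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lo | out >= hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo | out[bad] >= hi]
  }
  out
}

#' Generate a synthetic oyster record table
#'
#' Draws `spec$n` records: factor labels from their weights, shell heights
#' from the height distribution, dry weights from the group's power law with
#' multiplicative lognormal noise, nutrient percents from truncated normals,
#' then masks each measured column independently at its missingness rate.
#' Identical spec and seed give identical records (and identical CSV bytes
#' through [write_oyster_records()]).
#'
#' @param spec A [generator_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return A validated oyster record data frame.
#' @export
generate_records <- function(spec = generator_spec(), seed = spec$seed) {
  validate_generator_spec(spec)
  n <- spec$n
  with_seed(seed, {
    state <- sample(spec$states, n, replace = TRUE, prob = spec$state_weights)
    ploidy <- sample(spec$ploidy_levels, n, replace = TRUE,
                     prob = spec$ploidy_weights)
    practice <- sample(spec$practice_levels, n, replace = TRUE,
                       prob = spec$practice_weights)
    H <- switch(spec$height_dist,
      uniform = runif(n, spec$height_range[1], spec$height_range[2]),
      lognormal = {
        lr <- log(spec$height_range)
        rnorm_trunc(n, mean = mean(lr), sd = diff(lr) / 4,
                    lo = lr[1], hi = lr[2]) |> exp()
      }
    )
    pars <- function(component, i) {
      base <- spec[[paste0(component, "_allometry")]]
      ag <- spec$allometry_groups
      if (!is.null(ag)) {
        lev <- switch(ag$factor, state = state[i], ploidy = ploidy[i],
                      practice = practice[i])
        ov <- ag$params[[lev]][[component]]
        if (!is.null(ov)) base[c("a", "b")] <- ov[c("a", "b")]
      }
      base
    }
    mk_weight <- function(component, ln_sd) {
      noise <- rnorm(n, 0, ln_sd)
      vapply(seq_len(n), function(i) {
        p <- pars(component, i)
        p[["a"]] * H[i]^p[["b"]]
      }, 0) * exp(noise)
    }
    tissue_dw <- mk_weight("tissue", spec$ln_sd_tissue)
    shell_dw <- mk_weight("shell", spec$ln_sd_shell)
    tissue_n <- rnorm_trunc(n, spec$tissue_n_mean, spec$tissue_n_sd)
    shell_n <- rnorm_trunc(n, spec$shell_n_mean, spec$shell_n_sd)

    rec <- data.frame(
      source_id = sprintf("synth-%05d", seq_len(n)),
      state = state, ploidy = ploidy, practice = practice,
      shell_height_mm = H,
      tissue_dw_g = tissue_dw, shell_dw_g = shell_dw,
      tissue_n_pct = tissue_n, shell_n_pct = shell_n,
      latitude = NA_real_, longitude = NA_real_,
      stringsAsFactors = FALSE
    )
    for (col in names(spec$missing_rates)) {
      r <- spec$missing_rates[[col]]
      if (r > 0) rec[[col]][runif(n) < r] <- NA_real_
    }
    rec
  })
}

#' Generate records with per-level nutrient shifts
#'
#' Runs [generate_records()] with the same seed, then adds `deltas[level]`
#' to the chosen nutrient column for records at each level of `factor`.
#' All-zero deltas reproduce [generate_records()] exactly; non-zero deltas
#' emulate group mean differences for power and type-I-error studies.
#'
#' @param spec A [generator_spec()].
#' @param factor `"state"`, `"ploidy"` or `"practice"`.
#' @param deltas Named numeric: one additive shift (percentage points) per
#'   factor level.
#' @param column `"tissue_n_pct"` or `"shell_n_pct"`.
#' @param seed Seed; defaults to `spec$seed`.
#' @return A record data frame.
#' @export
generate_group_shifted <- function(spec, factor = c("state", "ploidy", "practice"),
                                   deltas, column = c("tissue_n_pct", "shell_n_pct"),
                                   seed = spec$seed) {
  factor <- match.arg(factor)
  column <- match.arg(column)
  levels <- spec[[switch(factor, state = "states", ploidy = "ploidy_levels",
                         practice = "practice_levels")]]
  if (is.null(names(deltas)) || !setequal(names(deltas), levels)) {
    stop("deltas must be named with exactly the levels of '", factor, "'",
         call. = FALSE)
  }
  rec <- generate_records(spec, seed = seed)
  lab <- rec[[factor]]
  rec[[column]] <- rec[[column]] + unname(deltas[lab])
  rec
}
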