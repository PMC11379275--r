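# The calculator proper. Per-oyster nitrogen is the tau = 0.5 dry-weight
# prediction at the mean harvest shell height times the regional mean
# nitrogen concentration, summed over tissue and shell; farm totals scale
# linearly in harvest count. All arithmetic is in grams double precision;
# unit conversion happens only on output.

#' Describe a harvest scenario
#'
#' Captures the calculator's inputs: the number of oysters harvested, the
#' mean shell height at harvest, and report metadata (farm name, location,
#' ploidy, practice, harvest period). Metadata and period pass through to
#' reports and never affect the computed removal.
#'
#' @param count Number of oysters harvested (positive integer).
#' @param height Mean shell height at harvest, in `height_unit`.
#' @param height_unit `"mm"` or `"inch"`.
#' @param period Harvest period label ("1 day" to "5 years"); metadata only.
#' @param farm_name,location_text Free-text metadata.
#' @param latitude,longitude Optional decimal degrees; metadata only.
#' @param ploidy,practice Metadata labels; never switch the model used.
#' @return A `harvest_scenario`. Heights outside 20-200 mm warn
#'   (extrapolation beyond the data) but are accepted.
#' @export
harvest_scenario <- function(count, height, height_unit = c("mm", "inch"),
                             period = "1 year", farm_name = "",
                             location_text = "", latitude = NA_real_,
                             longitude = NA_real_, ploidy = "unknown",
                             practice = "unknown") {
  height_unit <- match.arg(height_unit)
  if (!is.finite(count) || count < 1 || count != floor(count)) {
    stop("count must be a positive integer", call. = FALSE)
  }
  height_mm <- convert_length(height, height_unit)
  if (height_mm < 20 || height_mm > 200) {
    warning("shell height ", signif(height_mm, 4),
            " mm is outside the documented 20-200 mm window; ",
            "prediction extrapolates beyond the data", call. = FALSE)
  }
  structure(list(
    count = count, height_mm = height_mm,
    height_input = height, height_unit = height_unit,
    period = period, farm_name = farm_name, location_text = location_text,
    latitude = latitude, longitude = longitude,
    ploidy = ploidy, practice = practice
  ), class = "harvest_scenario")
}

#' Nitrogen content of one oyster at a given shell height
#'
#' Tissue nitrogen is the tau = 0.5 tissue dry-weight prediction times the
#' regional mean tissue N concentration; shell nitrogen analogously; the
#' whole-animal value is their sum.
#'
#' @param H Shell height in mm (> 0).
#' @param registry An `anrc_registry` (default the shipped one).
#' @param model_group Optional subgroup label (e.g. `"diploid"`,
#'   `"no_gear"`): substitutes that subgroup's ln-ln-derived models for
#'   sensitivity analysis. The canonical calculation uses the single
#'   regional models (`NULL`).
#' @return A `nitrogen_per_oyster` list: `tissue_dw_g`, `shell_dw_g`,
#'   `tissue_n_g`, `shell_n_g`, `total_n_g` (= tissue + shell exactly).
#' @examples
#' per_oyster_nitrogen(77)
#' @export
per_oyster_nitrogen <- function(H, registry = default_registry(),
                                model_group = NULL) {
  if (!is.finite(H) || H <= 0) stop("shell height must be positive", call. = FALSE)
  validate_registry(registry)
  mt <- registry_model(registry, "tissue", group = model_group)
  ms <- registry_model(registry, "shell", group = model_group)
  tissue_dw <- predict_dry_weight(mt, H)
  shell_dw <- predict_dry_weight(ms, H)
  tissue_n <- tissue_dw * registry$nutrients$tissue$mean / 100
  shell_n <- shell_dw * registry$nutrients$shell$mean / 100
  structure(list(
    tissue_dw_g = tissue_dw, shell_dw_g = shell_dw,
    tissue_n_g = tissue_n, shell_n_g = shell_n,
    total_n_g = tissue_n + shell_n
  ), class = "nitrogen_per_oyster")
}

#' Farm-scale nitrogen removal at harvest
#'
#' Whole-animal nitrogen at the mean harvest height times the number of
#' oysters harvested. Totals are computed in grams and converted exactly to
#' kg and lb; when the registry carries tau = 0.25 / 0.75 band models, the
#' interquartile band of the farm total is attached.
#'
#' @param scenario A [harvest_scenario()].
#' @param registry An `anrc_registry`.
#' @param model_group Optional subgroup label, passed to
#'   [per_oyster_nitrogen()]; sensitivity analysis only.
#' @param band Attach the interquartile band when band models are present
#'   (default TRUE).
#' @return A `removal_estimate` with `per_oyster`, `farm_total_g/kg/lb`,
#'   optional `band_lb = c(lower, upper)`, and the registry version.
#' @examples
#' est <- farm_removal(harvest_scenario(1e6, 3.5, "inch"))
#' est$farm_total_lb
#' @export
farm_removal <- function(scenario, registry = default_registry(),
                         model_group = NULL, band = TRUE) {
  stopifnot(inherits(scenario, "harvest_scenario"))
  per <- per_oyster_nitrogen(scenario$height_mm, registry, model_group)
  total_g <- per$total_n_g * scenario$count
  out <- structure(list(
    scenario = scenario, per_oyster = per,
    farm_total_g = total_g,
    farm_total_kg = convert_mass(total_g, "kg"),
    farm_total_lb = convert_mass(total_g, "lb"),
    band_lb = NULL,
    model_group = model_group,
    registry_version = registry$version
  ), class = "removal_estimate")
  if (band && is.null(model_group)) {
    b <- removal_band(scenario, registry, warn_missing = FALSE)
    if (!is.null(b)) out$band_lb <- b
  }
  out
}

#' Interquartile band of the farm-scale removal
#'
#' Re-runs the farm total under the registry's tau = 0.25 and tau = 0.75
#' allometric models with the same nutrient means.
#'
#' @inheritParams farm_removal
#' @param warn_missing Warn (default) when the registry carries no band
#'   models; the point estimate is unaffected either way.
#' @return `c(lower, upper)` farm totals in lb, or `NULL` if the registry
#'   has no band models.
#' @export
removal_band <- function(scenario, registry = default_registry(),
                         warn_missing = TRUE) {
  stopifnot(inherits(scenario, "harvest_scenario"))
  eval_tau <- function(tau) {
    mt <- registry_model(registry, "tissue", tau = tau)
    ms <- registry_model(registry, "shell", tau = tau)
    if (is.null(mt) || is.null(ms)) return(NULL)
    g <- (predict_dry_weight(mt, scenario$height_mm) *
            registry$nutrients$tissue$mean / 100 +
          predict_dry_weight(ms, scenario$height_mm) *
            registry$nutrients$shell$mean / 100) * scenario$count
    convert_mass(g, "lb")
  }
  lo <- eval_tau(0.25)
  hi <- eval_tau(0.75)
  if (is.null(lo) || is.null(hi)) {
    if (warn_missing) {
      warning("registry has no tau = 0.25 / 0.75 band models; ",
              "band omitted", call. = FALSE)
    }
    return(NULL)
  }
  c(lower = lo, upper = hi)
}

#' Oysters needed to offset a nitrogen load (reverse calculation)
#'
#' Divides the target load by the whole-animal nitrogen of one oyster at the
#' given harvest height and rounds up: the returned count always removes at
#' least the stated load (one fewer oyster removes less).
#'
#' @param load Nitrogen load to offset, in `load_unit` (> 0).
#' @param load_unit `"g"`, `"kg"` or `"lb"`.
#' @param height Mean harvest shell height in `height_unit`.
#' @param height_unit `"mm"` or `"inch"`.
#' @param registry An `anrc_registry`.
#' @return Integer oyster count (ceiling of the exact quotient).
#' @examples
#' reverse_oyster_count(100, "lb", 77, "mm")
#' @export
reverse_oyster_count <- function(load, load_unit = c("g", "kg", "lb"),
                                 height, height_unit = c("mm", "inch"),
                                 registry = default_registry()) {
  load_unit <- match.arg(load_unit)
  height_unit <- match.arg(height_unit)
  if (!is.finite(load) || load <= 0) stop("load must be positive", call. = FALSE)
  load_g <- mass_to_grams(load, load_unit)
  H <- convert_length(height, height_unit)
  per <- per_oyster_nitrogen(H, registry)$total_n_g
  count <- ceiling(load_g / per)
  # the floating-point quotient can land a hair above an integer; correct
  # against the forward product so the contract is exact: `count` covers the
  # load and `count - 1` does not
  if (count > 1 && (count - 1) * per >= load_g) count <- count - 1
  if (count * per < load_g) count <- count + 1
  count
}

#' @export
print.removal_estimate <- function(x, ...) {
  s <- x$scenario
  cat("Nitrogen removal at harvest (registry ", x$registry_version,
      if (!is.null(x$model_group)) paste0(", subgroup ", x$model_group), ")\n",
      sep = "")
  cat(sprintf("  %s oysters at %.1f mm over %s\n",
              format(s$count, big.mark = ",", scientific = FALSE),
              s$height_mm, s$period))
  cat(sprintf("  per oyster: %.3g g N (tissue %.3g, shell %.3g)\n",
              x$per_oyster$total_n_g, x$per_oyster$tissue_n_g,
              x$per_oyster$shell_n_g))
  cat(sprintf("  farm total: %.1f lb (%.1f kg)\n",
              x$farm_total_lb, x$farm_total_kg))
  if (!is.null(x$band_lb)) {
    cat(sprintf("  interquartile band: %.1f - %.1f lb\n",
                x$band_lb[["lower"]], x$band_lb[["upper"]]))
  }
  invisible(x)
}
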