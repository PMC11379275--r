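# Permit-facing report generator. A report has five blocks — farm metadata,
# inputs, results, a fixed narrative on the nutrient-removal ecosystem
# service, and citations — and is deterministic: same scenario, estimate and
# format give the same bytes. Display rounding (1 decimal on lb/kg totals,
# 3 significant figures on per-oyster grams) applies to the markdown only;
# the JSON form carries full precision.

REPORT_NARRATIVE <- paste(
  "Oyster aquaculture removes nitrogen from eutrophic coastal waters:",
  "nitrogen assimilated into oyster tissue and shell during growth leaves",
  "the waterbody when the crop is harvested. The removal reported here is",
  "the harvest-associated service only; it excludes possible enhancement of",
  "sediment denitrification and burial of biodeposits. Values are computed",
  "from regional 50th-quantile allometric regressions of tissue and shell",
  "dry weight on shell height and regional mean tissue and shell nitrogen",
  "concentrations, applied to the reported mean size and number of oysters",
  "harvested. Where shown, the interquartile band spans the 25th and 75th",
  "quantile regressions fitted to the same data."
)

REPORT_CITATIONS <- c(
  "Regional compilation of farmed eastern oyster morphometrics and tissue/shell nitrogen concentrations (constants registry; version recorded below).",
  "Chesapeake Bay Program oyster best management practice methodology for harvest-based nutrient reduction (methodological basis)."
)

#' Build a permit-facing removal report
#'
#' @param scenario The [harvest_scenario()] the estimate was computed from.
#' @param estimate The matching [farm_removal()] result; a scenario/estimate
#'   mismatch (different count or height) is an error.
#' @param format `"markdown"` or `"json"`.
#' @return A single string: the serialized report. The JSON form round-trips
#'   to the same numbers at full precision.
#' @export
build_report <- function(scenario, estimate, format = c("markdown", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(scenario, "harvest_scenario"),
            inherits(estimate, "removal_estimate"))
  es <- estimate$scenario
  if (es$count != scenario$count || es$height_mm != scenario$height_mm) {
    stop("estimate was not produced from this scenario", call. = FALSE)
  }
  doc <- list(
    farm = list(
      farm_name = scenario$farm_name, location = scenario$location_text,
      latitude = scenario$latitude, longitude = scenario$longitude,
      ploidy = scenario$ploidy, practice = scenario$practice
    ),
    inputs = list(
      count = scenario$count, height = scenario$height_input,
      height_unit = scenario$height_unit, height_mm = scenario$height_mm,
      period = scenario$period
    ),
    results = list(
      per_oyster = unclass(estimate$per_oyster),
      farm_total_g = estimate$farm_total_g,
      farm_total_kg = estimate$farm_total_kg,
      farm_total_lb = estimate$farm_total_lb,
      band_lb = if (!is.null(estimate$band_lb)) as.list(estimate$band_lb),
      model_group = estimate$model_group,
      registry_version = estimate$registry_version
    ),
    narrative = REPORT_NARRATIVE,
    citations = REPORT_CITATIONS
  )
  if (format == "json") {
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE, null = "null")))
  }
  md_num <- function(x, d = 1) formatC(x, format = "f", digits = d)
  lines <- c(
    "# Oyster harvest nitrogen removal report",
    "",
    "## Farm",
    paste0("- Farm name: ", scenario$farm_name),
    paste0("- Location: ", scenario$location_text),
    paste0("- Coordinates: ",
           if (is.na(scenario$latitude)) "not provided" else
             paste0(scenario$latitude, ", ", scenario$longitude)),
    paste0("- Ploidy: ", scenario$ploidy, "; cultivation practice: ",
           scenario$practice),
    "",
    "## Inputs",
    paste0("- Oysters harvested: ", format(scenario$count, big.mark = ",",
                                           scientific = FALSE)),
    paste0("- Mean shell height at harvest: ", scenario$height_input, " ",
           scenario$height_unit, " (", md_num(scenario$height_mm), " mm)"),
    paste0("- Harvest period: ", scenario$period),
    "",
    "## Results",
    paste0("- Nitrogen per oyster: ", signif(estimate$per_oyster$total_n_g, 3),
           " g (tissue ", signif(estimate$per_oyster$tissue_n_g, 3),
           " g, shell ", signif(estimate$per_oyster$shell_n_g, 3), " g)"),
    paste0("- Farm-scale nitrogen removal: ", md_num(estimate$farm_total_lb),
           " lb (", md_num(estimate$farm_total_kg), " kg)"),
    if (!is.null(estimate$band_lb)) {
      paste0("- Interquartile band: ", md_num(estimate$band_lb[["lower"]]),
             " - ", md_num(estimate$band_lb[["upper"]]), " lb")
    },
    if (!is.null(estimate$model_group)) {
      paste0("- Model subgroup (sensitivity analysis, non-canonical): ",
             estimate$model_group)
    },
    paste0("- Constants registry version: ", estimate$registry_version),
    "",
    "## Ecosystem service narrative",
    REPORT_NARRATIVE,
    "",
    "## Citations",
    paste0("- ", REPORT_CITATIONS)
  )
  paste(lines, collapse = "\n")
}
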