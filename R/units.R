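# Unit conversions. All internal computation is in mm / g; conversions happen
# only at the user-facing boundary so farm totals are bit-exact reproducible.

MM_PER_INCH <- 25.4          # international inch, exact
G_PER_LB    <- 453.59237     # international avoirdupois pound, exact

#' Convert a shell height to millimetres
#'
#' Lengths are stored and computed in millimetres throughout; this converts a
#' user-supplied height at the interface boundary. The inch is the
#' international inch (25.4 mm exactly), so typical market sizes 2.5-3.5 in
#' map to 63.5-88.9 mm.
#'
#' @param value Positive length (vectorised).
#' @param unit `"mm"` or `"inch"`.
#' @return Length in mm.
#' @examples
#' convert_length(3.5, "inch")  # 88.9
#' @export
convert_length <- function(value, unit = c("mm", "inch")) {
  unit <- match.arg(unit)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("length must be finite and positive", call. = FALSE)
  }
  switch(unit, mm = value, inch = value * MM_PER_INCH)
}

#' Convert a mass in grams to an output unit
#'
#' Masses are computed in grams; reporting units are grams, kilograms or
#' avoirdupois pounds (453.59237 g exactly).
#'
#' @param value_g Non-negative mass in grams (vectorised).
#' @param unit `"g"`, `"kg"` or `"lb"`.
#' @return Mass expressed in `unit`.
#' @examples
#' convert_mass(453.59237, "lb")  # 1
#' @export
convert_mass <- function(value_g, unit = c("g", "kg", "lb")) {
  unit <- match.arg(unit)
  if (any(!is.finite(value_g)) || any(value_g < 0)) {
    stop("mass must be finite and non-negative", call. = FALSE)
  }
  switch(unit, g = value_g, kg = value_g / 1000, lb = value_g / G_PER_LB)
}

#' Convert a mass in an input unit to grams
#'
#' Inverse companion of [convert_mass()], used when reading user-supplied
#' nitrogen loads (reverse calculation).
#'
#' @param value Non-negative mass in `unit`.
#' @param unit `"g"`, `"kg"` or `"lb"`.
#' @return Mass in grams.
#' @export
mass_to_grams <- function(value, unit = c("g", "kg", "lb")) {
  unit <- match.arg(unit)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("mass must be finite and non-negative", call. = FALSE)
  }
  switch(unit, g = value, kg = value * 1000, lb = value * G_PER_LB)
}
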