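# Oyster record table: one row per measured animal. Heights in mm, dry
# weights in g, nitrogen as percent of component dry weight. Absent values
# are empty cells; the same wide schema holds rows measured for
# length:weight only and rows with paired nutrient data.

OYSTER_COLUMNS <- c(
  "source_id", "state", "ploidy", "practice", "shell_height_mm",
  "tissue_dw_g", "shell_dw_g", "tissue_n_pct", "shell_n_pct",
  "latitude", "longitude"
)
OYSTER_NUMERIC <- c(
  "shell_height_mm", "tissue_dw_g", "shell_dw_g",
  "tissue_n_pct", "shell_n_pct", "latitude", "longitude"
)
PLOIDY_LEVELS   <- c("diploid", "triploid", "unknown")
PRACTICE_LEVELS <- c("floating_gear", "bottom_gear", "no_gear", "unknown")

#' Read a table of per-animal oyster records
#'
#' Reads the wide CSV schema
#' `source_id,state,ploidy,practice,shell_height_mm,tissue_dw_g,shell_dw_g,`
#' `tissue_n_pct,shell_n_pct,latitude,longitude` (header matched
#' case-insensitively; columns other than `shell_height_mm` may be absent and
#' are filled with NA). Each row is validated against the record invariants:
#' positive shell height, non-negative dry weights, nitrogen percents strictly
#' inside (0, 100), and recognised ploidy/practice labels (empty labels become
#' `"unknown"`).
#'
#' @param path CSV file path.
#' @param strict If `TRUE`, any violating row (or unparseable numeric cell)
#'   aborts the read; otherwise violating rows are dropped and reported.
#' @return A list with `records` (validated data frame) and `report` (a
#'   `validation_report`: counts of accepted/rejected rows, the rule violated
#'   per rejected row, and eligibility counts for downstream analyses).
#' @seealso [write_oyster_records()], [generate_records()]
#' @export
read_oyster_records <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  names(raw) <- tolower(trimws(names(raw)))
  if (!"shell_height_mm" %in% names(raw)) {
    stop("mandatory column 'shell_height_mm' missing", call. = FALSE)
  }
  for (col in setdiff(OYSTER_COLUMNS, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[OYSTER_COLUMNS]
  validate_records(raw, strict = strict)
}

# Shared by read_oyster_records and the CLI: takes an all-character frame in
# schema order, returns typed records + report.
validate_records <- function(raw, strict = FALSE) {
  n <- nrow(raw)
  rec <- raw
  bad_parse <- rep(FALSE, n)
  for (col in OYSTER_NUMERIC) {
    chr <- trimws(as.character(raw[[col]]))
    chr[chr == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(chr))
    bad_parse <- bad_parse | (!is.na(chr) & is.na(num))
    rec[[col]] <- num
  }
  for (col in c("source_id", "state")) {
    chr <- trimws(as.character(raw[[col]]))
    chr[is.na(chr)] <- ""
    rec[[col]] <- chr
  }
  for (col in c("ploidy", "practice")) {
    chr <- tolower(trimws(as.character(raw[[col]])))
    chr[is.na(chr) | chr == ""] <- "unknown"
    rec[[col]] <- chr
  }

  rules <- list(
    "unparseable numeric cell" = bad_parse,
    "positive height"      = is.na(rec$shell_height_mm) | rec$shell_height_mm <= 0,
    "non-negative mass"    = (!is.na(rec$tissue_dw_g) & rec$tissue_dw_g < 0) |
                             (!is.na(rec$shell_dw_g)  & rec$shell_dw_g  < 0),
    "nitrogen percent in (0,100)" =
      (!is.na(rec$tissue_n_pct) & (rec$tissue_n_pct <= 0 | rec$tissue_n_pct >= 100)) |
      (!is.na(rec$shell_n_pct)  & (rec$shell_n_pct  <= 0 | rec$shell_n_pct  >= 100)),
    "recognised ploidy"    = !(rec$ploidy %in% PLOIDY_LEVELS),
    "recognised practice"  = !(rec$practice %in% PRACTICE_LEVELS)
  )
  viol <- data.frame(row = integer(), rule = character())
  for (rule in names(rules)) {
    hit <- which(rules[[rule]])
    if (length(hit)) viol <- rbind(viol, data.frame(row = hit, rule = rule))
  }
  viol <- viol[order(viol$row, match(viol$rule, names(rules))), , drop = FALSE]
  rownames(viol) <- NULL
  bad_rows <- unique(viol$row)
  if (strict && length(bad_rows)) {
    stop("record validation failed at row ", bad_rows[1], ": ",
         viol$rule[viol$row == bad_rows[1]][1], call. = FALSE)
  }
  keep <- setdiff(seq_len(n), bad_rows)
  records <- rec[keep, , drop = FALSE]
  rownames(records) <- NULL

  report <- structure(list(
    n_read = n, n_accepted = length(keep), n_rejected = length(bad_rows),
    violations = viol,
    eligible = list(
      tissue_allometry = sum(!is.na(records$tissue_dw_g)),
      shell_allometry  = sum(!is.na(records$shell_dw_g)),
      tissue_nutrient  = sum(!is.na(records$tissue_dw_g) & !is.na(records$tissue_n_pct)),
      shell_nutrient   = sum(!is.na(records$shell_dw_g)  & !is.na(records$shell_n_pct))
    )
  ), class = "validation_report")
  list(records = records, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Oyster record validation: ", x$n_accepted, " accepted, ",
      x$n_rejected, " rejected of ", x$n_read, " rows\n", sep = "")
  if (nrow(x$violations)) {
    tab <- table(x$violations$rule)
    for (r in names(tab)) cat("  - ", r, ": ", tab[[r]], " row(s)\n", sep = "")
  }
  cat("Eligible for tissue/shell allometry: ",
      x$eligible$tissue_allometry, "/", x$eligible$shell_allometry,
      "; paired nutrient rows: ", x$eligible$tissue_nutrient, "/",
      x$eligible$shell_nutrient, "\n", sep = "")
  invisible(x)
}

#' Write oyster records to CSV
#'
#' Writes the documented wide schema with absent values as empty cells.
#' Numeric fields are formatted to 12 significant digits so a write/read
#' round trip reproduces values to that precision.
#'
#' @param records Data frame of validated oyster records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_oyster_records <- function(records, path) {
  out <- records[intersect(OYSTER_COLUMNS, names(records))]
  for (col in setdiff(OYSTER_COLUMNS, names(out))) out[[col]] <- NA
  out <- out[OYSTER_COLUMNS]
  for (col in OYSTER_NUMERIC) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", formatC(v, digits = 12, format = "g"))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
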