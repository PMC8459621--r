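#' Cage production records
#'
#' A cage record is one cage's end-of-cycle bookkeeping: what was stocked,
#' what was fed, what died and what was harvested. Records are plain tibbles
#' with one row per cage and a fixed column set, so they round-trip cleanly
#' through CSV and feed directly into [cage_nutrient_loss()] and
#' [compute_metrics()].
#'
#' @section Columns:
#' \describe{
#'   \item{cage_id}{cage identifier (character)}
#'   \item{volume_m3}{cage capacity, m^3}
#'   \item{stock_count}{juveniles stocked, fish}
#'   \item{stock_mean_weight_g}{mean juvenile weight at stocking, g/fish}
#'   \item{stock_total_weight_kg}{total stocked biomass, kg}
#'   \item{feed_supplied_kg}{feed supplied over the cycle, kg as-fed}
#'   \item{dead_count}{mortalities over the cycle, fish}
#'   \item{dead_total_weight_kg}{total weight of dead fish, kg}
#'   \item{harvest_count}{fish harvested, fish}
#'   \item{harvest_total_weight_kg}{total harvest biomass, kg}
#'   \item{cycle_days}{production-cycle length, days}
#' }
#'
#' @section Invariants:
#' `volume_m3 > 0`, `cycle_days > 0`, all masses and counts non-negative,
#' and `harvest_count + dead_count == stock_count` (every stocked fish is
#' accounted for). `stock_total_weight_kg` is taken as recorded; if it
#' disagrees with `stock_count * stock_mean_weight_g / 1000` by more than 1%
#' a warning is raised but the record is kept, since farms record both
#' quantities independently.
#'
#' @name cage_records
NULL

cage_record_columns <- function() {
  c(
    "cage_id", "volume_m3", "stock_count", "stock_mean_weight_g",
    "stock_total_weight_kg", "feed_supplied_kg", "dead_count",
    "dead_total_weight_kg", "harvest_count", "harvest_total_weight_kg",
    "cycle_days"
  )
}

#' Construct and validate cage production records
#'
#' Coerces a data frame to the cage-record schema and checks every
#' bookkeeping invariant. Validation failures are collected across rows and
#' reported together, each naming the offending `cage_id` and the rule it
#' broke.
#'
#' @param x A data frame with the columns listed under [cage_records].
#' @return A validated tibble of class `cage_records`.
#' @export
#' @examples
#' rec <- cage_records(data.frame(
#'   cage_id = "A1", volume_m3 = 75, stock_count = 5625,
#'   stock_mean_weight_g = 50, stock_total_weight_kg = 281.25,
#'   feed_supplied_kg = 2023, dead_count = 625, dead_total_weight_kg = 76.6,
#'   harvest_count = 5000, harvest_total_weight_kg = 1226, cycle_days = 170
#' ))
cage_records <- function(x) {
  x <- tibble::as_tibble(x)
  missing <- setdiff(cage_record_columns(), names(x))
  if (length(missing) > 0) {
    stop("cage records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[cage_record_columns()]
  x$cage_id <- as.character(x$cage_id)
  numeric_cols <- setdiff(cage_record_columns(), "cage_id")
  for (col in numeric_cols) {
    if (!is.numeric(x[[col]])) {
      stop("cage record column '", col, "' is not numeric", call. = FALSE)
    }
  }
  if (nrow(x) > 0) {
    validate_cage_rows(x)
  }
  class(x) <- c("cage_records", class(x))
  x
}

validate_cage_rows <- function(x) {
  rule <- function(cond, msg) {
    bad <- which(!cond | is.na(cond))
    if (length(bad) == 0) character(0) else
      paste0("cage_id ", x$cage_id[bad], ": ", msg)
  }
  mass_cols <- c("stock_total_weight_kg", "feed_supplied_kg",
                 "dead_total_weight_kg", "harvest_total_weight_kg",
                 "stock_mean_weight_g")
  count_cols <- c("stock_count", "dead_count", "harvest_count")
  problems <- c(
    rule(x$volume_m3 > 0, "volume_m3 must be > 0"),
    rule(x$cycle_days > 0, "cycle_days must be > 0"),
    unlist(lapply(mass_cols, function(col)
      rule(x[[col]] >= 0, paste0(col, " must be >= 0")))),
    unlist(lapply(count_cols, function(col)
      rule(x[[col]] >= 0, paste0(col, " must be >= 0")))),
    rule(x$harvest_count + x$dead_count == x$stock_count,
         "harvest_count + dead_count must equal stock_count")
  )
  if (length(problems) > 0) {
    stop("invalid cage record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  # recorded vs implied stocked biomass: warn only, never reject
  implied <- x$stock_count * x$stock_mean_weight_g / 1000
  ok <- implied == 0 | x$stock_total_weight_kg == 0
  reldiff <- abs(x$stock_total_weight_kg - implied) / pmax(implied, 1e-12)
  off <- which(!ok & reldiff > 0.01)
  if (length(off) > 0) {
    warning("stock_total_weight_kg differs by >1% from stock_count x ",
            "stock_mean_weight_g / 1000 for cage_id: ",
            paste(x$cage_id[off], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Read cage production records from CSV
#'
#' Reads a one-row-per-cage CSV (columns as documented in [cage_records])
#' and validates every row. A missing column is a schema error naming the
#' column; a non-numeric cell is a parse error reporting the row; an
#' invariant violation names the cage and the rule.
#'
#' @param path Path to a records CSV.
#' @return A validated `cage_records` tibble, rows in file order.
#' @export
read_cage_records <- function(path) {
  if (!file.exists(path)) {
    stop("records file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(cage_record_columns(), names(raw))
  if (length(missing) > 0) {
    stop("records CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(cage_record_columns(), "cage_id")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at data row ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- vals
  }
  cage_records(raw)
}

#' Write cage production records to CSV
#'
#' @param records A `cage_records` tibble (or coercible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cage_records <- function(records, path) {
  records <- cage_records(records)
  readr::write_csv(records, path)
  invisible(path)
}
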