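#' Specific growth rate
#'
#' Instantaneous growth rate of the caged population over the cycle,
#' `100 * log(harvest / stock) / days` in %/day. The natural log is the
#' default (the convention under which gourami grow-out SGRs of roughly
#' 0.9–1.0 %/day are reported); base 10 is available for comparison with
#' sources that use it.
#'
#' @param stock_total_weight Stocked biomass, kg (> 0).
#' @param harvest_total_weight Harvest biomass, kg (> 0).
#' @param cycle_days Cycle length, days (> 0).
#' @param log_base Base of the logarithm; default `exp(1)`.
#' @return SGR in %/day.
#' @export
#' @examples
#' specific_growth_rate(281.25, 1226, 170)
specific_growth_rate <- function(stock_total_weight, harvest_total_weight,
                                 cycle_days, log_base = exp(1)) {
  if (any(stock_total_weight <= 0) || any(harvest_total_weight <= 0)) {
    stop("weights must be > 0 to compute a growth rate", call. = FALSE)
  }
  if (any(cycle_days <= 0)) stop("cycle_days must be > 0", call. = FALSE)
  100 * log(harvest_total_weight / stock_total_weight, base = log_base) /
    cycle_days
}

#' Gross fish yield
#'
#' Harvest biomass per unit cage volume, kg/m^3 per cycle.
#'
#' @param harvest_total_weight Harvest biomass, kg.
#' @param volume Cage capacity, m^3 (> 0).
#' @return Gross yield in kg/m^3.
#' @export
gross_fish_yield <- function(harvest_total_weight, volume) {
  if (any(volume <= 0)) stop("volume must be > 0", call. = FALSE)
  harvest_total_weight / volume
}

#' Net fish yield
#'
#' Biomass gained per unit cage volume: harvest minus stocked biomass over
#' the cage capacity, kg/m^3 per cycle.
#'
#' @param harvest_total_weight Harvest biomass, kg.
#' @param stock_total_weight Stocked biomass, kg.
#' @param volume Cage capacity, m^3 (> 0).
#' @return Net yield in kg/m^3.
#' @export
net_fish_yield <- function(harvest_total_weight, stock_total_weight, volume) {
  if (any(volume <= 0)) stop("volume must be > 0", call. = FALSE)
  (harvest_total_weight - stock_total_weight) / volume
}

#' Feed conversion ratio
#'
#' Feed supplied divided by total harvest weight. Note the denominator: in
#' this farm-accounting convention FCR is feed over harvest biomass, not
#' feed over weight gain (which would run slightly higher).
#'
#' @param feed_supplied Feed supplied over the cycle, kg.
#' @param harvest_total_weight Harvest biomass, kg (> 0).
#' @return FCR, dimensionless.
#' @export
#' @examples
#' feed_conversion_ratio(2023, 1226)
feed_conversion_ratio <- function(feed_supplied, harvest_total_weight) {
  if (any(harvest_total_weight <= 0)) {
    stop("harvest_total_weight must be > 0", call. = FALSE)
  }
  feed_supplied / harvest_total_weight
}

#' Feed conversion efficiency
#'
#' Reciprocal of the FCR: kg of fish produced per kg of feed. Its
#' complement `1 - fce` is the waste fraction — the share of each kg of
#' feed that is not converted to harvested fish and ends up as load on the
#' waterbody.
#'
#' @param fcr Feed conversion ratio (> 0).
#' @return FCE, dimensionless.
#' @export
feed_conversion_efficiency <- function(fcr) {
  if (any(fcr <= 0)) stop("fcr must be > 0", call. = FALSE)
  1 / fcr
}

#' Daily feeding rate as percent of body mass
#'
#' The default `"mean_biomass"` mode expresses the mean daily feed ration as
#' a percentage of the mean standing biomass, `(feed / days) / ((stock +
#' harvest) / 2) * 100` — the quantity behind feeding levels of roughly
#' 1–3.5% body mass/day. The `"literal"` mode instead reports per-fish
#' daily weight gain as a percentage of mean harvest size (gain and size in
#' the same unit); it is retained for transparency but is a growth
#' statistic, not a ration level, and sits far below the mean-biomass
#' figure.
#'
#' @param feed_supplied Feed supplied over the cycle, kg.
#' @param cycle_days Cycle length, days (> 0).
#' @param stock_total_weight,harvest_total_weight Biomasses, kg (> 0).
#' @param mode `"mean_biomass"` (default) or `"literal"`.
#' @param stock_count,harvest_count Fish counts, required for `"literal"`.
#' @return Feeding rate in % per day.
#' @export
feeding_rate <- function(feed_supplied, cycle_days, stock_total_weight,
                         harvest_total_weight,
                         mode = c("mean_biomass", "literal"),
                         stock_count = NULL, harvest_count = NULL) {
  mode <- match.arg(mode)
  if (any(cycle_days <= 0)) stop("cycle_days must be > 0", call. = FALSE)
  if (any(stock_total_weight <= 0) || any(harvest_total_weight <= 0)) {
    stop("weights must be > 0", call. = FALSE)
  }
  if (mode == "mean_biomass") {
    mean_biomass <- (stock_total_weight + harvest_total_weight) / 2
    (feed_supplied / cycle_days) / mean_biomass * 100
  } else {
    if (is.null(stock_count) || is.null(harvest_count)) {
      stop("literal mode needs stock_count and harvest_count", call. = FALSE)
    }
    if (any(stock_count <= 0) || any(harvest_count <= 0)) {
      stop("counts must be > 0 in literal mode", call. = FALSE)
    }
    mean_harvest_g <- harvest_total_weight / harvest_count * 1000
    mean_stock_g <- stock_total_weight / stock_count * 1000
    gain_per_day_g <- (mean_harvest_g - mean_stock_g) / cycle_days
    gain_per_day_g / mean_harvest_g * 100
  }
}

#' Survival rate
#'
#' Percentage of stocked fish recovered at harvest.
#'
#' @param harvest_count Fish harvested (<= `stock_count`).
#' @param stock_count Fish stocked (> 0).
#' @return Survival in %.
#' @export
survival_rate <- function(harvest_count, stock_count) {
  if (any(stock_count <= 0)) stop("stock_count must be > 0", call. = FALSE)
  if (any(harvest_count > stock_count)) {
    stop("harvest_count cannot exceed stock_count", call. = FALSE)
  }
  100 * harvest_count / stock_count
}

#' Compute all production-performance metrics per cage
#'
#' Applies the seven farm-characteristic metrics to each cage record:
#' specific growth rate, gross and net fish yield, feed conversion ratio and
#' efficiency, feeding rate and survival.
#'
#' @param records A `cage_records` tibble.
#' @param log_base Log base for the SGR (default natural log).
#' @param feeding_mode Feeding-rate mode, see [feeding_rate()].
#' @return A tibble with one row per cage: `cage_id`, `sgr` (%/day),
#'   `gross_yield`, `net_yield` (kg/m^3/cycle), `fcr`, `fce`,
#'   `feeding_rate` (%/day), `survival` (%).
#' @export
#' @examples
#' compute_metrics(reference_cage())
compute_metrics <- function(records, log_base = exp(1),
                            feeding_mode = c("mean_biomass", "literal")) {
  feeding_mode <- match.arg(feeding_mode)
  records <- cage_records(records)
  fcr <- feed_conversion_ratio(records$feed_supplied_kg,
                               records$harvest_total_weight_kg)
  tibble::tibble(
    cage_id = records$cage_id,
    sgr = specific_growth_rate(records$stock_total_weight_kg,
                               records$harvest_total_weight_kg,
                               records$cycle_days, log_base = log_base),
    gross_yield = gross_fish_yield(records$harvest_total_weight_kg,
                                   records$volume_m3),
    net_yield = net_fish_yield(records$harvest_total_weight_kg,
                               records$stock_total_weight_kg,
                               records$volume_m3),
    fcr = fcr,
    # a cage with no feed logged has FCR 0; its FCE is undefined, not infinite
    fce = ifelse(fcr > 0, 1 / fcr, NA_real_),
    feeding_rate = feeding_rate(records$feed_supplied_kg, records$cycle_days,
                                records$stock_total_weight_kg,
                                records$harvest_total_weight_kg,
                                mode = feeding_mode,
                                stock_count = records$stock_count,
                                harvest_count = records$harvest_count),
    survival = survival_rate(records$harvest_count, records$stock_count)
  )
}
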