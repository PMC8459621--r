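#' Convert an as-recorded mass to dry matter
#'
#' @param mass Mass in kg (non-negative).
#' @param moisture_frac Moisture mass fraction in \[0, 1).
#' @return Dry mass in kg: `mass * (1 - moisture_frac)`.
#' @export
#' @examples
#' to_dry_mass(1226, 0.689) # live fish biomass -> dry matter
to_dry_mass <- function(mass, moisture_frac) {
  stopifnot(all(mass >= 0))
  if (any(moisture_frac < 0 | moisture_frac > 1)) {
    stop("moisture_frac must lie in [0, 1)", call. = FALSE)
  }
  if (any(moisture_frac == 1)) {
    stop("moisture_frac = 1 leaves no dry matter", call. = FALSE)
  }
  mass * (1 - moisture_frac)
}

#' Nutrient mass contained in a system component
#'
#' Multiplies a component mass (feed, stocked juveniles, mortalities or
#' harvest) by its nutrient mass fraction. On the default `"as_recorded"`
#' basis the fraction is applied to the mass as logged by the farm; on the
#' `"dry_matter"` basis the mass is first moisture-corrected with
#' [to_dry_mass()].
#'
#' @param mass Component mass, kg.
#' @param nutrient_frac Nutrient mass fraction in \[0, 1\].
#' @param basis `"as_recorded"` (default) or `"dry_matter"`.
#' @param moisture_frac Moisture fraction, used only for `"dry_matter"`.
#' @return Nutrient mass, kg.
#' @export
component_nutrient_mass <- function(mass, nutrient_frac,
                                    basis = c("as_recorded", "dry_matter"),
                                    moisture_frac = 0) {
  basis <- match.arg(basis)
  stopifnot(all(mass >= 0), all(nutrient_frac >= 0 & nutrient_frac <= 1))
  if (basis == "dry_matter") {
    mass <- to_dry_mass(mass, moisture_frac)
  }
  mass * nutrient_frac
}

#' Nutrient loss from component nutrient masses
#'
#' The elementary budget behind the per-cage balance: loss to the waterbody
#' equals nutrient inputs (feed plus stocked juveniles) minus nutrient
#' retained in outputs (harvest plus dead fish), each already expressed as a
#' nutrient mass in kg.
#'
#' @param input_feed,input_juvenile,output_harvest,output_dead Nutrient
#'   masses, kg.
#' @return Loss in kg (may be negative for inconsistent bookkeeping).
#' @export
#' @examples
#' nutrient_loss(412.19, 44.49, 203.01, 17.40) # carbon, study-mean cage
nutrient_loss <- function(input_feed, input_juvenile, output_harvest,
                          output_dead) {
  (input_feed + input_juvenile) - (output_harvest + output_dead)
}

#' Per-cage C/N/P mass balance
#'
#' For each cage and each nutrient, computes the four component nutrient
#' masses (feed and juveniles in; harvest and dead fish out), their
#' difference (the loss released to the waterbody over the cycle) and the
#' loss per tonne of feed supplied. A negative loss is flagged with a
#' warning, not an error: it indicates inconsistent bookkeeping the analyst
#' should see, not an impossible input.
#'
#' @param records A `cage_records` tibble (one or more cages).
#' @param comp A `nutrient_composition`; defaults to [default_composition()].
#' @param basis Mass basis for all components: `"as_recorded"` (default,
#'   fractions applied to masses as logged) or `"dry_matter"` (masses
#'   moisture-corrected first; the fish moisture fraction is used for
#'   juveniles, mortalities and harvest alike).
#' @return A tibble with one row per cage x nutrient: `cage_id`, `nutrient`
#'   (`"C"`, `"N"`, `"P"`), `input_feed`, `input_juvenile`, `output_harvest`,
#'   `output_dead`, `loss` (all kg), `feed_mass_basis` (kg of feed on the
#'   chosen basis) and `loading_per_tonne` (kg loss per tonne of feed).
#' @export
#' @examples
#' cage_nutrient_loss(reference_cage())
cage_nutrient_loss <- function(records, comp = default_composition(),
                               basis = c("as_recorded", "dry_matter")) {
  basis <- match.arg(basis)
  records <- cage_records(records)
  stopifnot(inherits(comp, "nutrient_composition"))

  frac <- function(component, nutrient) {
    comp[[component]][[paste0(tolower(nutrient), "_frac")]]
  }
  nutrients <- c("C", "N", "P")
  out <- purrr::map_dfr(nutrients, function(nu) {
    tibble::tibble(
      cage_id = records$cage_id,
      nutrient = nu,
      input_feed = component_nutrient_mass(
        records$feed_supplied_kg, frac("feed", nu), basis,
        comp$feed$moisture_frac),
      input_juvenile = component_nutrient_mass(
        records$stock_total_weight_kg, frac("fish", nu), basis,
        comp$fish$moisture_frac),
      output_harvest = component_nutrient_mass(
        records$harvest_total_weight_kg, frac("fish", nu), basis,
        comp$fish$moisture_frac),
      output_dead = component_nutrient_mass(
        records$dead_total_weight_kg, frac("fish", nu), basis,
        comp$fish$moisture_frac),
      feed_mass_basis = if (basis == "dry_matter") {
        to_dry_mass(records$feed_supplied_kg, comp$feed$moisture_frac)
      } else {
        records$feed_supplied_kg
      }
    )
  })
  out$loss <- nutrient_loss(out$input_feed, out$input_juvenile,
                            out$output_harvest, out$output_dead)
  out$loading_per_tonne <- ifelse(
    out$feed_mass_basis > 0, out$loss / (out$feed_mass_basis / 1000), NA_real_)
  neg <- out$loss < 0
  if (any(neg)) {
    warning("negative nutrient loss (inputs < retained outputs) for: ",
            paste(unique(paste0(out$cage_id[neg], "/", out$nutrient[neg])),
                  collapse = ", "), call. = FALSE)
  }
  out[c("cage_id", "nutrient", "input_feed", "input_juvenile",
        "output_harvest", "output_dead", "loss", "feed_mass_basis",
        "loading_per_tonne")]
}

#' Nutrient loading per tonne of feed
#'
#' Normalises a per-cycle nutrient loss by the feed supplied, giving the
#' load in kg of nutrient per tonne of feed — the unit in which cage-farm
#' loadings are compared across species and systems.
#'
#' @param loss Nutrient loss, kg.
#' @param feed_mass Feed mass on the same basis as the loss, kg; must be > 0.
#' @return Loading in kg/tonne feed.
#' @export
#' @examples
#' loading_per_tonne_feed(8.70, 2025.35) # phosphorus, study-mean cage
loading_per_tonne_feed <- function(loss, feed_mass) {
  if (any(feed_mass <= 0)) {
    stop("feed_mass must be > 0 to express loading per tonne", call. = FALSE)
  }
  loss / (feed_mass / 1000)
}

#' Aggregate per-cage balances across a farm
#'
#' Summarises each balance column per nutrient as mean, sample standard
#' deviation (n - 1 denominator), minimum and maximum — the shape in which
#' multi-cage nutrient budgets are conventionally tabulated. With a single
#' cage the SD is undefined; it is reported as 0 and flagged via the
#' `sd_defined` column.
#'
#' @param balances Output of [cage_nutrient_loss()] (non-empty).
#' @return A tibble with one row per nutrient x quantity:
#'   `nutrient`, `quantity`, `mean`, `sd`, `min`, `max`, `n`, `sd_defined`.
#' @export
aggregate_balances <- function(balances) {
  if (nrow(balances) == 0) {
    stop("cannot aggregate an empty set of balances", call. = FALSE)
  }
  quantities <- c("input_feed", "input_juvenile", "output_harvest",
                  "output_dead", "loss", "loading_per_tonne")
  long <- tidyr::pivot_longer(balances, dplyr::all_of(quantities),
                              names_to = "quantity", values_to = "value")
  res <- dplyr::summarise(
    dplyr::group_by(long, .data$nutrient, .data$quantity),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
    min = min(.data$value),
    max = max(.data$value),
    n = dplyr::n(),
    sd_defined = dplyr::n() > 1,
    .groups = "drop"
  )
  res$quantity <- factor(res$quantity, levels = quantities)
  res <- dplyr::arrange(res, .data$nutrient, .data$quantity)
  res$quantity <- as.character(res$quantity)
  res
}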