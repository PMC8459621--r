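#' Nutrient composition tables
#'
#' Mass fractions of carbon, nitrogen, phosphorus and moisture for the three
#' components of the cage system: the feed, the fish (a single composition
#' applied alike to stocked juveniles, mortalities and harvest) and the
#' faeces. Faeces composition is carried for reporting but takes no part in
#' the loss equations. All fractions are stored on the \[0, 1\] scale.
#'
#' @param feed,fish,faeces Named numeric vectors (or lists) with elements
#'   `C`, `N`, `P` and `H2O`, on the scale declared by `unit`.
#' @param unit `"percent"` (values divided by 100 on input; the usual way
#'   proximate analyses are reported) or `"fraction"`.
#' @return A list of class `nutrient_composition` with one element per
#'   component, each holding `c_frac`, `n_frac`, `p_frac`, `moisture_frac`.
#' @export
#' @examples
#' nutrient_composition(
#'   feed = c(C = 20.23, N = 6.02, P = 0.71, H2O = 8.75),
#'   fish = c(C = 16.56, N = 3.01, P = 0.40, H2O = 68.90),
#'   faeces = c(C = 14.21, N = 1.20, P = 0.95, H2O = 72.29)
#' )
nutrient_composition <- function(feed, fish, faeces, unit = "percent") {
  unit <- match.arg(unit, c("percent", "fraction"))
  scale <- if (unit == "percent") 100 else 1
  one <- function(v, component) {
    v <- unlist(v)
    needed <- c("C", "N", "P", "H2O")
    if (!all(needed %in% names(v))) {
      stop("composition for '", component, "' must name C, N, P and H2O",
           call. = FALSE)
    }
    out <- list(
      c_frac = unname(v[["C"]]) / scale,
      n_frac = unname(v[["N"]]) / scale,
      p_frac = unname(v[["P"]]) / scale,
      moisture_frac = unname(v[["H2O"]]) / scale
    )
    fr <- unlist(out)
    if (any(fr < 0 | fr > 1)) {
      stop("composition fraction out of [0, 1] for '", component,
           "' after unit conversion", call. = FALSE)
    }
    if (out$c_frac + out$n_frac + out$p_frac > 1) {
      stop("C + N + P fractions exceed 1 for '", component, "'",
           call. = FALSE)
    }
    out
  }
  structure(
    list(feed = one(feed, "feed"), fish = one(fish, "fish"),
         faeces = one(faeces, "faeces")),
    class = "nutrient_composition"
  )
}

#' Read a nutrient composition table from JSON
#'
#' The file is a JSON object keyed by component (`feed`, `fish`, `faeces`),
#' each holding `C`, `N`, `P`, `H2O`, plus an optional top-level `unit` key
#' (`"percent"`, the default, or `"fraction"`).
#'
#' @param path Path to the composition JSON file.
#' @return A `nutrient_composition` object (fractions on \[0, 1\]).
#' @export
read_composition <- function(path) {
  if (!file.exists(path)) {
    stop("composition file not found: ", path, call. = FALSE)
  }
  obj <- jsonlite::fromJSON(path)
  unit <- if (!is.null(obj$unit)) obj$unit else "percent"
  for (component in c("feed", "fish", "faeces")) {
    if (is.null(obj[[component]])) {
      stop("composition JSON is missing component '", component, "'",
           call. = FALSE)
    }
  }
  nutrient_composition(obj$feed, obj$fish, obj$faeces, unit = unit)
}

#' Write a nutrient composition table to JSON
#'
#' Writes on the percent scale with an explicit `unit` key, mirroring the
#' way proximate compositions are reported.
#'
#' @param comp A `nutrient_composition` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(comp, path) {
  stopifnot(inherits(comp, "nutrient_composition"))
  back <- function(x) {
    list(C = x$c_frac * 100, N = x$n_frac * 100, P = x$p_frac * 100,
         H2O = x$moisture_frac * 100)
  }
  obj <- list(feed = back(comp$feed), fish = back(comp$fish),
              faeces = back(comp$faeces), unit = "percent")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reference nutrient composition for giant gourami cage culture
#'
#' Percent-of-dry-weight compositions measured for commercial floating
#' pellet feed, giant gourami and gourami faeces in a 20-cage Lake Maninjau
#' grow-out study: feed 20.23% C, 6.02% N, 0.71% P, 8.75% moisture; fish
#' 16.56% C, 3.01% N, 0.40% P, 68.90% moisture; faeces 14.21% C, 1.20% N,
#' 0.95% P, 72.29% moisture. Used as the package default wherever a
#' composition is not supplied.
#'
#' @return A `nutrient_composition` object.
#' @export
default_composition <- function() {
  nutrient_composition(
    feed = c(C = 20.23, N = 6.02, P = 0.71, H2O = 8.75),
    fish = c(C = 16.56, N = 3.01, P = 0.40, H2O = 68.90),
    faeces = c(C = 14.21, N = 1.20, P = 0.95, H2O = 72.29),
    unit = "percent"
  )
}

#' @export
print.nutrient_composition <- function(x, ...) {
  cat("<nutrient_composition> (mass fractions)\n")
  tab <- do.call(rbind, lapply(x, function(comp) unlist(comp)))
  print(round(tab, 4))
  invisible(x)
}
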