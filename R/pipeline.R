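#' Run the full nutrient-loading report for a farm
#'
#' Reads (or accepts) cage records and a composition table, computes the
#' per-cage C/N/P balances, the per-cage performance metrics, the aggregate
#' balance table and the cross-cage regression report, and writes the bundle
#' to `out_dir`:
#' `balances.csv`, `metrics.csv`, `aggregate.json`, `regressions.csv` and
#' `run.log` (which records the basis and mode the run used, so every
#' reported number is auditable). All stages are computed before anything
#' is written, so a failure leaves no partial bundle.
#'
#' @param records A `cage_records` tibble or a path to a records CSV.
#' @param composition A `nutrient_composition`, a path to a composition
#'   JSON, or `NULL` for [default_composition()].
#' @param out_dir Output directory, created if needed. `NULL` computes the
#'   bundle without writing.
#' @param basis Mass basis, `"as_recorded"` or `"dry_matter"`.
#' @param log_base SGR log base (default natural log).
#' @param feeding_mode Feeding-rate mode, see [feeding_rate()].
#' @param pairs Regression pairs, see [relationship_report()].
#' @param plots If `TRUE`, also write one scatter+line PNG per pair.
#' @return Invisibly, a list with `balances`, `metrics`, `aggregate`,
#'   `regressions`.
#' @export
#' @examples
#' sim <- simulate_cages(n_cages = 20, seed = 1)
#' rep <- run_nutrient_report(sim$records, out_dir = NULL)
#' rep$aggregate
run_nutrient_report <- function(records, composition = NULL, out_dir = NULL,
                                basis = c("as_recorded", "dry_matter"),
                                log_base = exp(1),
                                feeding_mode = c("mean_biomass", "literal"),
                                pairs = default_relationship_pairs(),
                                plots = FALSE) {
  basis <- match.arg(basis)
  feeding_mode <- match.arg(feeding_mode)
  if (is.character(records)) records <- read_cage_records(records)
  records <- cage_records(records)
  comp <- if (is.null(composition)) {
    default_composition()
  } else if (is.character(composition)) {
    read_composition(composition)
  } else {
    stopifnot(inherits(composition, "nutrient_composition"))
    composition
  }

  balances <- cage_nutrient_loss(records, comp, basis = basis)
  metrics <- compute_metrics(records, log_base = log_base,
                             feeding_mode = feeding_mode)
  aggregate <- aggregate_balances(balances)
  regressions <- if (nrow(records) >= 2) {
    relationship_report(records, balances = balances, metrics = metrics,
                        pairs = pairs)
  } else {
    NULL
  }
  bundle <- list(balances = balances, metrics = metrics,
                 aggregate = aggregate, regressions = regressions)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(balances, file.path(out_dir, "balances.csv"))
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    agg_json <- split(aggregate[setdiff(names(aggregate), "nutrient")],
                      aggregate$nutrient)
    jsonlite::write_json(agg_json, file.path(out_dir, "aggregate.json"),
                         dataframe = "rows", digits = NA)
    if (!is.null(regressions)) {
      readr::write_csv(regressions, file.path(out_dir, "regressions.csv"))
    }
    log_lines <- c(
      paste("cageload run:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      paste("cages:", nrow(records)),
      paste("mass basis:", basis),
      paste("sgr log base:", ifelse(abs(log_base - exp(1)) < 1e-12,
                                    "natural", as.character(log_base))),
      paste("feeding-rate mode:", feeding_mode),
      paste("regression pairs:",
            if (is.null(regressions)) "(skipped, < 2 cages)"
            else paste(regressions$pair, collapse = ", "))
    )
    writeLines(log_lines, file.path(out_dir, "run.log"))
    if (plots && !is.null(regressions)) {
      write_relationship_plots(records, balances, metrics, regressions$pair,
                               out_dir)
    }
  }
  invisible(bundle)
}

write_relationship_plots <- function(records, balances, metrics, pairs,
                                     out_dir) {
  density <- records$stock_count / records$volume_m3
  loss_of <- function(nu) {
    sub <- balances[balances$nutrient == nu, ]
    sub$loss[match(records$cage_id, sub$cage_id)]
  }
  axes <- list(
    feed_vs_c_loss = list(records$feed_supplied_kg, loss_of("C"),
                          "feed supplied (kg)", "C loss (kg)"),
    feed_vs_n_loss = list(records$feed_supplied_kg, loss_of("N"),
                          "feed supplied (kg)", "N loss (kg)"),
    feed_vs_p_loss = list(records$feed_supplied_kg, loss_of("P"),
                          "feed supplied (kg)", "P loss (kg)"),
    feed_vs_net_yield = list(records$feed_supplied_kg, metrics$net_yield,
                             "feed supplied (kg)", "net yield (kg/m3)"),
    stocking_density_vs_net_yield = list(density, metrics$net_yield,
                                         "stocking density (fish/m3)",
                                         "net yield (kg/m3)"),
    cycle_days_vs_net_yield = list(records$cycle_days, metrics$net_yield,
                                   "cycle length (days)",
                                   "net yield (kg/m3)"),
    feeding_rate_vs_net_yield = list(metrics$feeding_rate,
                                     metrics$net_yield,
                                     "feeding rate (%/day)",
                                     "net yield (kg/m3)"),
    feed_vs_survival = list(records$feed_supplied_kg, metrics$survival,
                            "feed supplied (kg)", "survival (%)")
  )
  for (p in intersect(pairs, names(axes))) {
    a <- axes[[p]]
    gg <- plot_relationship(a[[1]], a[[2]], xlab = a[[3]], ylab = a[[4]])
    ggplot2::ggsave(file.path(out_dir, paste0(p, ".png")), gg,
                    width = 5, height = 4, dpi = 150)
  }
  invisible(NULL)
}

#' Simulate a cohort and write it as a records CSV with ground truth
#'
#' @param out_dir Output directory; `records.csv` and `ground_truth.csv`
#'   are written there.
#' @param n_cages Number of cages.
#' @param seed Integer seed (required for a reproducible cohort).
#' @param ... Further arguments to [cage_generator_params()].
#' @return Invisibly, the list from [simulate_cages()].
#' @export
simulate_to_csv <- function(out_dir, n_cages = 20, seed = NULL, ...) {
  sim <- simulate_cages(cage_generator_params(n_cages = n_cages,
                                              seed = seed, ...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cage_records(sim$records, file.path(out_dir, "records.csv"))
  readr::write_csv(sim$truth, file.path(out_dir, "ground_truth.csv"))
  message("simulated ", n_cages, " cages (seed ",
          if (is.null(seed)) "unset" else seed, ") -> ", out_dir)
  invisible(sim)
}
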