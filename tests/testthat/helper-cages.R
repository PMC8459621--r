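# Build random but always-valid cage records directly (independently of
# simulate_cages), for property-style tests over the bookkeeping invariants.
random_records <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stock_count <- sample(3000:8000, n, replace = TRUE)
  survival <- runif(n, 0.80, 0.99)
  harvest_count <- round(survival * stock_count)
  iw <- runif(n, 40, 60)           # g
  hmw <- runif(n, 200, 320)        # g
  tibble::tibble(
    cage_id = sprintf("rc%04d", seq_len(n)),
    volume_m3 = 75,
    stock_count = stock_count,
    stock_mean_weight_g = iw,
    stock_total_weight_kg = stock_count * iw / 1000,
    feed_supplied_kg = runif(n, 1200, 3500),
    dead_count = stock_count - harvest_count,
    dead_total_weight_kg = (stock_count - harvest_count) * 0.5 * hmw / 1000,
    harvest_count = harvest_count,
    harvest_total_weight_kg = harvest_count * hmw / 1000,
    cycle_days = sample(160:175, n, replace = TRUE)
  )
}

write_records_csv <- function(records, path = withr::local_tempfile(
                                fileext = ".csv",
                                .local_envir = parent.frame())) {
  readr::write_csv(records, path)
  path
}

write_composition_json <- function(path = withr::local_tempfile(
                                     fileext = ".json",
                                     .local_envir = parent.frame())) {
  cageload::write_composition(cageload::default_composition(), path)
  path
}
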