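Package: cageload
Title: Nutrient Loading and Production Performance of Floating-Cage Fish Farms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Per-cage carbon, nitrogen and phosphorus mass balances for
    floating-cage aquaculture, the standard farm production-performance
    metrics (specific growth rate, gross and net fish yield, feed conversion
    ratio and efficiency, feeding rate, survival), least-squares
    relationships between feed supply, stocking and yield across cages, and
    a synthetic generator that emulates a 20-cage giant gourami grow-out
    study so the full analysis runs without external data. Includes CSV/JSON
    readers and writers for cage production records and nutrient composition
    tables, and a reporting pipeline that emits per-cage and aggregate
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    tidyr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
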