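#' Ordinary least-squares line fit with r-squared
#'
#' Fits `y = slope * x + intercept` by ordinary least squares (via
#' [stats::lm()]) and reports the coefficient of determination as the
#' squared Pearson correlation of x and y — the line-plus-r-squared summary
#' used for cross-cage relationships such as feed supply versus nutrient
#' loss. The intercept is always estimated; no p-values or intervals are
#' reported.
#'
#' @param x,y Numeric vectors of equal length >= 2; `x` must vary.
#' @return An object of class `cage_lsfit`: a list with `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
#' @examples
#' fit_cage_ols(c(0, 1, 2), c(1, 3, 5))
fit_cage_ols <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("x has zero variance: degenerate design", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  structure(
    list(slope = unname(stats::coef(fit)[["x"]]),
         intercept = unname(stats::coef(fit)[["(Intercept)"]]),
         r_squared = r2,
         n = length(x)),
    class = "cage_lsfit"
  )
}

#' @export
print.cage_lsfit <- function(x, ...) {
  cat(sprintf("<cage_lsfit> y = %.4g x + %.4g  (r² = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Predict from a fitted line
#'
#' @param object A `cage_lsfit`.
#' @param x Numeric vector of x values.
#' @param ... Unused.
#' @return `slope * x + intercept`.
#' @export
predict.cage_lsfit <- function(object, x, ...) {
  object$slope * x + object$intercept
}

#' Default cross-cage relationships
#'
#' The seven relationships conventionally examined for cage farms: feed
#' supply against each nutrient loss, and feed supply, stocking density,
#' cycle length and feeding rate against net fish yield. The feed-vs-
#' survival pair is available but not fitted by default (set
#' `include_survival = TRUE` in [relationship_report()]).
#'
#' @return Character vector of pair names.
#' @export
default_relationship_pairs <- function() {
  c("feed_vs_c_loss", "feed_vs_n_loss", "feed_vs_p_loss",
    "feed_vs_net_yield", "stocking_density_vs_net_yield",
    "cycle_days_vs_net_yield", "feeding_rate_vs_net_yield")
}

#' Fit the cross-cage production relationships
#'
#' Assembles the per-cage variables (feed supply, stocking density, cycle
#' length, feeding rate, net yield, nutrient losses, survival) from records,
#' balances and metrics, and fits one least-squares line per requested pair.
#'
#' @param records A `cage_records` tibble with at least 2 cages.
#' @param balances Output of [cage_nutrient_loss()] on the same records;
#'   computed with defaults when `NULL` and a loss pair is requested.
#' @param metrics Output of [compute_metrics()]; computed with defaults when
#'   `NULL` and needed.
#' @param pairs Character vector of pair names, a subset of
#'   [default_relationship_pairs()] plus `"feed_vs_survival"`.
#' @param include_survival Add the feed-vs-survival pair to the default set.
#' @return A tibble: `pair`, `slope`, `intercept`, `r_squared`, `n`.
#' @export
#' @examples
#' sim <- simulate_cages(n_cages = 20, seed = 1)
#' relationship_report(sim$records)
relationship_report <- function(records, balances = NULL, metrics = NULL,
                                pairs = default_relationship_pairs(),
                                include_survival = FALSE) {
  records <- cage_records(records)
  if (nrow(records) < 2) {
    stop("need at least 2 cages to fit relationships", call. = FALSE)
  }
  if (include_survival) pairs <- union(pairs, "feed_vs_survival")
  needs_loss <- any(grepl("_loss$", pairs))
  if (is.null(balances) && needs_loss) {
    balances <- cage_nutrient_loss(records)
  }
  if (is.null(metrics)) metrics <- compute_metrics(records)

  vars <- tibble::tibble(
    cage_id = records$cage_id,
    feed = records$feed_supplied_kg,
    stocking_density = records$stock_count / records$volume_m3,
    cycle_days = records$cycle_days,
    feeding_rate = metrics$feeding_rate[match(records$cage_id,
                                              metrics$cage_id)],
    net_yield = metrics$net_yield[match(records$cage_id, metrics$cage_id)],
    survival = metrics$survival[match(records$cage_id, metrics$cage_id)]
  )
  if (!is.null(balances)) {
    for (nu in c("C", "N", "P")) {
      sub <- balances[balances$nutrient == nu, ]
      vars[[paste0(tolower(nu), "_loss")]] <-
        sub$loss[match(vars$cage_id, sub$cage_id)]
    }
  }
  pair_axes <- list(
    feed_vs_c_loss = c("feed", "c_loss"),
    feed_vs_n_loss = c("feed", "n_loss"),
    feed_vs_p_loss = c("feed", "p_loss"),
    feed_vs_net_yield = c("feed", "net_yield"),
    stocking_density_vs_net_yield = c("stocking_density", "net_yield"),
    cycle_days_vs_net_yield = c("cycle_days", "net_yield"),
    feeding_rate_vs_net_yield = c("feeding_rate", "net_yield"),
    feed_vs_survival = c("feed", "survival")
  )
  unknown <- setdiff(pairs, names(pair_axes))
  if (length(unknown) > 0) {
    stop("unknown relationship pair(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(pairs, function(p) {
    ax <- pair_axes[[p]]
    fit <- fit_cage_ols(vars[[ax[1]]], vars[[ax[2]]])
    tibble::tibble(pair = p, slope = fit$slope, intercept = fit$intercept,
                   r_squared = fit$r_squared, n = fit$n)
  })
}

#' Scatter-plus-fitted-line plot for one relationship
#'
#' @param x,y Numeric vectors (one point per cage).
#' @param xlab,ylab Axis labels.
#' @return A ggplot object with the points and the least-squares line.
#' @export
plot_relationship <- function(x, y, xlab = "x", ylab = "y") {
  fit <- fit_cage_ols(x, y)
  df <- tibble::tibble(x = x, y = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = xlab, y = ylab,
      subtitle = sprintf("y = %.4g x + %.4g,  r² = %.3f",
                         fit$slope, fit$intercept, fit$r_squared)
    ) +
    ggplot2::theme_minimal()
}
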