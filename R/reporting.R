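# End-of-horizon comparison statistics versus the base case, tabular
# export, and an optional boxplot of the per-country relative changes.

#' Final prices of a trajectory
#'
#' The last (horizon-month) column, restricted to countries that have a
#' price. Countries that never priced are omitted with a warning.
#'
#' @param traj An `epr_trajectory`.
#' @return Named numeric vector of final prices.
#' @export
final_prices <- function(traj) {
  stopifnot(inherits(traj, "epr_trajectory"))
  last <- traj[, ncol(traj)]
  unset <- names(last)[is.na(last)]
  if (length(unset))
    warning("countries never priced within the horizon: ",
            paste(unset, collapse = ", "), call. = FALSE)
  last[!is.na(last)]
}

#' Compare a scenario trajectory with the base case
#'
#' For every simulated (non-exogenous) country priced at the horizon in
#' both runs, the relative change
#' `(scenario final - base final) / base final` as a signed fraction
#' (negative = cheaper than the base case), plus the unweighted arithmetic
#' mean and the five-number summary (min, Q1, median, Q3, max; quartiles by
#' linear interpolation between closest ranks). Countries unpriced in
#' either run are excluded and reported in the `excluded` element.
#'
#' @param scenario_traj,base_traj `epr_trajectory` objects over the same
#'   country universe and horizon.
#' @return An object of class `scenario_comparison` with elements
#'   `per_country`, `mean_change`, `quartiles` and `excluded`.
#' @examples
#' traj <- run_simulation(fixture_cascade()$config)
#' compare_to_base(traj, traj)$mean_change
#' @export
compare_to_base <- function(scenario_traj, base_traj) {
  stopifnot(inherits(scenario_traj, "epr_trajectory"),
            inherits(base_traj, "epr_trajectory"))
  if (!setequal(rownames(scenario_traj), rownames(base_traj)) ||
      ncol(scenario_traj) != ncol(base_traj))
    stop("trajectories cover different country universes or horizons",
         call. = FALSE)
  simulated <- setdiff(attr(base_traj, "simulated"),
                       attr(base_traj, "exogenous"))
  s <- scenario_traj[simulated, ncol(scenario_traj)]
  b <- base_traj[simulated, ncol(base_traj)]
  ok <- !is.na(s) & !is.na(b)
  excluded <- simulated[!ok]
  per_country <- (s[ok] - b[ok]) / b[ok]
  per_country <- per_country[order(names(per_country))]
  q <- stats::quantile(per_country, probs = c(0, 0.25, 0.5, 0.75, 1),
                       names = FALSE, type = 7)
  structure(list(
    per_country = per_country,
    mean_change = mean(per_country),
    quartiles = stats::setNames(q, c("min", "q1", "median", "q3", "max")),
    excluded = excluded
  ), class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison>\n")
  cat(sprintf("  mean change: %+.1f%% over %d countries\n",
              100 * x$mean_change, length(x$per_country)))
  q <- 100 * x$quartiles
  cat(sprintf("  min %+.1f%%  Q1 %+.1f%%  median %+.1f%%  Q3 %+.1f%%  max %+.1f%%\n",
              q[1], q[2], q[3], q[4], q[5]))
  if (length(x$excluded))
    cat("  excluded (unpriced):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate scenario comparisons
#'
#' One row per (scenario, country) with the relative change, plus one
#' summary row per scenario carrying the mean and the five-number summary.
#' Rows are ordered by scenario (input order), then country code, with the
#' summary row last. Values are kept at full precision (round at display
#' time only; 0.1 percentage points is the conventional display
#' precision).
#'
#' @param comparisons Named list of [compare_to_base()] results.
#' @return A data frame with columns `scenario`, `country` (`NA` on
#'   summary rows), `change`, `mean_change`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
summary_table <- function(comparisons) {
  stopifnot(length(comparisons) > 0L,
            !is.null(names(comparisons)), all(nzchar(names(comparisons))))
  blocks <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    stopifnot(inherits(cmp, "scenario_comparison"))
    country_rows <- data.frame(
      scenario = nm,
      country = names(cmp$per_country),
      change = unname(cmp$per_country),
      mean_change = NA_real_, min = NA_real_, q1 = NA_real_,
      median = NA_real_, q3 = NA_real_, max = NA_real_,
      stringsAsFactors = FALSE
    )
    summary_row <- data.frame(
      scenario = nm, country = NA_character_, change = NA_real_,
      mean_change = cmp$mean_change,
      min = cmp$quartiles[["min"]], q1 = cmp$quartiles[["q1"]],
      median = cmp$quartiles[["median"]], q3 = cmp$quartiles[["q3"]],
      max = cmp$quartiles[["max"]],
      stringsAsFactors = FALSE
    )
    rbind(country_rows, summary_row)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Boxplot of per-country changes, one box per scenario
#'
#' The conventional display of a scenario batch: the distribution over
#' countries of the relative price change at the horizon versus the base
#' case. Requires ggplot2.
#'
#' @param comparisons Named list of [compare_to_base()] results.
#' @return A ggplot object.
#' @export
plot_scenario_changes <- function(comparisons) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_scenario_changes requires the ggplot2 package",
         call. = FALSE)
  df <- do.call(rbind, lapply(names(comparisons), function(nm) {
    data.frame(scenario = nm,
               change = 100 * unname(comparisons[[nm]]$per_country),
               stringsAsFactors = FALSE)
  }))
  df$scenario <- factor(df$scenario, levels = names(comparisons))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$change)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL,
                  y = "price change vs base case after 10 years (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
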