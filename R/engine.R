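# The discrete-event core. One month is the basic time period; every
# month-t+1 price is computed synchronously from the month-t state, so the
# trajectory is independent of the order in which countries are listed.

#' Initial price state of a simulation
#'
#' Month-0 state: kick-off and exogenous prices set (with `set_month = 0`),
#' every other country unpriced (`NA`).
#'
#' @param config A valid [simulation_config()].
#' @return An object of class `price_state` with elements `month`, `prices`
#'   (named numeric, `NA` = not yet priced) and `set_month`.
#' @export
initialize_state <- function(config) {
  codes <- unique(c(names(config$countries), names(config$kickoff),
                    names(config$exogenous)))
  prices <- stats::setNames(rep(NA_real_, length(codes)), codes)
  set_month <- stats::setNames(rep(NA_integer_, length(codes)), codes)
  prices[names(config$kickoff)] <- config$kickoff
  prices[names(config$exogenous)] <- config$exogenous
  set_month[names(c(config$kickoff, config$exogenous))] <- 0L
  structure(list(month = 0L, prices = prices, set_month = set_month),
            class = "price_state")
}

# Collect the quotes a country sees in `prices`: walk the priority pool,
# keep the first `active_count` members with an available price, adjust
# each under the active policy. Cap prices (Latvia) are taken from the same
# state and adjusted identically; unavailable caps are omitted.
.gather_quotes <- function(cc, prices, policy) {
  avail <- cc$pool[!is.na(prices[cc$pool])]
  use <- avail[seq_len(min(cc$active_count, length(avail)))]
  adjusted <- vapply(use, function(ref)
    adjust_reference_price(prices[[ref]], ref, cc$code, policy), numeric(1))
  caps <- numeric(0)
  if (cc$rule$variant == "kth_lowest_capped") {
    cap_avail <- cc$rule$caps[!is.na(prices[cc$rule$caps])]
    caps <- vapply(cap_avail, function(ref)
      adjust_reference_price(prices[[ref]], ref, cc$code, policy),
      numeric(1))
  }
  list(adjusted = adjusted, caps = caps)
}

#' Advance the simulation by one month
#'
#' All evaluations read the month-t prices; there are no within-month
#' cascades. An unpriced country sets its first price as soon as at least
#' `min_required` of its (first `active_count`) pool members have prices.
#' A priced, non-exogenous country with revision interval `R` re-derives
#' its benchmark at `set_month + R`, `set_month + 2R`, ... (keeping the old
#' price should fewer than `min_required` references be available);
#' otherwise the price carries forward unchanged. Countries without a
#' revision interval never change after first setting.
#'
#' @param state A `price_state` (see [initialize_state()]).
#' @param config The [simulation_config()] the state belongs to.
#' @return The `price_state` of month `state$month + 1`.
#' @export
step_month <- function(state, config) {
  t1 <- state$month + 1L
  prices <- state$prices
  set_month <- state$set_month
  new_prices <- prices
  new_set <- set_month
  policy <- config$adjustments
  exo <- names(config$exogenous)

  for (cc in config$countries) {
    code <- cc$code
    if (code %in% exo) next
    if (is.na(prices[[code]])) {
      q <- .gather_quotes(cc, prices, policy)
      if (length(q$adjusted) >= cc$min_required) {
        new_prices[[code]] <- compute_benchmark(cc$rule, q$adjusted, q$caps)
        new_set[[code]] <- t1
      }
    } else if (!is.na(cc$revision_interval)) {
      since <- t1 - set_month[[code]]
      if (since > 0L && since %% cc$revision_interval == 0L) {
        q <- .gather_quotes(cc, prices, policy)
        if (length(q$adjusted) >= cc$min_required)
          new_prices[[code]] <- compute_benchmark(cc$rule, q$adjusted,
                                                  q$caps)
      }
    }
  }
  structure(list(month = t1, prices = new_prices, set_month = new_set),
            class = "price_state")
}

#' Run a simulation to its horizon
#'
#' Iterates [step_month()] from [initialize_state()]. Fully deterministic:
#' identical across runs and across orderings of the country list; no
#' inflation, deflation or exchange-rate drift anywhere.
#'
#' @param config A valid [simulation_config()].
#' @param horizon Optional override of `config$horizon` (months).
#' @return An `epr_trajectory`: a country x month matrix of prices with
#'   `NA` for not-yet-priced entries, columns `"0"` to `"<horizon>"`, and
#'   attributes `simulated` and `exogenous` carrying the country roles.
#' @examples
#' traj <- run_simulation(fixture_cascade()$config)
#' traj["C", "2"]
#' @export
run_simulation <- function(config, horizon = config$horizon) {
  violations <- validate_config(config)
  if (length(violations))
    stop("invalid configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  horizon <- as.integer(horizon)
  state <- initialize_state(config)
  codes <- names(state$prices)
  traj <- matrix(NA_real_, nrow = length(codes), ncol = horizon + 1L,
                 dimnames = list(codes, as.character(0:horizon)))
  traj[, 1L] <- state$prices
  if (horizon > 0L) {
    for (m in seq_len(horizon)) {
      state <- step_month(state, config)
      traj[, m + 1L] <- state$prices
    }
  }
  structure(traj,
            class = c("epr_trajectory", "matrix", "array"),
            simulated = setdiff(codes, names(config$exogenous)),
            exogenous = names(config$exogenous))
}

#' @export
print.epr_trajectory <- function(x, ...) {
  h <- ncol(x) - 1L
  cat(sprintf("<epr_trajectory> %d countries x %d months\n", nrow(x), h))
  last <- x[, ncol(x)]
  set <- sum(!is.na(last))
  cat(sprintf("  priced at month %d: %d/%d countries\n", h, set, nrow(x)))
  invisible(x)
}

#' Long-format view of a trajectory
#'
#' @param x An `epr_trajectory`.
#' @param row.names,optional Ignored (standard [as.data.frame()] arguments).
#' @param ... Ignored.
#' @return A data frame with columns `country`, `month`, `price` (`NA`
#'   while unpriced) and `is_set`.
#' @export
as.data.frame.epr_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  countries <- rownames(x)
  months <- as.integer(colnames(x))
  data.frame(
    country = rep(countries, times = length(months)),
    month = rep(months, each = length(countries)),
    price = as.vector(unclass(x)),
    is_set = !is.na(as.vector(unclass(x))),
    stringsAsFactors = FALSE
  )
}

#' Export one or more trajectories as long-format CSV
#'
#' Columns `scenario`, `country`, `month`, `price`, `is_set`; an unpriced
#' entry is written as an empty price field.
#'
#' @param trajectories A single `epr_trajectory` or a named list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectories, path) {
  if (inherits(trajectories, "epr_trajectory"))
    trajectories <- list(trajectory = trajectories)
  stopifnot(length(names(trajectories)) == length(trajectories))
  rows <- lapply(names(trajectories), function(nm) {
    df <- as.data.frame(trajectories[[nm]])
    cbind(scenario = nm, df, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
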