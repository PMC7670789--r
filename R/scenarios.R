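# Policy scenarios: declarative transforms of the base-case configuration.
# Each built-in scenario changes exactly one parameter of the EPR
# methodology for all simulated countries, leaving the rest country-specific.

.BUILTIN_SCENARIOS <- c(
  "base_case", "strategic_basket", "large_basket", "lowest_price",
  "statutory_discounts", "statutory_and_commercial_discounts", "ppp",
  "biannual_revisions"
)

.STRATEGIC_BASKET <- c("DE", "IT", "FI", "PT")

#' Construct a scenario specification
#'
#' Either one of the eight built-in scenarios by name, or a user-defined
#' scenario carrying explicit overrides.
#'
#' Built-in scenarios (one parameter changed for every simulated country):
#' `base_case` (identity), `strategic_basket` (basket becomes Germany,
#' Italy, Finland, Portugal — a mix of high-, middle- and low-priced
#' countries — minus the country itself), `large_basket` (basket becomes
#' all 30 other countries of the universe), `lowest_price` (every
#' benchmark formula becomes the minimum), `statutory_discounts`
#' (statutory rebates in Germany, Greece and Ireland are considered),
#' `statutory_and_commercial_discounts` (additionally an assumed 20%
#' confidential discount on quotes from the configured large economies),
#' `ppp` (quotes rescaled by purchasing power parities) and
#' `biannual_revisions` (every country, including former no-revision
#' countries, revises every 6 months).
#'
#' @param name Scenario name.
#' @param basket Override: replacement basket (codes; the own country is
#'   always excluded at application time).
#' @param rule Override: replacement [benchmark_rule()] for every country.
#' @param revision_interval Override: replacement revision interval.
#' @param adjustments Override: named logical, e.g.
#'   `c(statutory = TRUE)` — flags to activate.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("lowest_price")
#' scenario_spec("my_scenario", revision_interval = 12)
#' @export
scenario_spec <- function(name, basket = NULL, rule = NULL,
                          revision_interval = NULL, adjustments = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  overrides <- !vapply(list(basket, rule, revision_interval, adjustments),
                       is.null, logical(1))
  if (!name %in% .BUILTIN_SCENARIOS && !any(overrides))
    stop("unknown scenario '", name,
         "' and no explicit overrides supplied", call. = FALSE)
  structure(list(name = name, basket = basket, rule = rule,
                 revision_interval = revision_interval,
                 adjustments = adjustments),
            class = "scenario_spec")
}

#' The eight bundled scenario specifications
#'
#' @return Named list of [scenario_spec()] objects: the base case plus the
#'   seven one-parameter policy changes.
#' @export
builtin_scenarios <- function() {
  specs <- lapply(.BUILTIN_SCENARIOS, scenario_spec)
  stats::setNames(specs, .BUILTIN_SCENARIOS)
}

.replace_baskets <- function(config, basket) {
  config$countries <- lapply(config$countries, function(cc) {
    pool <- setdiff(basket, cc$code)
    cc$pool <- pool
    cc$active_count <- length(pool)
    cc$min_required <- min(cc$min_required, length(pool))
    cc
  })
  names(config$countries) <- vapply(config$countries, `[[`, character(1),
                                    "code")
  config
}

#' Apply a scenario to a base configuration
#'
#' Returns a new, valid configuration; the input is never modified.
#' `base_case` is the identity.
#'
#' @param base A valid [simulation_config()] (normally
#'   [builtin_base_case()]).
#' @param spec A [scenario_spec()] or a scenario name.
#' @return A new [simulation_config()].
#' @examples
#' base <- builtin_base_case()
#' apply_scenario(base, "strategic_basket")$countries$AT$pool
#' @export
apply_scenario <- function(base, spec) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(base, "simulation_config"))
  config <- base

  if (spec$name %in% .BUILTIN_SCENARIOS) {
    config <- switch(spec$name,
      base_case = config,
      strategic_basket = .replace_baskets(config, .STRATEGIC_BASKET),
      large_basket = {
        universe <- if (length(config$universe)) config$universe else
          unique(c(names(config$countries), names(config$kickoff),
                   names(config$exogenous)))
        .replace_baskets(config, universe)
      },
      lowest_price = {
        config$countries <- lapply(config$countries, function(cc) {
          cc$rule <- benchmark_rule("minimum")
          cc
        })
        names(config$countries) <- vapply(config$countries, `[[`,
                                          character(1), "code")
        config
      },
      statutory_discounts = {
        config$adjustments$active[["statutory"]] <- TRUE
        config
      },
      statutory_and_commercial_discounts = {
        config$adjustments$active[["statutory"]] <- TRUE
        config$adjustments$active[["commercial"]] <- TRUE
        config
      },
      ppp = {
        config$adjustments$active[["ppp"]] <- TRUE
        config
      },
      biannual_revisions = {
        config$countries <- lapply(config$countries, function(cc) {
          cc$revision_interval <- 6L
          cc
        })
        names(config$countries) <- vapply(config$countries, `[[`,
                                          character(1), "code")
        config
      }
    )
  }

  if (!is.null(spec$basket))
    config <- .replace_baskets(config, spec$basket)
  if (!is.null(spec$rule)) {
    config$countries <- lapply(config$countries, function(cc) {
      cc$rule <- spec$rule
      cc
    })
    names(config$countries) <- vapply(config$countries, `[[`, character(1),
                                      "code")
  }
  if (!is.null(spec$revision_interval)) {
    config$countries <- lapply(config$countries, function(cc) {
      cc$revision_interval <- as.integer(spec$revision_interval)
      cc
    })
    names(config$countries) <- vapply(config$countries, `[[`, character(1),
                                      "code")
  }
  if (!is.null(spec$adjustments))
    config$adjustments$active[names(spec$adjustments)] <-
      as.logical(spec$adjustments)

  violations <- validate_config(config)
  if (length(violations))
    stop("scenario '", spec$name, "' produced an invalid configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  config
}

#' Run a batch of scenarios
#'
#' @param base A valid [simulation_config()].
#' @param specs Named or unnamed list of [scenario_spec()] objects (or
#'   scenario names); defaults to the eight bundled scenarios.
#' @return Named list of `epr_trajectory` objects, one per scenario.
#' @examples
#' \donttest{
#' trajs <- run_all_scenarios(builtin_base_case())
#' names(trajs)
#' }
#' @export
run_all_scenarios <- function(base, specs = builtin_scenarios()) {
  if (length(specs) == 0L) stop("no scenarios supplied", call. = FALSE)
  specs <- lapply(specs, function(s) if (is.character(s)) scenario_spec(s)
                  else s)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate scenario names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  out <- lapply(specs, function(s) run_simulation(apply_scenario(base, s)))
  stats::setNames(out, nms)
}
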