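# Country rulebooks and full simulation configurations: constructors,
# structural validation, and a YAML serialisation round-trip.

#' Construct one country's EPR rulebook
#'
#' @param code Two-letter country code.
#' @param pool Priority-ordered reference pool (country codes). For most
#'   countries the whole pool is the basket; countries with a "k out of n"
#'   arrangement (Croatia 3-of-5, Cyprus 4-of-10) evaluate the first
#'   `active_count` pool members that have an available price, falling
#'   through to lower-priority alternatives when data are missing.
#' @param rule A [benchmark_rule()].
#' @param min_required Reference prices that must be available before the
#'   country's first price can be set.
#' @param active_count Pool members used per evaluation; defaults to the
#'   full pool.
#' @param revision_interval Months between scheduled price revisions,
#'   anchored at the country's first price setting; `NA` for countries
#'   whose legislation provides no revision.
#' @return An object of class `country_epr_config`.
#' @examples
#' country_epr_config("AT", pool = c("DE", "IT"),
#'                    rule = benchmark_rule("average"), min_required = 2)
#' @export
country_epr_config <- function(code, pool, rule,
                               min_required = 1L,
                               active_count = length(pool),
                               revision_interval = NA_integer_) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  structure(list(
    code = code,
    pool = as.character(pool),
    active_count = as.integer(active_count),
    min_required = as.integer(min_required),
    rule = rule,
    revision_interval = if (is.null(revision_interval) ||
                            is.na(revision_interval)) NA_integer_
                        else as.integer(revision_interval)
  ), class = "country_epr_config")
}

#' @export
print.country_epr_config <- function(x, ...) {
  cat(sprintf("<country_epr_config> %s: pool %d (use %d, need %d), %s, %s\n",
              x$code, length(x$pool), x$active_count, x$min_required,
              format(x$rule),
              if (is.na(x$revision_interval)) "no revision"
              else sprintf("revise every %d months", x$revision_interval)))
  invisible(x)
}

#' Construct a full simulation configuration
#'
#' @param countries List of [country_epr_config()] objects, one per
#'   simulated country.
#' @param kickoff Named numeric: launch prices seeding the cascade (the
#'   bundled base case launches Germany at 100 and Italy at 70). Kick-off
#'   countries may also carry a rulebook in `countries`, in which case they
#'   are revised on their own schedule but never re-derived at launch.
#' @param exogenous Named numeric: countries referenced at a constant price
#'   and never simulated (Denmark, Sweden, UK at 100 in the base case).
#' @param horizon Simulation horizon in months (`120` = 10 years).
#' @param adjustments An [adjustment_policy()].
#' @param universe Optional declared country universe; defaults to every
#'   code mentioned by the configuration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(countries,
                              kickoff = numeric(0),
                              exogenous = numeric(0),
                              horizon = 120L,
                              adjustments = adjustment_policy(),
                              universe = NULL) {
  countries <- unname(countries)
  codes <- vapply(countries, function(cc) cc$code, character(1))
  names(countries) <- codes
  if (is.null(universe)) {
    universe <- unique(c(codes, names(kickoff), names(exogenous),
                         unlist(lapply(countries, `[[`, "pool"),
                                use.names = FALSE)))
  }
  structure(list(
    horizon = as.integer(horizon),
    kickoff = vapply(kickoff, as.numeric, numeric(1)),
    exogenous = vapply(exogenous, as.numeric, numeric(1)),
    countries = countries,
    adjustments = adjustments,
    universe = as.character(universe)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> %d simulated countries, ",
                     "%d kick-off, %d exogenous, horizon %d months\n"),
              length(x$countries), length(x$kickoff), length(x$exogenous),
              x$horizon))
  invisible(x)
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant and returns a character vector of
#' violations, each naming the country, field and rule breached. Validation
#' never raises; an empty vector means the configuration is valid.
#'
#' @param config A [simulation_config()].
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(...) v <<- c(v, sprintf(...))

  if (!inherits(config, "simulation_config"))
    return("not a simulation_config object")
  if (is.na(config$horizon) || config$horizon < 0)
    add("horizon: must be a non-negative number of months")

  codes <- names(config$countries)
  if (anyDuplicated(codes))
    add("countries: duplicate codes (%s)",
        paste(unique(codes[duplicated(codes)]), collapse = ", "))

  both <- intersect(names(config$kickoff), names(config$exogenous))
  if (length(both))
    add("kickoff/exogenous: sets must be disjoint (%s)",
        paste(both, collapse = ", "))
  for (nm in names(config$kickoff))
    if (!is.finite(config$kickoff[[nm]]) || config$kickoff[[nm]] <= 0)
      add("%s: kickoff price must be positive", nm)
  for (nm in names(config$exogenous))
    if (!is.finite(config$exogenous[[nm]]) || config$exogenous[[nm]] <= 0)
      add("%s: exogenous price must be positive", nm)

  known <- unique(c(codes, names(config$kickoff), names(config$exogenous)))
  if (length(config$universe)) {
    out <- setdiff(known, config$universe)
    if (length(out))
      add("universe: codes outside the declared universe (%s)",
          paste(out, collapse = ", "))
  }

  for (cc in config$countries) {
    code <- cc$code
    if (cc$code %in% cc$pool)
      add("%s: pool: self-reference (a country never references itself)",
          code)
    if (anyDuplicated(cc$pool))
      add("%s: pool: duplicate members (%s)", code,
          paste(unique(cc$pool[duplicated(cc$pool)]), collapse = ", "))
    if (length(cc$pool) == 0L)
      add("%s: pool: empty reference pool", code)
    unresolved <- setdiff(cc$pool, known)
    if (length(unresolved))
      add("%s: pool: members that are neither simulated, kick-off nor exogenous (%s)",
          code, paste(unresolved, collapse = ", "))
    if (is.na(cc$active_count) || cc$active_count < 1 ||
        cc$active_count > length(cc$pool))
      add("%s: active_count: must satisfy 1 <= active_count <= pool size",
          code)
    if (is.na(cc$min_required) || cc$min_required < 1)
      add("%s: min_required: must be a positive integer", code)
    else if (!is.na(cc$active_count) && cc$min_required > cc$active_count)
      add("%s: min_required: exceeds active_count (min_required %d > %d)",
          code, cc$min_required, cc$active_count)
    if (!inherits(cc$rule, "benchmark_rule"))
      add("%s: rule: not a benchmark_rule", code)
    else if (cc$rule$variant == "kth_lowest_capped") {
      if (code %in% cc$rule$caps)
        add("%s: rule: cap countries must not include the country itself",
            code)
      badcap <- setdiff(cc$rule$caps, known)
      if (length(badcap))
        add("%s: rule: unknown cap countries (%s)", code,
            paste(badcap, collapse = ", "))
    }
    if (!is.na(cc$revision_interval) && cc$revision_interval < 1)
      add("%s: revision_interval: must be a positive number of months or NA",
          code)
  }

  adj <- config$adjustments
  if (!inherits(adj, "adjustment_policy")) {
    add("adjustments: not an adjustment_policy")
  } else {
    bad <- names(adj$statutory_rates)[adj$statutory_rates < 0 |
                                      adj$statutory_rates >= 1]
    if (length(bad))
      add("adjustments: statutory rates outside [0, 1) for %s",
          paste(bad, collapse = ", "))
    if (adj$commercial_rate < 0 || adj$commercial_rate >= 1)
      add("adjustments: commercial rate outside [0, 1)")
    if (any(adj$ppp_index <= 0, na.rm = TRUE))
      add("adjustments: PPP indices must be positive")
    if (adj$active[["ppp"]]) {
      involved <- unique(c(codes,
                           unlist(lapply(config$countries, `[[`, "pool"),
                                  use.names = FALSE)))
      miss <- setdiff(involved, names(adj$ppp_index))
      if (length(miss))
        add("adjustments: PPP active but no index for %s",
            paste(miss, collapse = ", "))
    }
  }
  v
}

# ---- YAML serialisation ----------------------------------------------------

# YAML 1.1 would read the country code NO (Norway) as boolean false. Parse
# with handlers that keep yes/no/on/off-style scalars as strings and only
# true/false (any case) as logicals; the writer quotes 'NO' on the way out.
.yaml_bool_handler <- function(x) {
  if (tolower(x) %in% c("true", "false")) as.logical(toupper(x)) else x
}

.read_yaml_safe <- function(path) {
  yaml::read_yaml(path, handlers = list("bool#yes" = .yaml_bool_handler,
                                        "bool#no" = .yaml_bool_handler))
}

.rule_to_list <- function(rule) {
  out <- list(variant = rule$variant)
  if (!is.null(rule$m)) out$m <- rule$m
  if (!is.null(rule$k)) out$k <- rule$k
  if (!is.null(rule$caps)) out$caps <- as.list(rule$caps)
  out
}

.rule_from_list <- function(x, where) {
  if (is.null(x$variant))
    stop("config error at ", where, ": rule has no 'variant'", call. = FALSE)
  benchmark_rule(x$variant, m = x$m, k = x$k,
                 caps = if (!is.null(x$caps)) unlist(x$caps))
}

.named_numeric <- function(x) {
  if (is.null(x) || length(x) == 0L) return(numeric(0))
  vapply(x, as.numeric, numeric(1))
}

#' Read a simulation configuration from a YAML file
#'
#' The schema has top-level keys `universe`, `kickoff`, `exogenous`,
#' `horizon_months`, `countries` (a sequence of mappings with `code`,
#' `pool`, `active_count`, `min_required`, `rule`, `revision_interval`) and
#' `adjustments`. [write_simulation_config()] writes the same dialect;
#' loading a written configuration reproduces it exactly.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated [simulation_config()].
#' @seealso [builtin_base_case()] for the bundled 2015 base case.
#' @export
load_simulation_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  raw <- tryCatch(.read_yaml_safe(path), error = function(e)
    stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE))

  countries <- lapply(raw$countries, function(cc) {
    if (is.null(cc$code))
      stop("config error in ", path, ": country entry without 'code'",
           call. = FALSE)
    pool <- as.character(unlist(cc$pool))
    country_epr_config(
      code = cc$code,
      pool = pool,
      rule = .rule_from_list(cc$rule, paste0("country ", cc$code)),
      min_required = if (is.null(cc$min_required)) 1L else cc$min_required,
      active_count = if (is.null(cc$active_count)) length(pool)
                     else cc$active_count,
      revision_interval = if (is.null(cc$revision_interval)) NA_integer_
                          else cc$revision_interval
    )
  })

  adjraw <- raw$adjustments
  adjustments <- if (is.null(adjraw)) adjustment_policy() else {
    adjustment_policy(
      statutory_rates = .named_numeric(adjraw$statutory$rates),
      commercial_rate = if (is.null(adjraw$commercial$rate)) 0
                        else adjraw$commercial$rate,
      commercial_countries = as.character(unlist(adjraw$commercial$countries)),
      ppp_index = .named_numeric(adjraw$ppp$index),
      active = c(statutory = isTRUE(adjraw$statutory$active),
                 commercial = isTRUE(adjraw$commercial$active),
                 ppp = isTRUE(adjraw$ppp$active))
    )
  }

  config <- simulation_config(
    countries = countries,
    kickoff = .named_numeric(raw$kickoff),
    exogenous = .named_numeric(raw$exogenous),
    horizon = if (is.null(raw$horizon_months)) 120L else raw$horizon_months,
    adjustments = adjustments,
    universe = if (!is.null(raw$universe)) as.character(unlist(raw$universe))
  )

  violations <- validate_config(config)
  if (length(violations))
    stop("invalid configuration in ", path, ":\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  config
}

#' Write a simulation configuration to a YAML file
#'
#' @param config A [simulation_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  adj <- config$adjustments
  out <- list(
    universe = as.list(config$universe),
    horizon_months = config$horizon,
    kickoff = as.list(config$kickoff),
    exogenous = as.list(config$exogenous),
    countries = lapply(unname(config$countries), function(cc) {
      entry <- list(
        code = cc$code,
        pool = as.list(cc$pool),
        active_count = cc$active_count,
        min_required = cc$min_required,
        rule = .rule_to_list(cc$rule)
      )
      if (!is.na(cc$revision_interval))
        entry$revision_interval <- cc$revision_interval
      entry
    }),
    adjustments = list(
      statutory = list(active = unname(adj$active[["statutory"]]),
                       rates = as.list(adj$statutory_rates)),
      commercial = list(active = unname(adj$active[["commercial"]]),
                        rate = adj$commercial_rate,
                        countries = as.list(adj$commercial_countries)),
      ppp = list(active = unname(adj$active[["ppp"]]),
                 index = as.list(adj$ppp_index))
    )
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
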