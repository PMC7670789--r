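# Seeded generator of random EPR country networks, plus a hand-traceable
# cascade fixture. The generator is the only source of randomness in the
# package; simulations themselves are deterministic.

#' Recipe for a random EPR country network
#'
#' Structural ranges default to the regime observed in the 2015 survey:
#' basket sizes between 1 and 30, revision intervals drawn from
#' none/6/12/24/36/60 months, a rule mix dominated by average and minimum.
#'
#' @param seed Integer seed; identical recipes generate identical systems.
#' @param n_countries Total countries (kick-off sources + simulated),
#'   at least 2.
#' @param basket_size_range Length-2 integer vector `(lo, hi)`; clamped to
#'   `n_countries - 1`.
#' @param rule_mix Named non-negative weights over
#'   `c("average", "minimum", "avg_lowest", "kth_lowest")`.
#' @param revision_mix Named non-negative weights over
#'   `c("none", "6", "12", "24", "36", "60")`.
#' @param min_required_policy Function mapping a basket size to the
#'   minimum-availability requirement (clipped into `[1, size]`). Default:
#'   always 1, the most common surveyed value.
#' @param kickoff_fraction Fraction of countries given constant launch
#'   prices (at least one country is always a kick-off source).
#' @param price_range Range the kick-off launch prices are drawn from.
#' @param horizon Horizon in months attached to generated configurations.
#' @return An object of class `system_recipe`.
#' @export
system_recipe <- function(seed,
                          n_countries = 8L,
                          basket_size_range = c(1L, 4L),
                          rule_mix = c(average = 0.4, minimum = 0.3,
                                       avg_lowest = 0.2, kth_lowest = 0.1),
                          revision_mix = c(none = 0.3, `6` = 0.2, `12` = 0.2,
                                           `24` = 0.1, `36` = 0.1,
                                           `60` = 0.1),
                          min_required_policy = function(size) 1L,
                          kickoff_fraction = 0.25,
                          price_range = c(50, 150),
                          horizon = 60L) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_countries >= 2L,
            length(basket_size_range) == 2L,
            basket_size_range[1] >= 1L,
            basket_size_range[1] <= basket_size_range[2],
            all(rule_mix >= 0), sum(rule_mix) > 0,
            all(revision_mix >= 0), sum(revision_mix) > 0,
            is.function(min_required_policy),
            kickoff_fraction > 0, kickoff_fraction < 1,
            length(price_range) == 2L, price_range[1] > 0,
            price_range[1] <= price_range[2],
            horizon >= 0L)
  if (basket_size_range[1] > n_countries - 1L)
    stop("infeasible recipe: smallest basket exceeds n_countries - 1",
         call. = FALSE)
  allowed_rules <- c("average", "minimum", "avg_lowest", "kth_lowest")
  rule_mix <- rule_mix[intersect(names(rule_mix), allowed_rules)]
  if (length(rule_mix) == 0L)
    stop("rule_mix names none of: ",
         paste(allowed_rules, collapse = ", "), call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    n_countries = as.integer(n_countries),
    basket_size_range = as.integer(basket_size_range),
    rule_mix = rule_mix,
    revision_mix = revision_mix,
    min_required_policy = min_required_policy,
    kickoff_fraction = kickoff_fraction,
    price_range = as.numeric(price_range),
    horizon = as.integer(horizon)
  ), class = "system_recipe")
}

# Two-letter synthetic codes: ZA, ZB, ... then YA, YB, ... — disjoint from
# the real 2015 universe is not guaranteed nor needed; synthetic systems
# declare their own universe.
.synthetic_codes <- function(n) {
  grid <- as.vector(outer(LETTERS, rev(LETTERS),
                          function(a, b) paste0(b, a)))
  if (n > length(grid)) stop("too many countries requested", call. = FALSE)
  grid[seq_len(n)]
}

# sample() with deterministic size-1 behaviour (sample(5L, 1) would draw
# from 1:5).
.pick <- function(x, size) x[sample.int(length(x), size)]

#' Generate a random EPR country network
#'
#' A deterministic function of its recipe: the RNG is seeded from
#' `recipe$seed` and the caller's RNG state is left untouched. Kick-off
#' countries are constant price sources (no rulebook); every simulated
#' country gets a random priority pool over the other countries, a rule
#' drawn from the recipe's mix, and a revision interval from the revision
#' mix. Generated configurations always pass [validate_config()].
#'
#' @param recipe A [system_recipe()].
#' @return A valid [simulation_config()].
#' @examples
#' cfg <- generate_system(system_recipe(seed = 1, n_countries = 6))
#' validate_config(cfg)
#' @export
generate_system <- function(recipe) {
  stopifnot(inherits(recipe, "system_recipe"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(recipe$seed)

  n <- recipe$n_countries
  codes <- .synthetic_codes(n)
  n_kick <- max(1L, min(n - 1L, round(recipe$kickoff_fraction * n)))
  kick_codes <- codes[seq_len(n_kick)]
  sim_codes <- setdiff(codes, kick_codes)
  kickoff <- stats::setNames(
    stats::runif(n_kick, recipe$price_range[1], recipe$price_range[2]),
    kick_codes)

  lo <- recipe$basket_size_range[1]
  hi <- min(recipe$basket_size_range[2], n - 1L)
  rules <- names(recipe$rule_mix)
  rule_w <- recipe$rule_mix / sum(recipe$rule_mix)
  rev_opts <- names(recipe$revision_mix)
  rev_w <- recipe$revision_mix / sum(recipe$revision_mix)

  countries <- lapply(sim_codes, function(code) {
    size <- if (lo == hi) lo else .pick(lo:hi, 1L)
    pool <- .pick(setdiff(codes, code), size)
    variant <- sample(rules, 1L, prob = rule_w)
    rule <- switch(variant,
      average = benchmark_rule("average"),
      minimum = benchmark_rule("minimum"),
      avg_lowest = benchmark_rule("avg_lowest",
                                  m = .pick(1:3, 1L)),
      kth_lowest = benchmark_rule("kth_lowest",
                                  k = .pick(1:3, 1L))
    )
    rev_choice <- sample(rev_opts, 1L, prob = rev_w)
    min_req <- min(max(1L, as.integer(recipe$min_required_policy(size))),
                   size)
    country_epr_config(
      code = code, pool = pool, rule = rule,
      min_required = min_req, active_count = size,
      revision_interval = if (rev_choice == "none") NA_integer_
                          else as.integer(rev_choice)
    )
  })

  config <- simulation_config(
    countries = countries,
    kickoff = kickoff,
    horizon = recipe$horizon,
    universe = codes
  )
  violations <- validate_config(config)
  if (length(violations))  # generator contract: never happens
    stop("generated system failed validation:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  config
}

#' The hand-traceable 3-country cascade fixture
#'
#' Country A launches at 100; B references only A (minimum rule); C
#' references A and B and needs both before averaging. The expected
#' trajectory is derived by hand: B is priced at month 1 (100), C at
#' month 2 (100), and nothing changes afterwards (no revisions).
#'
#' @param horizon Horizon in months (default 6).
#' @return List with elements `config` (a [simulation_config()]) and
#'   `trajectory` (the expected price matrix, countries x months 0..horizon).
#' @examples
#' fix <- fixture_cascade()
#' all.equal(unclass(run_simulation(fix$config))[, ], fix$trajectory)
#' @export
fixture_cascade <- function(horizon = 6L) {
  horizon <- as.integer(horizon)
  config <- simulation_config(
    countries = list(
      country_epr_config("B", pool = "A",
                         rule = benchmark_rule("minimum"),
                         min_required = 1L),
      country_epr_config("C", pool = c("A", "B"),
                         rule = benchmark_rule("average"),
                         min_required = 2L)
    ),
    kickoff = c(A = 100),
    horizon = horizon
  )
  months <- 0:horizon
  expected <- matrix(NA_real_, nrow = 3, ncol = horizon + 1L,
                     dimnames = list(c("B", "C", "A"),
                                     as.character(months)))
  expected["A", ] <- 100
  expected["B", months >= 1] <- 100
  expected["C", months >= 2] <- 100
  list(config = config, trajectory = expected)
}
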