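# Pure price arithmetic: benchmark formulas and reference-price adjustments.
# Everything here is stateless; the engine feeds it month-t quotes.

.RULE_VARIANTS <- c("average", "minimum", "avg_lowest", "kth_lowest",
                    "kth_lowest_capped")

#' Construct a benchmark rule
#'
#' A benchmark rule maps a set of (adjusted) reference prices to a single
#' benchmark price. The variants cover the formulas used by European EPR
#' legislation in 2015: the arithmetic average, the minimum, the average of
#' the `m` lowest prices, the `k`-th lowest price, and the `k`-th lowest
#' price additionally capped by the prices of named countries (Latvia's
#' rule: the third-lowest basket price, not exceeding the price in Lithuania
#' or Estonia).
#'
#' @param variant One of `"average"`, `"minimum"`, `"avg_lowest"`,
#'   `"kth_lowest"`, `"kth_lowest_capped"`.
#' @param m Number of lowest prices averaged (`avg_lowest` only).
#' @param k Rank selected (`kth_lowest` variants only).
#' @param caps Country codes whose prices cap the result
#'   (`kth_lowest_capped` only).
#' @return An object of class `benchmark_rule`.
#' @examples
#' benchmark_rule("avg_lowest", m = 3)
#' benchmark_rule("kth_lowest_capped", k = 3, caps = c("LT", "EE"))
#' @export
benchmark_rule <- function(variant, m = NULL, k = NULL, caps = NULL) {
  variant <- match.arg(variant, .RULE_VARIANTS)
  if (variant == "avg_lowest") {
    if (is.null(m) || length(m) != 1L || is.na(m) || m < 1)
      stop("avg_lowest requires m >= 1", call. = FALSE)
    m <- as.integer(m)
  } else {
    m <- NULL
  }
  if (variant %in% c("kth_lowest", "kth_lowest_capped")) {
    if (is.null(k) || length(k) != 1L || is.na(k) || k < 1)
      stop(variant, " requires k >= 1", call. = FALSE)
    k <- as.integer(k)
  } else {
    k <- NULL
  }
  if (variant == "kth_lowest_capped") {
    if (is.null(caps) || length(caps) == 0L)
      stop("kth_lowest_capped requires a non-empty caps set", call. = FALSE)
    caps <- as.character(caps)
  } else {
    caps <- NULL
  }
  structure(list(variant = variant, m = m, k = k, caps = caps),
            class = "benchmark_rule")
}

#' @export
format.benchmark_rule <- function(x, ...) {
  switch(x$variant,
    average = "average",
    minimum = "minimum",
    avg_lowest = sprintf("average of %d lowest", x$m),
    kth_lowest = sprintf("%d-th lowest", x$k),
    kth_lowest_capped = sprintf("%d-th lowest, capped by %s", x$k,
                                paste(x$caps, collapse = "/"))
  )
}

#' @export
print.benchmark_rule <- function(x, ...) {
  cat("<benchmark_rule> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Compute a benchmark price from reference quotes
#'
#' Applies a [benchmark_rule()] to a vector of adjusted reference prices.
#' When fewer quotes are available than a rank-based rule asks for
#' (`m`-lowest average with fewer than `m` quotes, `k`-th lowest with fewer
#' than `k`), the rule degrades gracefully: all available quotes are
#' averaged, respectively the highest available rank is taken. Capping can
#' only lower the result and ignores cap countries without an available
#' price.
#'
#' @param rule A [benchmark_rule()].
#' @param quotes Non-empty numeric vector of adjusted reference prices.
#' @param cap_prices Named numeric vector of available cap-country prices
#'   (used by `kth_lowest_capped` only; missing cap countries are simply
#'   omitted).
#' @return A single benchmark price.
#' @examples
#' compute_benchmark(benchmark_rule("average"), c(100, 70))
#' compute_benchmark(benchmark_rule("avg_lowest", m = 3), c(100, 90, 80, 70))
#' @export
compute_benchmark <- function(rule, quotes, cap_prices = numeric(0)) {
  stopifnot(inherits(rule, "benchmark_rule"))
  quotes <- as.numeric(quotes)
  if (length(quotes) == 0L)
    stop("compute_benchmark requires at least one reference quote",
         call. = FALSE)
  if (anyNA(quotes))
    stop("reference quotes must not contain NA", call. = FALSE)
  n <- length(quotes)
  sorted <- sort(quotes)
  value <- switch(rule$variant,
    average = mean(quotes),
    minimum = sorted[1L],
    avg_lowest = mean(sorted[seq_len(min(rule$m, n))]),
    kth_lowest = sorted[min(rule$k, n)],
    kth_lowest_capped = sorted[min(rule$k, n)]
  )
  if (rule$variant == "kth_lowest_capped" && length(cap_prices) > 0L) {
    caps <- cap_prices[!is.na(cap_prices)]
    if (length(caps) > 0L) value <- min(value, caps)
  }
  as.numeric(value)
}

#' Construct an adjustment policy
#'
#' Bundles the three price adjustments a referencing country may apply to
#' the quotes it collects, each behind an activation flag:
#'
#' * statutory discounts: published manufacturer rebates in the referenced
#'   country (Germany, Greece and Ireland in 2015), applied as
#'   `raw * (1 - rate)` whenever that country is referenced;
#' * a commercial (confidential) discount: a flat assumed rebate applied to
#'   quotes from a named set of large economies;
#' * purchasing-power-parity adjustment: quotes rescaled to the referencing
#'   country's price level, `raw * index_own / index_ref`, with `index` a
#'   comparative price-level index (any common base; only ratios matter).
#'
#' @param statutory_rates Named numeric, rebate rate in `[0, 1)` per
#'   country that grants a statutory discount. Countries absent from the
#'   mapping carry no statutory discount.
#' @param commercial_rate Single rate in `[0, 1)`.
#' @param commercial_countries Codes whose quotes receive the commercial
#'   discount.
#' @param ppp_index Named positive numeric price-level index.
#' @param active Named logical flags `statutory`, `commercial`, `ppp`.
#' @return An object of class `adjustment_policy`.
#' @export
adjustment_policy <- function(statutory_rates = numeric(0),
                              commercial_rate = 0,
                              commercial_countries = character(0),
                              ppp_index = numeric(0),
                              active = c(statutory = FALSE,
                                         commercial = FALSE,
                                         ppp = FALSE)) {
  act <- c(statutory = FALSE, commercial = FALSE, ppp = FALSE)
  act[names(active)] <- as.logical(active)
  structure(list(
    statutory_rates = statutory_rates,
    commercial_rate = as.numeric(commercial_rate),
    commercial_countries = as.character(commercial_countries),
    ppp_index = ppp_index,
    active = act
  ), class = "adjustment_policy")
}

#' @export
print.adjustment_policy <- function(x, ...) {
  on <- names(x$active)[x$active]
  cat("<adjustment_policy> active:",
      if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Adjust one reference price under an adjustment policy
#'
#' Multiplicative and order-independent:
#' `raw * (1 - statutory_rate_ref) * (1 - commercial_rate) * (ppp_own / ppp_ref)`,
#' with each factor present only when the corresponding flag is active and
#' applicable to `ref`.
#'
#' @param raw_price Positive raw (list) price in the referenced country.
#' @param ref Code of the referenced country.
#' @param own Code of the referencing country (needed for PPP).
#' @param policy An [adjustment_policy()].
#' @return The adjusted price.
#' @examples
#' pol <- adjustment_policy(commercial_rate = 0.2,
#'                          commercial_countries = "DE",
#'                          active = c(commercial = TRUE))
#' adjust_reference_price(100, "DE", "AT", pol)
#' @export
adjust_reference_price <- function(raw_price, ref, own, policy) {
  stopifnot(inherits(policy, "adjustment_policy"))
  p <- raw_price
  if (policy$active[["statutory"]]) {
    rate <- policy$statutory_rates[ref]
    if (!is.na(rate)) {
      if (rate < 0 || rate >= 1)
        stop("statutory rate for ", ref, " outside [0, 1)", call. = FALSE)
      p <- p * (1 - as.numeric(rate))
    }
  }
  if (policy$active[["commercial"]] && ref %in% policy$commercial_countries) {
    if (policy$commercial_rate < 0 || policy$commercial_rate >= 1)
      stop("commercial rate outside [0, 1)", call. = FALSE)
    p <- p * (1 - policy$commercial_rate)
  }
  if (policy$active[["ppp"]]) {
    i_own <- policy$ppp_index[own]
    i_ref <- policy$ppp_index[ref]
    if (is.na(i_own))
      stop("PPP adjustment active but no index for ", own, call. = FALSE)
    if (is.na(i_ref))
      stop("PPP adjustment active but no index for ", ref, call. = FALSE)
    if (i_own <= 0 || i_ref <= 0)
      stop("PPP indices must be positive", call. = FALSE)
    p <- p * as.numeric(i_own) / as.numeric(i_ref)
  }
  as.numeric(p)
}
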