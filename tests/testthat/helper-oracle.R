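# Independent naive simulator used as an oracle: every month, every
# country's due event is re-derived from scratch from the month-t price
# vector, with its own quote collection and rule arithmetic. Kept free of
# any code shared with the package engine.
oracle_run <- function(config, horizon = config$horizon) {
  codes <- unique(c(names(config$countries), names(config$kickoff),
                    names(config$exogenous)))
  price <- setNames(rep(NA_real_, length(codes)), codes)
  price[names(config$kickoff)] <- config$kickoff
  price[names(config$exogenous)] <- config$exogenous
  first_set <- setNames(rep(NA_integer_, length(codes)), codes)
  first_set[!is.na(price)] <- 0L
  out <- matrix(NA_real_, length(codes), horizon + 1L,
                dimnames = list(codes, as.character(0:horizon)))
  out[, 1L] <- price
  adj <- config$adjustments

  quote_of <- function(ref, own, pr) {
    x <- pr[[ref]]
    if (isTRUE(adj$active[["statutory"]]) &&
        ref %in% names(adj$statutory_rates))
      x <- x * (1 - adj$statutory_rates[[ref]])
    if (isTRUE(adj$active[["commercial"]]) &&
        ref %in% adj$commercial_countries)
      x <- x * (1 - adj$commercial_rate)
    if (isTRUE(adj$active[["ppp"]]))
      x <- x * adj$ppp_index[[own]] / adj$ppp_index[[ref]]
    x
  }

  bench_of <- function(cc, pr) {
    avail <- cc$pool[!vapply(cc$pool, function(p) is.na(pr[[p]]),
                             logical(1))]
    if (length(avail) > cc$active_count)
      avail <- avail[seq_len(cc$active_count)]
    if (length(avail) < cc$min_required || length(avail) == 0L)
      return(NA_real_)
    q <- sort(vapply(avail, quote_of, numeric(1), own = cc$code, pr = pr))
    r <- cc$rule
    val <- if (r$variant == "average") sum(q) / length(q)
      else if (r$variant == "minimum") q[[1L]]
      else if (r$variant == "avg_lowest") {
        mm <- min(r$m, length(q)); sum(q[seq_len(mm)]) / mm
      } else q[[min(r$k, length(q))]]
    if (r$variant == "kth_lowest_capped")
      for (cap in r$caps)
        if (!is.na(pr[[cap]])) val <- min(val, quote_of(cap, cc$code, pr))
    val
  }

  for (t in seq_len(horizon)) {
    nxt <- price
    fs <- first_set
    for (cc in config$countries) {
      if (cc$code %in% names(config$exogenous)) next
      if (is.na(price[[cc$code]])) {
        v <- bench_of(cc, price)
        if (!is.na(v)) {
          nxt[[cc$code]] <- v
          fs[[cc$code]] <- t
        }
      } else if (!is.na(cc$revision_interval)) {
        age <- t - first_set[[cc$code]]
        if (age > 0L && age %% cc$revision_interval == 0L) {
          v <- bench_of(cc, price)
          if (!is.na(v)) nxt[[cc$code]] <- v
        }
      }
    }
    price <- nxt
    first_set <- fs
    out[, t + 1L] <- price
  }
  out
}
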