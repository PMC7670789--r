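# The 2015 European EPR network: 25 EU Member States plus Iceland, Norway and
# Switzerland simulated; Denmark, Sweden and the UK appear only as exogenous
# reference sources at a constant price.

.EPR_SIMULATED <- c(
  "AT", "BE", "BG", "HR", "CY", "CZ", "DE", "EE", "ES", "FI", "FR", "GR",
  "HU", "IE", "IS", "IT", "LT", "LU", "LV", "MT", "NL", "NO", "PL", "PT",
  "RO", "SI", "SK", "CH"
)

.EPR_EXOGENOUS <- c("DK", "SE", "UK")

#' Country universe of the 2015 European EPR network
#'
#' Two-letter codes for the 31 countries of the bundled base case: the 28
#' EPR-applying countries that are simulated (25 EU Member States plus
#' Iceland, Norway and Switzerland) and the three countries that are
#' referenced at a constant exogenous price (Denmark, Sweden, United
#' Kingdom).
#'
#' @param which `"all"` (default), `"simulated"` or `"exogenous"`.
#' @return Character vector of country codes.
#' @examples
#' epr_universe("exogenous")
#' @export
epr_universe <- function(which = c("all", "simulated", "exogenous")) {
  which <- match.arg(which)
  switch(which,
    all = c(.EPR_SIMULATED, .EPR_EXOGENOUS),
    simulated = .EPR_SIMULATED,
    exogenous = .EPR_EXOGENOUS
  )
}
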