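# The bundled 2015 base case: 28 EPR-applying countries with their surveyed
# rulebook scalars, an approximate (reconstructed) basket-membership file,
# and the Germany 100 / Italy 70 kick-off with DK/SE/UK fixed at 100.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "eprsim")
  if (!nzchar(path) || !file.exists(path))
    stop("bundled data file '", file, "' is missing or corrupt; ",
         "reinstall the package or supply a replacement file explicitly",
         call. = FALSE)
  path
}

.read_survey_parameters <- function() {
  utils::read.csv(.extdata("epr_parameters_2015.csv"),
                  stringsAsFactors = FALSE)
}

.read_membership <- function(path) {
  mem <- tryCatch(.read_yaml_safe(path), error = function(e)
    stop("cannot parse basket membership file ", path, ": ",
         conditionMessage(e), "; supply a valid YAML mapping code -> [codes]",
         call. = FALSE))
  lapply(mem, function(x) as.character(unlist(x)))
}

#' The bundled 2015 base-case configuration
#'
#' Returns the 28-country configuration in which every country applies its
#' real-life 2015 EPR methodology unchanged: per-country basket size,
#' minimum-availability requirement, benchmark formula and revision
#' interval as surveyed in 2015 (for example Luxembourg references a single
#' country, Hungary and Poland the whole 28 EU + 3 EFTA group, the Czech
#' Republic averages the 3 lowest prices with 36-month revisions, and
#' Latvia takes the third-lowest price capped by Lithuania and Estonia).
#' Germany launches at 100 and Italy at 70; Denmark, Sweden and the UK are
#' held constant at 100. No adjustments are active.
#'
#' Basket *membership* is not part of the published survey scalars; it is
#' populated from a bundled, clearly documented approximate file
#' (`basket_membership_2015_reconstructed.yaml`) that callers can override.
#'
#' @param membership Optional path to a replacement basket-membership YAML
#'   file (mapping country code to an ordered list of codes); sizes must
#'   match the published basket sizes.
#' @param horizon Simulation horizon in months (default 120).
#' @return A validated [simulation_config()].
#' @examples
#' base <- builtin_base_case()
#' base$countries$AT
#' @export
builtin_base_case <- function(membership = NULL, horizon = 120L) {
  tab <- .read_survey_parameters()
  mem_path <- if (is.null(membership)) {
    .extdata("basket_membership_2015_reconstructed.yaml")
  } else membership
  if (!file.exists(mem_path))
    stop("basket membership file not found: ", mem_path,
         "; supply one via builtin_base_case(membership = ...)",
         call. = FALSE)
  mem <- .read_membership(mem_path)

  countries <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    pool <- mem[[row$code]]
    if (is.null(pool))
      stop("membership file has no basket for ", row$code, call. = FALSE)
    if (length(pool) != row$pool_size)
      stop("membership file basket for ", row$code, " has ", length(pool),
           " members; expected ", row$pool_size, call. = FALSE)
    rule <- benchmark_rule(
      row$rule,
      m = if (!is.na(row$m)) row$m,
      k = if (!is.na(row$k)) row$k,
      caps = if (!is.na(row$caps) && nzchar(row$caps))
        strsplit(row$caps, ";", fixed = TRUE)[[1]]
    )
    country_epr_config(
      code = row$code,
      pool = pool,
      rule = rule,
      min_required = row$min_required,
      active_count = row$active_count,
      revision_interval = if (is.na(row$revision_months)) NA_integer_
                          else row$revision_months
    )
  })

  adjraw <- .read_yaml_safe(.extdata("adjustment_defaults.yaml"))
  adjustments <- adjustment_policy(
    statutory_rates = .named_numeric(adjraw$statutory$rates),
    commercial_rate = adjraw$commercial$rate,
    commercial_countries = as.character(unlist(adjraw$commercial$countries)),
    ppp_index = .named_numeric(adjraw$ppp$index)
  )

  config <- simulation_config(
    countries = countries,
    kickoff = c(DE = 100, IT = 70),
    exogenous = c(DK = 100, SE = 100, UK = 100),
    horizon = horizon,
    adjustments = adjustments,
    universe = epr_universe()
  )
  violations <- validate_config(config)
  if (length(violations))
    stop("bundled base case failed validation (corrupt data files?):\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  config
}
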