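# Small builders shared across tests.

# Two kick-off countries (DE 100, IT 70) plus caller-supplied rulebooks.
two_kickoff_config <- function(..., horizon = 12L, adjustments = NULL) {
  args <- list(countries = list(...),
               kickoff = c(DE = 100, IT = 70),
               horizon = horizon)
  if (!is.null(adjustments)) args$adjustments <- adjustments
  do.call(simulation_config, args)
}

# Hand-built trajectory object (for reporting tests): `cols` is a list of
# named price vectors, one per month column.
make_traj <- function(cols, simulated, exogenous = character(0)) {
  codes <- names(cols[[1]])
  m <- do.call(cbind, lapply(cols, function(x) x[codes]))
  dimnames(m) <- list(codes, as.character(seq_along(cols) - 1L))
  structure(m, class = c("epr_trajectory", "matrix", "array"),
            simulated = simulated, exogenous = exogenous)
}

# Strip class/attributes so matrices compare cleanly.
traj_matrix <- function(traj, rows = rownames(traj)) {
  m <- unclass(traj)
  attr(m, "simulated") <- NULL
  attr(m, "exogenous") <- NULL
  m[rows, , drop = FALSE]
}
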