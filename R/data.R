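#' Chlorthalidone forced-degradation case study
#'
#' Accessors for the packaged chlorthalidone data: the acid and alkali
#' 2^3 factorial stress experiments (factor levels and observed %
#' degradation per run) and the 3-day x 3-replicate accuracy/precision table
#' at the 80/100/120% fortification levels.  The files live under
#' `inst/extdata/` as plain CSV and are read with the package's own readers.
#'
#' In the acid system the factors are HCl strength (0.01-0.1 mol/L),
#' reflux temperature (55-80 degC) and heating time (30-60 min); the alkali
#' system uses NaOH strength (0.01-0.1 mol/L), 55-80 degC and 15-30 min.
#'
#' @param system `"acid"` or `"alkali"`.
#' @return `chlorthalidone_factors()`: a factor tibble for [fd_design()];
#'   `chlorthalidone_runs()`: a run tibble with coded levels and
#'   `response_pct`; `chlorthalidone_precision()`: a tibble with `level`,
#'   `nominal_mg`, `day`, `replicate`, `found_mg`.
#' @examples
#' des <- fd_design(chlorthalidone_factors("acid"))
#' head(chlorthalidone_runs("acid"))
#' @export
chlorthalidone_factors <- function(system = c("acid", "alkali")) {
  system <- match.arg(system)
  read_factor_table(degopt_extdata(paste0("factors_", system, ".csv")))
}

#' @rdname chlorthalidone_factors
#' @export
chlorthalidone_runs <- function(system = c("acid", "alkali")) {
  system <- match.arg(system)
  read_run_table(degopt_extdata(paste0("runs_", system, ".csv")))
}

#' @rdname chlorthalidone_factors
#' @export
chlorthalidone_precision <- function() {
  read_precision_table(degopt_extdata("precision.csv"))
}

degopt_extdata <- function(file) {
  path <- system.file("extdata", file, package = "degopt")
  if (!nzchar(path)) {
    abort(sprintf("Packaged data file '%s' not found.", file),
          class = "degopt_io_error")
  }
  path
}
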