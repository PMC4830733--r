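#' Simulate factorial responses from a known coded-unit polynomial
#'
#' Generates `Y_i = polynomial(coded run i) + eps_i` with i.i.d. Gaussian
#' noise, for testing the screening/fitting pipeline against known ground
#' truth.  With `noise_sd = 0` the responses are exactly polynomial, so
#' refitting recovers the coefficients to machine precision.  Optionally the
#' responses are back-converted to stressed peak areas against a fixed
#' unstressed reference, producing input for [assemble_responses()].
#'
#' All generators in this family consume an explicit `seed` through an
#' isolated RNG stream ([withr::with_seed()]), so they are reproducible and
#' never disturb the caller's RNG state.
#'
#' @param design An [fd_design()] object.
#' @param intercept True intercept (% degradation).
#' @param coefficients Named numeric vector of true coefficients; names must
#'   be among the design's term labels; omitted terms are 0.
#' @param noise_sd Standard deviation of the Gaussian response noise (%),
#'   >= 0.
#' @param seed Integer seed.
#' @param area_unstressed If non-`NULL`, also return peak areas computed so
#'   that `percent_degradation()` reproduces the responses.
#' @return A tibble with columns `run`, `response` and (optionally)
#'   `area_unstressed`, `area_stressed`; the true parameters are attached as
#'   attribute `truth`.
#' @examples
#' des <- fd_design(tibble::tibble(name = c("A", "B", "C"),
#'                                 low = c(0, 0, 0), high = c(1, 1, 1)))
#' sim_factorial_responses(des, intercept = 18.32,
#'                         coefficients = c(X2 = 10.26, X3 = 4.56),
#'                         noise_sd = 0.5, seed = 1)
#' @export
sim_factorial_responses <- function(design, intercept, coefficients,
                                    noise_sd = 0, seed,
                                    area_unstressed = NULL) {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "degopt_domain_error")
  }
  beta <- setNames(rep(0, length(design$term_labels)), design$term_labels)
  if (length(coefficients)) {
    unknown <- setdiff(names(coefficients), design$term_labels)
    if (length(unknown)) {
      abort(paste0("Unknown term(s) in `coefficients`: ",
                   paste(unknown, collapse = ", ")),
            class = "degopt_shape_error")
    }
    beta[names(coefficients)] <- coefficients
  }
  n <- design_runs(design)
  mu <- intercept + as.numeric(design$effect_matrix %*% beta)
  eps <- withr::with_seed(seed, rnorm(n, 0, noise_sd))
  y <- mu + eps
  out <- tibble(run = seq_len(n), response = y)
  if (!is.null(area_unstressed)) {
    out$area_unstressed <- area_unstressed
    out$area_stressed <- area_unstressed * (1 - y / 100)
  }
  structure(out, truth = list(intercept = intercept, coefficients = beta,
                              noise_sd = noise_sd, seed = seed))
}

#' Simulate calibration data from a known line
#'
#' `peak_area = slope * concentration + intercept + eps`, with `replicates`
#' independent readings per concentration.
#'
#' @param concentrations Concentration levels (e.g. `seq(2, 12, 2)` ug/mL).
#' @param slope,intercept True line parameters.
#' @param replicates Readings per concentration (>= 1).
#' @param noise_sd SD of the additive area noise, >= 0.
#' @param seed Integer seed.
#' @return A tibble with columns `concentration`, `replicate`, `peak_area`;
#'   truth attached as attribute `truth`.
#' @export
sim_calibration_data <- function(concentrations, slope, intercept,
                                 replicates = 3L, noise_sd = 0, seed) {
  if (replicates < 1L) {
    abort("`replicates` must be >= 1.", class = "degopt_domain_error")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "degopt_domain_error")
  }
  grid <- tidyr::expand_grid(concentration = concentrations,
                             replicate = seq_len(replicates))
  eps <- withr::with_seed(seed, rnorm(nrow(grid), 0, noise_sd))
  grid$peak_area <- slope * grid$concentration + intercept + eps
  structure(grid, truth = list(slope = slope, intercept = intercept,
                               noise_sd = noise_sd, seed = seed))
}

#' Simulate a day-nested precision table
#'
#' `value[d, r] = nominal + day_effect[d] + eps[d, r]` with
#' `day_effect ~ N(0, between_day_sd^2)` and `eps ~ N(0, within_day_sd^2)` —
#' the variance-components structure that the day-grouped one-way ANOVA of
#' [precision_anova()] assesses.  With `between_day_sd = 0` the ANOVA F has
#' its null distribution (expected value near 1).
#'
#' @param nominal Nominal amount (mg).
#' @param between_day_sd,within_day_sd Variance-component SDs (mg), >= 0.
#' @param days,replicates Table dimensions (default 3 x 3).
#' @param seed Integer seed.
#' @return A tibble with columns `day`, `replicate`, `value`; truth attached
#'   as attribute `truth`.
#' @export
sim_precision_table <- function(nominal, between_day_sd, within_day_sd,
                                days = 3L, replicates = 3L, seed) {
  if (between_day_sd < 0 || within_day_sd < 0) {
    abort("Variance-component SDs must be >= 0.", class = "degopt_domain_error")
  }
  if (days < 2L || replicates < 2L) {
    abort("Need >= 2 days and >= 2 replicates.", class = "degopt_domain_error")
  }
  vals <- withr::with_seed(seed, {
    day_eff <- rnorm(days, 0, between_day_sd)
    eps <- rnorm(days * replicates, 0, within_day_sd)
    rep(day_eff, each = replicates) + eps
  })
  out <- tidyr::expand_grid(day = seq_len(days), replicate = seq_len(replicates))
  out$value <- nominal + vals
  structure(out, truth = list(nominal = nominal,
                              between_day_sd = between_day_sd,
                              within_day_sd = within_day_sd, seed = seed))
}

#' Monte-Carlo detection frequencies of the pooled-error F screen
#'
#' Simulates factorial responses from known coefficients many times, runs
#' [yates_analysis()] + [f_screen()] on each replicate, and reports how often
#' each term is declared significant.  For truly-nonzero terms this is the
#' screen's power; for null terms its false-positive rate under the
#' pooled-error scheme.
#'
#' @inheritParams sim_factorial_responses
#' @param f_critical Critical F for the screen.
#' @param n_sims Number of simulated experiments.
#' @param pool_size Pooling size passed to [yates_analysis()].
#' @return A tibble with columns `term`, `true_coefficient`,
#'   `detection_rate`.
#' @export
screening_power_report <- function(design, intercept, coefficients, noise_sd,
                                   f_critical, n_sims = 500L, pool_size = 2L,
                                   seed = 1L) {
  labels <- design$term_labels
  seeds <- seed + seq_len(n_sims) - 1L
  hits <- matrix(0L, n_sims, length(labels), dimnames = list(NULL, labels))
  for (i in seq_len(n_sims)) {
    y <- sim_factorial_responses(design, intercept, coefficients,
                                 noise_sd = noise_sd, seed = seeds[i])
    yt <- yates_analysis(y, pool_size = pool_size)
    hits[i, f_screen(yt, f_critical = f_critical)] <- 1L
  }
  beta <- setNames(rep(0, length(labels)), labels)
  beta[names(coefficients)] <- coefficients
  tibble(term = labels, true_coefficient = unname(beta),
         detection_rate = unname(colMeans(hits)))
}
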