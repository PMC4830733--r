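# Shared fixtures: the chlorthalidone case-study inputs, built in code.

acid_factors_tbl <- function() {
  tibble::tibble(
    name  = c("acid_strength", "temperature", "time"),
    low   = c(0.01, 55, 30),
    high  = c(0.10, 80, 60),
    units = c("mol/L", "degC", "min")
  )
}

alkali_factors_tbl <- function() {
  tibble::tibble(
    name  = c("alkali_strength", "temperature", "time"),
    low   = c(0.01, 55, 30 / 2),
    high  = c(0.10, 80, 30),
    units = c("mol/L", "degC", "min")
  )
}

# observed % degradation per run, standard order
acid_responses <- c(7.14, 5.03, 22.61, 20.27, 10.00, 10.07, 36.23, 35.24)
alkali_responses <- c(5.43, 7.66, 25.43, 27.69, 11.69, 10.25, 32.51, 36.42)

# the integer-rounded response column of the worked alkali Yates table
# (its run-7 entry is 32, a round-down of 32.51)
alkali_rounded <- c(5, 8, 25, 28, 12, 10, 32, 36)

acid_run_tbl <- function() tibble::tibble(run = 1:8, response_pct = acid_responses)
alkali_run_tbl <- function() tibble::tibble(run = 1:8, response_pct = alkali_responses)

# 3-day x 3-replicate amount-found tables (mg), days as rows
precision_tables <- function() {
  list(
    "80%" = rbind(c(10, 10.05, 10.03),
                  c(10.02, 10.03, 10.03),
                  c(10, 10.09, 10.04)),
    "100%" = rbind(c(12.45, 12.42, 12.33),
                   c(12.42, 12.41, 12.49),
                   c(12.45, 12.42, 12.46)),
    "120%" = rbind(c(14.09, 14.02, 14.06),
                   c(14.01, 14.03, 14.04),
                   c(14.032, 14.07, 14.09))
  )
}

# a k-factor design with simple unit levels, for property tests
unit_design <- function(k) {
  fd_design(tibble::tibble(
    name = paste0("F", seq_len(k)),
    low = rep(0, k), high = rep(1, k)
  ))
}

# independent oracle: effect-column dot products with the responses
contrast_oracle <- function(design, y) {
  c(sum(y), as.numeric(crossprod(design$effect_matrix, y)))
}
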