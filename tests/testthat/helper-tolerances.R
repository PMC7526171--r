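# Tolerance for comparing with a printed value: one unit in the last
# printed digit or 2% relative, whichever is larger.
printed_tol <- function(value, last_digit) {
  pmax(last_digit, 0.02 * abs(value))
}

expect_printed <- function(actual, printed, last_digit) {
  expect_lt(abs(actual - printed), printed_tol(printed, last_digit))
}

rel_diff <- function(a, b) max(abs(a - b) / (abs(b) + 1e-12))

rich_signal <- function() nutrient_signal(10000, 300, 1500)

mean_dgc <- function(p = default_params()) p$DgcB + pled_profile()$offset
mean_pde <- function(p = default_params()) p$basalPDE + pdea_profile()$offset
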