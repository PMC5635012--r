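# shared fixtures: dimensionless points and randomized parameter draws

dp_point <- function(d_ratio = 20, N = 15, tau_ratio = 20, conc = 2,
                     phi = 0.3, C = 1) {
  dimensionless_params(d_ratio = d_ratio, N = N, tau_ratio = tau_ratio,
                       conc = conc, phi = phi, C = C)
}

# a draw of valid dimensionless parameters, away from degenerate boundaries
random_dp <- function(tau_range = c(0.1, 50), N_max = 15) {
  dimensionless_params(
    d_ratio = stats::runif(1, 2, 50),
    N = sample.int(N_max, 1),
    tau_ratio = exp(stats::runif(1, log(tau_range[1]), log(tau_range[2]))),
    conc = stats::runif(1, 0.2, 10),
    phi = stats::runif(1, 0.05, 0.95),
    C = stats::runif(1, 0.5, 2))
}

# focal-species parameters for the multi-species (matrix saturation) setting:
# per-species number density 4 per um^3 (about 1 ug/mL of a 150-kDa IgG),
# matrix sites 1e5 per um^3, R0 set so the dimensionless concentration is kept
multispecies_params <- function(tau_ratio, phi, N = 20, conc = 10) {
  p <- from_dimensionless(dp_point(d_ratio = 20, N = N, tau_ratio = tau_ratio,
                                   conc = conc, phi = phi))
  p$R0 <- p$conc_A * p$R0 / 4
  p$conc_A <- 4
  p$conc_M <- 1e5
  p
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", actual, expected, tol))
}
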