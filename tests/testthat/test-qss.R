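test_that("rho(s|n) matches the closed form and normalizes", {
  expect_identical(rho_s_given_n(0, 0.5), 1)
  # a_on = 0 limit: anchors never matrix-bound
  expect_equal(rho_s_given_n(5, 1), c(1, rep(0, 5)))
  # three-state birth-death oracle at n = 2 (solved independently in the
  # chain module tests): alpha = 0.3, D_A/D_P = 20, C = 1
  expect_equal(rho_s_given_n(2, 0.3), c(0.6642066, 0.1549815, 0.1808118),
               tolerance = 1e-6)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(0:30, 1)
    r <- rho_s_given_n(n, stats::runif(1), D_A = stats::runif(1, 1, 50),
                       D_P = stats::runif(1, 0.1, 5), C = stats::runif(1, 0.2, 3))
    expect_equal(sum(r), 1, tolerance = 1e-12)
    expect_true(all(r >= 0))
  }
  expect_error(rho_s_given_n(2, 1.4), "alpha")
})

test_that("alpha equals phi when C = 1", {
  set.seed(6)
  for (i in 1:10) {
    a_on <- stats::runif(1, 0, 5); a_off <- stats::runif(1, 0.01, 5)
    expect_equal(alpha_kinetic(a_on, a_off, C = 1), free_fraction(a_on, a_off))
  }
})

test_that("rho(n) is the birth-death law of the averaged gain rate", {
  # two-level hand value: N = 1, kappa(0) = k_on + k_on' = 2/3
  p <- from_dimensionless(dp_point(N = 1, tau_ratio = 20, conc = 2, phi = 0.3))
  r <- rho_n(p)
  expect_equal(r$kappa[1], 2 / 3, tolerance = 1e-10)
  expect_equal(r$rho_n, c(0.6, 0.4), tolerance = 1e-10)

  # no binding channels at all: all mass at n = 0
  p0 <- trapping_params(conc_A = 0, a_on = 1, a_off = 1, N = 5)
  expect_equal(rho_n(p0)$rho_n, c(1, rep(0, 5)))

  # defining detailed-balance recursion at N = 15
  p15 <- from_dimensionless(dp_point(N = 15, conc = 5))
  r15 <- rho_n(p15)
  N <- 15
  for (n in 0:(N - 1)) {
    expect_equal(r15$rho_n[n + 2] / r15$rho_n[n + 1],
                 (N - n) * r15$kappa[n + 1] / ((n + 1) * p15$k_off),
                 tolerance = 1e-9)
  }
  expect_equal(sum(r15$rho_n), 1, tolerance = 1e-12)
  expect_error(rho_n(trapping_params(conc_A = 1, a_on = 1, a_off = 1, k_off = 0)),
               "k_off")
})

test_that("QSS effective diffusivity hits limits and hand values", {
  # phi = 1: anchors never bind matrix, D_eff = D_P exactly
  expect_equal(d_eff_qss(dp_point(phi = 1)), 1)
  # zero concentration: no anchors, D_eff = D_P
  expect_equal(d_eff_qss(dp_point(conc = 0)), 1)
  # N = 1 hand evaluation: rho(0) + rho(1) rho(0|1)
  d1 <- d_eff_qss(dp_point(N = 1, conc = 2, phi = 0.3))
  expect_equal(d1, 0.6 + 0.4 * (6 / 6.7), tolerance = 1e-9)
  r <- qss(from_dimensionless(dp_point(N = 10, conc = 5)))
  expect_true(all(abs(rowSums(r$rho_s_given_n) - 1) < 1e-12))
  expect_true(r$D_eff_ratio >= 0 && r$D_eff_ratio <= 1)
})

test_that("QSS matches the exact chain when matrix kinetics dominate", {
  set.seed(42)
  worst <- 0
  for (i in 1:20) {
    dp <- random_dp(tau_range = c(1e3, 1e4))
    p <- from_dimensionless(dp)
    exact <- stationary(build_chain(p))$D_eff_ratio
    approx <- d_eff_qss(p)
    rel <- abs(approx - exact) / exact
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.01)
})

test_that("trapping strengthens with more sites, anchors, and anchor mobility", {
  for (conc in c(2, 10)) {
    vals <- vapply(c(1, 2, 5, 10, 20), function(N)
      d_eff_qss(dp_point(N = N, conc = conc)), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  vals_c <- vapply(c(0, 0.5, 1, 2, 5, 10), function(conc)
    d_eff_qss(dp_point(conc = conc)), numeric(1))
  expect_true(all(diff(vals_c) < 0))
  # faster anchors trap better at fixed physical anchor concentration [A] R0
  # (the dimensionless concentration axis would rescale [A] as D_A varies)
  vals_d <- vapply(c(2, 5, 10, 20, 50), function(d)
    d_eff_qss(trapping_params(D_P = 1, D_A = d, conc_A = 0.2, R0 = 1,
                              a_on = 14, a_off = 6, k_off = 1, N = 15)),
    numeric(1))
  expect_true(all(diff(vals_d) < 0))
})

test_that("optimal free fraction: boundary for N = 1, interior for N = 15", {
  pm1 <- phi_minimizer(N = 1, tau_ratio = 20, conc = 10)
  expect_equal(pm1$phi_opt, 0)
  expect_false(pm1$interior)
  # profile decreases monotonically toward phi = 0
  expect_true(all(diff(pm1$profile$D_eff_ratio) > 0))

  pm15 <- phi_minimizer(N = 15, tau_ratio = 20, conc = 10)
  expect_true(pm15$interior)
  expect_gt(pm15$phi_opt, 0.05)
  expect_lt(pm15$phi_opt, 0.6)

  pm0 <- phi_minimizer(N = 15, tau_ratio = 20, conc = 0)
  expect_true(pm0$degenerate)
  expect_equal(pm0$D_eff_min, 1)
})

test_that("site competition follows the exact occupancy form and its limits", {
  # [A_T]/[M] = 10 with a_on = a_off: exact 1/11, approximation 1/10
  xi <- saturation_xi(1, 1, conc_A_total = 10, conc_M = 1)
  expect_equal(xi$xi, 1 / 11, tolerance = 1e-12)
  expect_equal(xi$xi_approx, 1 / 10, tolerance = 1e-12)

  p <- multispecies_params(tau_ratio = 20, phi = 0.3)
  # vast excess of anchors: no sites left, tau_AM -> 1/a_off
  sr <- saturated_regime(p, conc_A_total = 1e12)
  expect_lt(sr$xi, 1e-6)
  expect_equal(sr$tau_AM_saturated, 1 / p$a_off, tolerance = 1e-4)
  # substitution arithmetic at [M]/[A_T] = 0.2
  sr2 <- saturated_regime(p, conc_A_total = 5 * p$conc_M)
  expect_equal(sr2$phi_eff, 0.8)
  expect_equal(sr2$alpha_eff, 0.8)
  expect_warning(saturated_regime(p, conc_A_total = p$conc_M / 2), "assume")
})

test_that("competition-adjusted rates recover both concentration limits", {
  p <- multispecies_params(tau_ratio = 20, phi = 0.3)
  # dilute limit: unmodified rates
  sp0 <- saturated_params(p, conc_A_total = 0)
  expect_equal(sp0$a_on, p$a_on, tolerance = 1e-12)
  expect_equal(sp0$phi_eff, 0.3, tolerance = 1e-12)
  # crowded limit: phi_eff -> 1 - [M]/[A_T]
  r <- 50
  sp <- saturated_params(p, conc_A_total = r * p$conc_M)
  expect_equal(sp$phi_eff, 1 - 1 / r, tolerance = 0.02)
})

test_that("species competition only ever hurts the focal species", {
  p <- multispecies_params(tau_ratio = 20, phi = 0.3)
  sc <- species_capacity(p, m = 10^(0:4), engine = "chain")
  expect_true(all(diff(sc$D_eff_ratio) >= -1e-12))
  # m = 1 in the dilute regime matches the plain model
  expect_equal(sc$D_eff_ratio[1], stationary(build_chain(p))$D_eff_ratio,
               tolerance = 1e-4)
  # capacity summaries
  expect_gt(species_capacity_limit(sc, 2), 1)
  expect_gte(species_capacity_limit(sc, 0.1, type = "absolute"),
             species_capacity_limit(sc, 0.05, type = "absolute"))
})

test_that("rapid anchor exchange preserves absolute trapping capacity far better", {
  m <- unique(round(10^seq(0, 5.2, by = 0.2)))
  caps <- vapply(c(0.05, 20), function(tr) {
    pm <- phi_minimizer(d_ratio = 20, N = 20, tau_ratio = tr, conc = 10,
                        resolution = 21, engine = "chain")
    sc <- species_capacity(multispecies_params(tr, pm$phi_opt), m, engine = "chain")
    species_capacity_limit(sc, threshold = 0.05, type = "absolute")
  }, numeric(1))
  # permanent-ish bonds lose effective trapping with far fewer coexisting
  # species than rapidly exchanging bonds
  expect_gt(caps[2] / max(caps[1], 1), 10)
})
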