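test_that("Gillespie estimator is exact for a particle with no sites", {
  p <- trapping_params(N = 0, conc_A = 1, a_on = 1, a_off = 1)
  expect_warning(run <- gillespie(p, max_transitions = 100, seed = 1),
                 "always free")
  expect_identical(run$D_eff_hat, p$D_P)
})

test_that("Gillespie reproduces the two-state permanent-bond chain", {
  p <- from_dimensionless(dp_point(N = 15, tau_ratio = 0.01, conc = 2, phi = 0))
  run <- gillespie(p, max_transitions = 1e6, seed = 101)
  exact <- 21 / 51
  expect_lt(abs(run$D_eff_ratio - exact), 3 * run$se_ratio)
  expect_gt(run$se_ratio, 0)
})

test_that("Gillespie agrees with the exact stationary free fraction across random parameters", {
  set.seed(77)
  draws <- replicate(20, random_dp(tau_range = c(0.5, 30), N_max = 10),
                     simplify = FALSE)
  fails <- 0
  for (dp in draws) {
    p <- from_dimensionless(dp)
    exact <- stationary(build_chain(p))$D_eff_ratio
    run <- gillespie(p, max_transitions = 3e5,
                     seed = sample.int(1e6, 1))
    if (abs(run$D_eff_ratio - exact) > 3 * run$se_ratio) fails <- fails + 1
  }
  # 3-sigma bands admit rare excursions; batch means are approximate
  expect_lte(fails, 2)
})

test_that("identical seed and parameters give bit-identical runs", {
  p <- from_dimensionless(dp_point(N = 5, conc = 3))
  r1 <- gillespie(p, max_transitions = 5e3, seed = 9, keep_log = TRUE)
  r2 <- gillespie(p, max_transitions = 5e3, seed = 9, keep_log = TRUE)
  expect_identical(r1$t_total, r2$t_total)
  expect_identical(r1$log, r2$log)
  s1 <- simulate_spatial(trapping_params(N = 0, D_P = 1, conc_A = 0,
                                         a_on = 0, a_off = 1, L = 5, T = 20),
                         n_particles = 50, seed = 4)
  s2 <- simulate_spatial(trapping_params(N = 0, D_P = 1, conc_A = 0,
                                         a_on = 0, a_off = 1, L = 5, T = 20),
                         n_particles = 50, seed = 4)
  expect_identical(s1$first_passage_time, s2$first_passage_time)
})

test_that("time-limited runs respect the stopping rule", {
  p <- from_dimensionless(dp_point(N = 5, conc = 3))
  run <- gillespie(p, max_transitions = NULL, max_time = 50, seed = 2)
  expect_equal(run$t_total, 50, tolerance = 1e-9)
})

test_that("anchor-free spatial simulation crosses an easy slab", {
  # tau_L = 625 s << T = 7200 s: nearly every particle crosses
  p <- trapping_params(N = 0, D_P = 2, conc_A = 0, a_on = 0, a_off = 1,
                       L = 50, T = 7200)
  run <- simulate_spatial(p, n_particles = 200, seed = 3, dt_max = 0.5)
  expect_gt(run$penetrated_fraction, 0.97)
})

test_that("pure-Brownian first-passage times follow the series-solution law", {
  p <- trapping_params(N = 0, D_P = 1, conc_A = 0, a_on = 0, a_off = 1,
                       L = 10, T = 400)
  run <- simulate_spatial(p, n_particles = 2000, seed = 12)
  t_abs <- run$first_passage_time[!is.na(run$first_passage_time)]
  norm <- penetration_probability(1, 10, 400)$probability
  cdf <- function(q) vapply(q, function(t)
    penetration_probability(1, 10, t)$probability / norm, numeric(1))
  ks <- suppressWarnings(stats::ks.test(t_abs, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("anchored spatial runs agree with the homogenized series solution", {
  # tau_AM, tau_AP << tau_L so the switching walk homogenizes
  base <- dp_point(N = 3, tau_ratio = 20, conc = 1, phi = 0.3)
  for (L in c(8, 12)) {
    p <- from_dimensionless(base, L = L, T = 6 * L^2)
    d_eff <- stationary(build_chain(p))$D_eff_ratio * p$D_P
    run <- simulate_spatial(p, n_particles = 250, seed = 40 + L)
    series <- penetration_probability(d_eff, p$L, p$T)$probability
    expect_lt(abs(run$penetrated_fraction - series),
              3 * max(run$se, 0.01))
  }
})

test_that("run summaries serialize to JSON with the seed and parameters", {
  p <- from_dimensionless(dp_point(N = 2, conc = 2))
  run <- gillespie(p, max_transitions = 1e3, seed = 5)
  js <- jsonlite::fromJSON(run_summary_json(run))
  expect_equal(js$seed, 5)
  expect_equal(js$D_eff_ratio, run$D_eff_ratio, tolerance = 1e-12)
  expect_equal(js$params$N, 2)
})
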