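brownian_set <- function(n_tracks, D = 1, n_frames = 300, dt = 0.0667,
                         sigma = 0) {
  df <- do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    data.frame(track_id = i, frame = seq_len(n_frames),
               x_um = cumsum(c(0, stats::rnorm(n_frames - 1, 0, sqrt(2 * D * dt)))),
               y_um = cumsum(c(0, stats::rnorm(n_frames - 1, 0, sqrt(2 * D * dt)))))
  }))
  trajectory_set(df, dt = dt, sigma = max(sigma, 1e-6))
}

test_that("time-averaged MSD matches closed forms", {
  # stationary track
  expect_equal(msd_time_averaged(rep(1, 50), rep(2, 50), 5), 0)
  # ballistic track: MSD(n dt) = v^2 (n dt)^2
  v <- 0.3; dt <- 0.0667
  x <- v * (0:99) * dt
  for (lag in c(1, 4, 10))
    expect_equal(msd_time_averaged(x, rep(0, 100), lag), (v * lag * dt)^2,
                 tolerance = 1e-12)
  expect_error(msd_time_averaged(x, rep(0, 100), 100), "track length")
  expect_error(msd_time_averaged(x, rep(0, 100), 0), "positive")
})

test_that("Brownian ensembles recover MSD = 4 D tau", {
  set.seed(88)
  ts <- brownian_set(200, D = 1)
  ens <- ensemble_geometric_msd(ts, lags = 1:5)
  expect_equal(ens$msd_gmean, 4 * 1 * ens$tau, tolerance = 0.1)
  # per-track MSD at one lag is unbiased within 3 ensemble SE
  m1 <- vapply(split(as.data.frame(ts), ts$track_id),
               function(tr) msd_time_averaged(tr$x_um, tr$y_um, 1), numeric(1))
  se <- stats::sd(m1) / sqrt(length(m1))
  expect_lt(abs(mean(m1) - 4 * 0.0667), 3 * se)
})

test_that("geometric ensemble averaging behaves like a log-mean", {
  df <- rbind(data.frame(track_id = 1, frame = 1:10,
                         x_um = seq(0, 0.9, by = 0.1), y_um = 0),
              data.frame(track_id = 2, frame = 1:10,
                         x_um = 10 * seq(0, 0.9, by = 0.1), y_um = 0))
  ts <- trajectory_set(df, dt = 0.1, sigma = 1e-4)
  ens <- ensemble_geometric_msd(ts, lags = 1)
  # MSDs are 0.01 and 1.0: geometric mean 0.1
  expect_equal(ens$msd_gmean, 0.1, tolerance = 1e-9)

  set.seed(3)
  ts2 <- brownian_set(20, D = 0.5, n_frames = 60)
  g <- ensemble_geometric_msd(ts2, lags = 1:3)$msd_gmean
  a <- vapply(1:3, function(l) mean(vapply(split(as.data.frame(ts2), ts2$track_id),
    function(tr) msd_time_averaged(tr$x_um, tr$y_um, l), numeric(1))), numeric(1))
  expect_true(all(g <= a))  # AM-GM
})

test_that("the mobility classification boundary is exact and inclusive", {
  tau_ref <- 4 * 0.0667
  expect_equal(d_eff_at_lag(0, 1), 0)
  # the MSD value that sits exactly on the cutoff
  msd_boundary <- 4 * tau_ref * 10^-1.5
  expect_equal(msd_boundary, 0.0337, tolerance = 1e-2)
  expect_true(classify_mobile(d_eff_at_lag(msd_boundary, tau_ref)))
  expect_false(classify_mobile(1e-2))
  expect_true(classify_mobile(0.25))
  expect_identical(MOBILE_CUTOFF, 10^-1.5)
})

test_that("anomalous exponent fits recover exact power laws", {
  tau <- (1:10) * 0.0667
  fit_b <- fit_anomalous_exponent(4 * 0.7 * tau, tau)
  expect_equal(fit_b$exponent, 1, tolerance = 1e-12)
  expect_equal(fit_b$D_0, 0.7, tolerance = 1e-12)
  fit_v <- fit_anomalous_exponent(0.09 * tau^2, tau)
  expect_equal(fit_v$exponent, 2, tolerance = 1e-12)
  expect_error(fit_anomalous_exponent(c(1, 2), c(1, 2)), ">= 3")
})

test_that("generated anchor-free tracks are Brownian with the video geometry", {
  p <- trapping_params(D_P = 1, N = 0, conc_A = 0, a_on = 0, a_off = 1)
  ts <- generate_tracks(p, n_tracks = 150, seed = 14)
  expect_identical(nrow(ts), 150L * 300L)  # 20 s at 66.7 ms
  res <- analyze_tracks(ts)
  expect_equal(res$summary$D_eff_gmean, 1, tolerance = 0.1)
  expect_equal(res$summary$mean_exponent, 1, tolerance = 0.05)
  expect_equal(res$summary$mobile_fraction, 1)
})

test_that("strong trapping drives the mobile fraction to zero", {
  dp <- dp_point(N = 15, tau_ratio = 20, conc = 50, phi = 0.2)
  p <- from_dimensionless(dp, k_off_scale = 1, D_P_scale = 1)
  ts <- generate_tracks(p, n_tracks = 80, seed = 15)
  res <- analyze_tracks(ts)
  expect_lt(res$summary$mobile_fraction, 0.05)
  # arrested ensemble is subdiffusive
  expect_lt(res$summary$mean_exponent, 1)
})

test_that("the MSD pipeline closes the loop with the chain prediction", {
  dp <- dp_point(N = 5, tau_ratio = 20, conc = 1, phi = 0.3)
  p <- from_dimensionless(dp)
  ratio <- stationary(build_chain(p))$D_eff_ratio
  ts <- generate_tracks(p, n_tracks = 250, seed = 16)
  res <- analyze_tracks(ts)
  # mean free-time fraction over 20 s tracks approximates D_eff/D_P;
  # the arithmetic mean of per-track D_eff estimates it
  expect_equal(mean(res$per_track$D_eff), ratio * p$D_P, tolerance = 0.2)
})

test_that("short tracks are excluded with a count and CSV round trip works", {
  p <- trapping_params(D_P = 0.5, N = 0, conc_A = 0, a_on = 0, a_off = 1)
  ts <- generate_tracks(p, n_tracks = 10, seed = 20)
  short <- data.frame(track_id = 99, frame = 1:3, x_um = 0, y_um = 0)
  ts2 <- trajectory_set(rbind(as.data.frame(ts), short))
  res <- analyze_tracks(ts2)
  expect_identical(res$summary$n_excluded, 1L)
  expect_identical(res$summary$n_tracks, 10L)

  path <- tempfile(fileext = ".csv")
  write_tracks(ts, path)
  ts3 <- read_tracks(path)
  cols <- c("track_id", "frame", "x_um", "y_um")
  df3 <- as.data.frame(ts3)[cols]
  df0 <- as.data.frame(ts)[cols]
  attributes(df3) <- attributes(df3)[c("names", "class", "row.names")]
  attributes(df0) <- attributes(df0)[c("names", "class", "row.names")]
  expect_equal(df3, df0, tolerance = 1e-6)

  jpath <- tempfile(fileext = ".json")
  export_msd_result(res, json_path = jpath)
  js <- jsonlite::fromJSON(jpath)
  expect_equal(js$mobile_fraction, res$summary$mobile_fraction)
})
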