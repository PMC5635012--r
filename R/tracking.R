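#' Mobile-particle diffusivity cutoff (um^2/s)
#'
#' Particles with an effective diffusivity of at least `10^-1.5` um^2/s at the
#' reference lag 0.2667 s are classified as mobile. Computed once so the
#' boundary comparison is exact.
#' @export
MOBILE_CUTOFF <- 10^-1.5

#' Default imaging parameters of the tracking pipeline
#'
#' 66.7-ms frame interval, 20-s videos (300 frames), 10-nm localization
#' noise; the mobile classification uses the 4-frame lag 0.2667 s, which
#' implies a 5-frame minimum usable trajectory.
#' @name tracking-defaults
#' @keywords internal
NULL

FRAME_DT <- 0.0667      # s
REF_LAG_FRAMES <- 4L    # 0.2667 s at 66.7 ms
MIN_TRACK_FRAMES <- 5L
NOISE_SD <- 0.010       # um

#' Assemble a trajectory set
#'
#' @param df Data frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#'   Frames must be strictly increasing within a track.
#' @param dt Frame interval (s).
#' @param sigma Localization noise sd per coordinate (um), used as the MSD
#'   noise floor `4 sigma^2` in geometric averaging.
#' @param seed,generator Optional provenance metadata.
#' @return The data frame with class `"trajectory_set"` and attributes `dt`,
#'   `sigma`, `seed`, `generator`.
#' @export
trajectory_set <- function(df, dt = FRAME_DT, sigma = NOISE_SD,
                           seed = NULL, generator = NULL) {
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop("'df' must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  increasing <- vapply(split(df$frame, df$track_id),
                       function(f) all(diff(f) > 0), logical(1))
  if (!all(increasing))
    stop("frames must be strictly increasing within each track", call. = FALSE)
  structure(df, dt = dt, sigma = sigma, seed = seed, generator = generator,
            class = c("trajectory_set", "data.frame"))
}

#' Read / write trajectory CSV files
#'
#' The interchange format is a plain CSV with header
#' `track_id,frame,x_um,y_um`.
#'
#' @param path File path.
#' @param dt,sigma Frame interval (s) and localization noise (um) to attach
#'   on read.
#' @return [read_tracks()] returns a [trajectory_set()]; [write_tracks()]
#'   returns its input invisibly.
#' @export
read_tracks <- function(path, dt = FRAME_DT, sigma = NOISE_SD) {
  df <- utils::read.csv(path)
  trajectory_set(df, dt = dt, sigma = sigma)
}

#' @rdname read_tracks
#' @param ts A [trajectory_set()].
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  utils::write.csv(as.data.frame(ts)[c("track_id", "frame", "x_um", "y_um")],
                   path, row.names = FALSE)
  invisible(ts)
}

#' Time-averaged mean squared displacement of one track
#'
#' `MSD(n dt) = 1/(N-n) sum_m [ (x_{m+n}-x_m)^2 + (y_{m+n}-y_m)^2 ]`, the
#' time average over all start frames of a single trajectory.
#'
#' @param x,y Coordinate vectors (um) at consecutive frames.
#' @param lag Lag in frames, `1 <= lag < length(x)`.
#' @return The MSD in um^2.
#' @export
msd_time_averaged <- function(x, y, lag) {
  n_frames <- length(x)
  if (length(y) != n_frames) stop("'x' and 'y' must match", call. = FALSE)
  if (lag < 1 || lag != round(lag)) stop("'lag' must be a positive integer",
                                         call. = FALSE)
  if (lag >= n_frames)
    stop("'lag' must be smaller than the track length", call. = FALSE)
  i <- seq_len(n_frames - lag)
  mean((x[i + lag] - x[i])^2 + (y[i + lag] - y[i])^2)
}

#' Per-track MSD curve
#'
#' @param track Data frame with `x_um`, `y_um` for one track (consecutive
#'   frames).
#' @param lags Integer lags (frames).
#' @return Numeric vector of MSD values (um^2), `NA` where the track is too
#'   short.
#' @export
track_msd <- function(track, lags) {
  vapply(lags, function(l) {
    if (l >= nrow(track)) return(NA_real_)
    msd_time_averaged(track$x_um, track$y_um, l)
  }, numeric(1))
}

#' Ensemble geometric mean MSD
#'
#' Per lag, the geometric mean of the per-track time-averaged MSDs: the mean
#' of `log10 MSD` across tracks, back-transformed. MSD values below the
#' localization-noise floor `4 sigma^2` (including exact zeros) are floored
#' there before taking logs.
#'
#' @param ts A [trajectory_set()].
#' @param lags Integer lags (frames), default 1-10.
#' @param min_frames Tracks spanning fewer frames than this are excluded.
#' @return A data frame `lag`, `tau` (s), `msd_gmean` (um^2), `n_tracks`.
#' @export
ensemble_geometric_msd <- function(ts, lags = 1:10,
                                   min_frames = MIN_TRACK_FRAMES) {
  stopifnot(inherits(ts, "trajectory_set"))
  dt <- attr(ts, "dt")
  floor_val <- 4 * attr(ts, "sigma")^2
  tracks <- split(as.data.frame(ts), ts$track_id)
  tracks <- tracks[vapply(tracks, nrow, integer(1)) >= min_frames]
  if (length(tracks) == 0) stop("no usable tracks", call. = FALSE)
  rows <- lapply(lags, function(l) {
    vals <- vapply(tracks, function(tr) {
      if (l >= nrow(tr)) return(NA_real_)
      msd_time_averaged(tr$x_um, tr$y_um, l)
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    vals <- pmax(vals, floor_val)
    data.frame(lag = l, tau = l * dt,
               msd_gmean = if (length(vals)) 10^mean(log10(vals)) else NA_real_,
               n_tracks = length(vals))
  })
  do.call(rbind, rows)
}

#' Effective diffusivity at a reference lag (2-D convention)
#'
#' `D_eff = MSD(tau) / (4 tau)`.
#'
#' @param msd MSD value(s) (um^2).
#' @param tau Lag time (s), > 0.
#' @return Effective diffusivity in um^2/s.
#' @export
d_eff_at_lag <- function(msd, tau) {
  if (any(tau <= 0)) stop("'tau' must be > 0", call. = FALSE)
  if (any(msd < 0)) stop("'msd' must be >= 0", call. = FALSE)
  msd / (4 * tau)
}

#' Mobile / immobile classification
#'
#' A particle is mobile if its effective diffusivity at the 0.2667-s
#' reference lag is at least `10^-1.5` um^2/s (boundary inclusive).
#'
#' @param d_eff Effective diffusivity (um^2/s).
#' @return Logical vector.
#' @export
classify_mobile <- function(d_eff) {
  d_eff >= MOBILE_CUTOFF
}

#' Fit the anomalous diffusion law MSD = 4 D_0 tau^alpha
#'
#' Ordinary least squares of `log10 MSD` on `log10 tau`; the slope is the
#' diffusive exponent (1 for Brownian motion, < 1 subdiffusive) and the
#' intercept gives `D_0`.
#'
#' @param msd MSD values (um^2), all > 0 after any flooring.
#' @param tau Lag times (s), same length, >= 3 points.
#' @return A list with `D_0` (um^2/s), `exponent`.
#' @export
fit_anomalous_exponent <- function(msd, tau) {
  if (length(msd) != length(tau) || length(msd) < 3)
    stop("need >= 3 (msd, tau) pairs", call. = FALSE)
  if (any(msd <= 0) || any(tau <= 0))
    stop("MSD and tau must be positive for the log-log fit", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, log10(tau)), log10(msd))
  exponent <- unname(fit$coefficients[2])
  list(D_0 = unname(10^fit$coefficients[1]) / 4, exponent = exponent)
}

#' Generate synthetic switching-diffusion trajectories
#'
#' Emulates the particle-tracking experiment: each particle runs the binding
#' chain, diffuses with `D_P` only while free of matrix bonds (`s = 0`), is
#' sampled at the frame interval, and receives i.i.d. Gaussian localization
#' noise per coordinate per frame. Defaults reproduce the imaging parameters:
#' 66.7-ms frames, 20-s videos (300 frames), 10-nm noise.
#'
#' @param p A [trapping_params()] object.
#' @param n_tracks Number of trajectories.
#' @param duration Video length (s).
#' @param dt Frame interval (s).
#' @param sigma Localization noise sd (um).
#' @param seed Integer seed (recorded).
#' @return A [trajectory_set()].
#' @export
#' @examples
#' p <- trapping_params(D_P = 1, N = 0)  # no anchors: pure Brownian tracks
#' ts <- generate_tracks(p, n_tracks = 5, seed = 1)
#' nrow(ts) / 5  # 300 frames per track
generate_tracks <- function(p, n_tracks = 100, duration = 20, dt = FRAME_DT,
                            sigma = NOISE_SD, seed = NULL) {
  stopifnot(inherits(p, "trapping_params"))
  if (n_tracks < 1 || duration <= 0 || dt <= 0 || sigma < 0)
    stop("invalid generator settings", call. = FALSE)
  n_frames <- max(2L, as.integer(round(duration / dt)))
  if (!is.null(seed)) set.seed(seed)
  ks <- smoluchowski_rates(p)
  pos <- .tracks_cpp(p$N, ks$k_on, ks$k_on_prime, p$k_off, p$a_on, p$a_off,
                     p$C, p$D_P / p$D_A, p$D_P, n_tracks, n_frames, dt, sigma)
  df <- data.frame(
    track_id = rep(seq_len(n_tracks), each = n_frames),
    frame = rep(seq_len(n_frames), n_tracks),
    x_um = as.vector(pos[, 2 * seq_len(n_tracks) - 1]),
    y_um = as.vector(pos[, 2 * seq_len(n_tracks)]))
  trajectory_set(df, dt = dt, sigma = sigma, seed = seed,
                 generator = list(params = unclass(p), duration = duration))
}

#' Multiple-particle-tracking analysis
#'
#' Per-track time-averaged MSDs, effective diffusivity at the 0.2667-s
#' reference lag, anomalous-exponent fit, and mobile classification; tracks
#' shorter than `min_frames` frames are dropped and counted. The ensemble
#' summary reports the geometric mean MSD curve, the geometric mean `D_eff`,
#' and the mobile fraction.
#'
#' @param ts A [trajectory_set()].
#' @param ref_lag Reference lag in frames (default 4, i.e. 0.2667 s at
#'   66.7-ms frames).
#' @param fit_lags Lags (frames) for the exponent fit (default 1-10).
#' @param min_frames Minimum usable track length (frames).
#' @return An object of class `"msd_result"`: `per_track` (data frame
#'   `track_id`, `n_frames`, `msd_ref`, `D_eff`, `exponent`, `mobile`),
#'   `ensemble` (geometric MSD curve), `summary` (list with `n_tracks`,
#'   `n_excluded`, `D_eff_gmean`, `mean_exponent`, `mobile_fraction`,
#'   `ref_tau`).
#' @export
analyze_tracks <- function(ts, ref_lag = REF_LAG_FRAMES, fit_lags = 1:10,
                           min_frames = MIN_TRACK_FRAMES) {
  stopifnot(inherits(ts, "trajectory_set"))
  dt <- attr(ts, "dt")
  floor_val <- 4 * attr(ts, "sigma")^2
  if (ref_lag >= min_frames)
    stop("'min_frames' must exceed 'ref_lag' so the reference MSD exists",
         call. = FALSE)
  all_tracks <- split(as.data.frame(ts), ts$track_id)
  usable <- vapply(all_tracks, nrow, integer(1)) >= min_frames
  n_excluded <- sum(!usable)
  tracks <- all_tracks[usable]
  if (length(tracks) == 0) stop("no track spans the minimum length", call. = FALSE)

  per <- lapply(tracks, function(tr) {
    msd_ref <- msd_time_averaged(tr$x_um, tr$y_um, ref_lag)
    d_eff <- d_eff_at_lag(msd_ref, ref_lag * dt)
    lags_ok <- fit_lags[fit_lags < nrow(tr)]
    expo <- if (length(lags_ok) >= 3) {
      msd <- pmax(track_msd(tr, lags_ok), floor_val)
      fit_anomalous_exponent(msd, lags_ok * dt)$exponent
    } else NA_real_
    data.frame(track_id = tr$track_id[1], n_frames = nrow(tr),
               msd_ref = msd_ref, D_eff = d_eff, exponent = expo,
               mobile = classify_mobile(d_eff))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  ens <- ensemble_geometric_msd(ts, lags = fit_lags, min_frames = min_frames)
  structure(list(
    per_track = per,
    ensemble = ens,
    summary = list(n_tracks = nrow(per), n_excluded = n_excluded,
                   D_eff_gmean = 10^mean(log10(pmax(per$D_eff,
                                                    floor_val / (4 * ref_lag * dt)))),
                   mean_exponent = mean(per$exponent, na.rm = TRUE),
                   mobile_fraction = mean(per$mobile),
                   ref_tau = ref_lag * dt)),
    class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("MSD analysis: %d tracks (%d excluded as too short)\n",
              s$n_tracks, s$n_excluded))
  cat(sprintf("  geometric <D_eff> = %.4g um^2/s at tau = %.4g s; mean exponent = %.3g\n",
              s$D_eff_gmean, s$ref_tau, s$mean_exponent))
  cat(sprintf("  mobile fraction = %.1f%% (cutoff %.4g um^2/s)\n",
              100 * s$mobile_fraction, MOBILE_CUTOFF))
  invisible(x)
}

#' Export an MSD analysis
#'
#' Writes the per-track table as CSV and/or the ensemble summary as JSON.
#'
#' @param res An `"msd_result"`.
#' @param csv_path,json_path Optional output paths.
#' @return `res`, invisibly.
#' @export
export_msd_result <- function(res, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(res, "msd_result"))
  if (!is.null(csv_path))
    utils::write.csv(res$per_track, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    out <- c(res$summary,
             list(ensemble_msd = res$ensemble, mobile_cutoff = MOBILE_CUTOFF))
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"), json_path)
  }
  invisible(res)
}
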