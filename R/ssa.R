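#' Gillespie simulation of the binding chain
#'
#' Exact stochastic simulation of the (n, s) chain started from the bare
#' particle state (0, 0). The long-run fraction of time spent free of matrix
#' bonds estimates the effective diffusivity:
#' `D_eff_hat = D_P * t_free / t_total`. A batch-means standard error is
#' computed by splitting the run into `n_batches` equal transition blocks.
#'
#' @param p A [trapping_params()] object.
#' @param max_transitions Stop after this many transitions (default 1e5).
#' @param max_time Stop once this much simulated time has elapsed (optional;
#'   at least one stopping rule must be positive).
#' @param seed Integer seed (recorded in the result). `NULL` leaves the RNG
#'   state untouched.
#' @param n_batches Number of batches for the standard error (>= 2,
#'   default 20).
#' @param keep_log Keep the full transition log (`time`, `n`, `s`)?
#' @return An object of class `"ssa_run"`: `m` transitions, `t_total`,
#'   `t_free`, `D_eff_hat`, `D_eff_ratio` (`= t_free/t_total`), `se`
#'   (batch-means SE of `D_eff_hat`), `batch_fractions`, `seed`, and `log`
#'   if requested. If no transition is possible from (0, 0) the particle is
#'   permanently free and `D_eff_hat = D_P` is returned with a warning.
#' @export
#' @examples
#' p <- from_dimensionless(dimensionless_params(N = 2, conc = 2))
#' run <- gillespie(p, max_transitions = 1e4, seed = 1)
#' run$D_eff_ratio
gillespie <- function(p, max_transitions = 1e5, max_time = NULL, seed = NULL,
                      n_batches = 20, keep_log = FALSE) {
  stopifnot(inherits(p, "trapping_params"))
  mt <- if (is.null(max_transitions)) 0 else max_transitions
  mtime <- if (is.null(max_time)) 0 else max_time
  if (mt <= 0 && mtime <= 0)
    stop("provide a positive 'max_transitions' and/or 'max_time'", call. = FALSE)
  if (n_batches < 2) stop("'n_batches' must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ks <- smoluchowski_rates(p)
  res <- .gillespie_cpp(p$N, ks$k_on, ks$k_on_prime, p$k_off, p$a_on, p$a_off,
                        p$C, p$D_P / p$D_A, mt, mtime, n_batches, keep_log)
  if (res$m == 0) {
    warning("no transitions possible from state (0, 0); particle is always free",
            call. = FALSE)
    out <- list(m = 0, t_total = 0, t_free = 0, D_eff_hat = p$D_P,
                D_eff_ratio = 1, se = 0, batch_fractions = numeric(0),
                seed = seed, params = p)
    return(structure(out, class = "ssa_run"))
  }
  ratio <- res$t_free / res$t_total
  bf <- res$batch_fractions
  se <- if (length(bf) >= 2) stats::sd(bf) / sqrt(length(bf)) else NA_real_
  structure(list(m = res$m, t_total = res$t_total, t_free = res$t_free,
                 D_eff_hat = p$D_P * ratio, D_eff_ratio = ratio,
                 se = p$D_P * se, se_ratio = se, batch_fractions = bf,
                 final_state = c(n = res$final_n, s = res$final_s),
                 seed = seed, params = p,
                 log = if (keep_log) res$log else NULL),
            class = "ssa_run")
}

#' @export
print.ssa_run <- function(x, ...) {
  cat(sprintf("Gillespie run: %g transitions, %.4g s simulated\n", x$m, x$t_total))
  cat(sprintf("  D_eff_hat = %.6g (SE %.2g), D_eff/D_P = %.6g\n",
              x$D_eff_hat, x$se, x$D_eff_ratio))
  invisible(x)
}

#' Summarize a stochastic run as JSON
#'
#' @param x An `"ssa_run"` or `"spatial_run"` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON (invisibly if written to file).
#' @export
run_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, c("ssa_run", "spatial_run")))
  keep <- setdiff(names(x), c("log", "first_passage_time", "params"))
  out <- x[keep]
  out$params <- unclass(x$params)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Spatial switching-diffusion simulation of gel-layer penetration
#'
#' Direct Monte-Carlo of particles entering a gel slab `[0, L]` at the outer
#' face `x = 0` (reflecting), absorbed at the inner face `x = L`. Each
#' particle runs the binding chain and diffuses with diffusivity `D_P` only
#' while free of matrix bonds (`s = 0`); crosslinked particles are immobile.
#' Brownian motion within free dwells is sub-stepped at `dt_max` to bound the
#' bias from crossings inside a step.
#'
#' @param p A [trapping_params()] object (uses its `L`, `T`, `D_P`).
#' @param n_particles Number of independent particles.
#' @param seed Integer seed (recorded).
#' @param dt_max Maximum Brownian sub-step (s); default `tau_L / 1e4`.
#' @return An object of class `"spatial_run"`: `penetrated_fraction`, its
#'   binomial `se`, `n_particles`, `first_passage_time` (NA where censored),
#'   `seed`.
#' @seealso [penetration_probability()] for the homogenized series solution.
#' @export
simulate_spatial <- function(p, n_particles = 1000, seed = NULL,
                             dt_max = NULL) {
  stopifnot(inherits(p, "trapping_params"))
  if (p$L <= 0 || p$T <= 0) stop("'L' and 'T' must be > 0", call. = FALSE)
  if (is.null(dt_max)) dt_max <- (p$L^2 / (2 * p$D_P)) / 1e4
  if (!is.null(seed)) set.seed(seed)
  ks <- smoluchowski_rates(p)
  res <- .spatial_cpp(p$N, ks$k_on, ks$k_on_prime, p$k_off, p$a_on, p$a_off,
                      p$C, p$D_P / p$D_A, p$D_P, p$L, p$T, n_particles, dt_max)
  frac <- mean(res$absorbed)
  structure(list(penetrated_fraction = frac,
                 se = sqrt(frac * (1 - frac) / n_particles),
                 n_particles = n_particles,
                 first_passage_time = res$first_passage_time,
                 seed = seed, dt_max = dt_max, params = p),
            class = "spatial_run")
}

#' @export
print.spatial_run <- function(x, ...) {
  cat(sprintf("Spatial run: %d particles, L = %g um, T = %g s\n",
              x$n_particles, x$params$L, x$params$T))
  cat(sprintf("  penetrated fraction = %.4g (SE %.2g)\n",
              x$penetrated_fraction, x$se))
  invisible(x)
}
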