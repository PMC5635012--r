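#' Sensitivity of log effective diffusivity to a dimensionless knob
#'
#' Finite-difference estimate of `d log(D_eff/D_P) / d p` for one of the four
#' dimensionless parameters, evaluated with the exact chain stationary solve
#' (the quasi-steady-state formula is independent of `tau_ratio` by
#' construction, so the exact chain is required for that axis and used for
#' all of them for consistency). Continuous parameters use an adaptively
#' refined central difference; the integer parameter `N` uses a centered unit
#' difference on `log(D_eff/D_P)`.
#'
#' Because the normalization of the step is a presentation choice, both
#' conventions are reported: `sensitivity` (per absolute unit of `p`) and
#' `sensitivity_relative` (per relative change, `= p * sensitivity`).
#'
#' For the diffusivity ratio the result depends on what is held fixed:
#' with the dimensionless concentration `[A](D_P + D_A) R0 / k_off` held
#' constant (`conc_held = "dimensionless"`, the convention of the
#' concentration axis), raising `D_A` dilutes the physical anchor
#' concentration and the sensitivity is typically positive; with the physical
#' `[A] R0` held constant (`conc_held = "physical"`), faster anchors
#' accumulate on the particle sooner and the sensitivity is negative.
#'
#' @param dp A [dimensionless_params()] evaluation point.
#' @param p_name One of `"tau_ratio"`, `"conc"`, `"N"`, `"d_ratio"`.
#' @param delta Initial relative step (continuous parameters); default 1e-3.
#' @param rtol Relative agreement between successive halved-step estimates at
#'   which the refinement stops (default 0.01).
#' @param engine `"chain"` (default) or `"qss"`.
#' @param conc_held For `p_name = "d_ratio"`: hold the dimensionless or the
#'   physical anchor concentration fixed while varying the ratio (see above).
#' @return An object of class `"sensitivity_result"`: `p_name`, `point`
#'   (value of `p`), `delta` (final absolute step), `sensitivity`,
#'   `sensitivity_relative`, `converged`.
#' @export
#' @examples
#' dp <- dimensionless_params(d_ratio = 20, N = 20, tau_ratio = 20, conc = 2)
#' sensitivity(dp, "N")
sensitivity <- function(dp, p_name = c("tau_ratio", "conc", "N", "d_ratio"),
                        delta = 1e-3, rtol = 0.01,
                        engine = c("chain", "qss"),
                        conc_held = c("dimensionless", "physical")) {
  stopifnot(inherits(dp, "dimensionless_params"))
  p_name <- match.arg(p_name)
  engine <- match.arg(engine)
  conc_held <- match.arg(conc_held)

  log_deff <- function(dpt) {
    val <- switch(engine,
                  chain = stationary(build_chain(from_dimensionless(dpt)))$D_eff_ratio,
                  qss = d_eff_qss(dpt))
    if (val <= 0) stop("D_eff/D_P vanished; log-sensitivity undefined",
                       call. = FALSE)
    log(val)
  }
  at <- function(value) {
    fields <- unclass(dp)
    if (p_name == "d_ratio" && conc_held == "physical") {
      # keep [A] R0 fixed: the dimensionless concentration scales with D_P+D_A
      fields$conc <- dp$conc * (1 + value) / (1 + dp$d_ratio)
    }
    fields[[p_name]] <- value
    do.call(dimensionless_params, fields)
  }
  p0 <- dp[[p_name]]

  if (p_name == "N") {
    if (p0 < 1) stop("unit difference in N needs N >= 1", call. = FALSE)
    sens <- (log_deff(at(p0 + 1)) - log_deff(at(p0 - 1))) / 2
    return(structure(list(p_name = p_name, point = p0, delta = 1,
                          sensitivity = sens,
                          sensitivity_relative = p0 * sens,
                          converged = TRUE, engine = engine),
                     class = "sensitivity_result"))
  }

  if (p0 <= 0)
    stop("sensitivity point must be interior (p > 0) for '", p_name, "'",
         call. = FALSE)
  h <- delta * p0
  central <- function(h) {
    lo <- p0 - h
    if (lo <= 0) stop("step produced an invalid parameter value", call. = FALSE)
    (log_deff(at(p0 + h)) - log_deff(at(lo))) / (2 * h)
  }
  est <- central(h)
  converged <- FALSE
  for (i in 1:8) {
    h2 <- h / 2
    est2 <- central(h2)
    if (abs(est2 - est) <= rtol * max(abs(est2), 1e-12)) {
      est <- est2; h <- h2; converged <- TRUE; break
    }
    est <- est2; h <- h2
  }
  structure(list(p_name = p_name, point = p0, delta = h, sensitivity = est,
                 sensitivity_relative = p0 * est, converged = converged,
                 engine = engine),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("d log(D_eff/D_P) / d %s at %g: %.6g (relative: %.6g; step %g, %s)\n",
              x$p_name, x$point, x$sensitivity, x$sensitivity_relative,
              x$delta, x$engine))
  invisible(x)
}

#' Sensitivity profile over all four dimensionless knobs
#'
#' @param dp Evaluation point ([dimensionless_params()]); the standard fixed
#'   point is `d_ratio = 20, N = 20, tau_ratio = 20, conc = 2`.
#' @param ... Passed to [sensitivity()].
#' @param path Optional CSV output path.
#' @return A data frame with one row per parameter: `parameter`, `point`,
#'   `delta`, `sensitivity`, `sensitivity_relative`.
#' @export
sensitivity_profile <- function(dp = dimensionless_params(d_ratio = 20, N = 20,
                                                          tau_ratio = 20,
                                                          conc = 2, phi = 0.3),
                                ..., path = NULL) {
  rows <- lapply(c("tau_ratio", "conc", "N", "d_ratio"), function(pn) {
    s <- sensitivity(dp, pn, ...)
    data.frame(parameter = pn, point = s$point, delta = s$delta,
               sensitivity = s$sensitivity,
               sensitivity_relative = s$sensitivity_relative)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
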