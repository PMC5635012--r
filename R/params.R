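#' Physical parameters of the anchor-matrix-particle trapping model
#'
#' Bundles the rates, diffusivities, concentrations and geometry that define
#' one instance of the trapping model. Internally all concentrations are
#' number densities in 1/um^3, diffusivities in um^2/s, lengths in um, times
#' in seconds.
#'
#' @param D_P Free nanoparticulate diffusivity (um^2/s).
#' @param D_A Anchor diffusivity (um^2/s). Anchors are much smaller than the
#'   particle, so typically `D_A >> D_P`.
#' @param D_M Matrix diffusivity (um^2/s). The polymer matrix is effectively
#'   immobile, hence the default 0.
#' @param conc_A Anchor number concentration `[A]` (1/um^3).
#' @param conc_M Matrix binding-site number concentration `[M]` (1/um^3).
#'   Default 1e5/um^3, corresponding to a 2% w/v gel with 10 anchor-binding
#'   sites per 500-kDa matrix molecule.
#' @param R0 Effective encounter parameter (um) of the Smoluchowski relation,
#'   such that `rate = D * conc_A * R0` has units 1/s. The classical geometric
#'   factor (4 pi) is absorbed into `R0`.
#' @param a_on,a_off Anchor-matrix binding and unbinding rates (1/s).
#' @param k_off Anchor-particle unbinding rate (1/s).
#' @param C Dimensionless intra-complex binding rate scale (default 1).
#' @param N Number of anchor-binding sites per particle (integer >= 0).
#' @param V_P Particle volume (um^3); default is a 200-nm-diameter sphere.
#'   Used only for regime condition C6.
#' @param L Gel layer thickness (um).
#' @param T Observation window (s).
#'
#' @return An object of class `"trapping_params"` (a named list).
#' @seealso [dimensionless_params()], [timescales()], [regime_report()]
#' @export
#' @examples
#' p <- trapping_params(conc_A = 2 / 21, a_on = 0.7, a_off = 0.3)
#' smoluchowski_rates(p)
trapping_params <- function(D_P = 1, D_A = 20, D_M = 0,
                            conc_A = 0, conc_M = 1e5, R0 = 1,
                            a_on = 0, a_off = 1, k_off = 1, C = 1, N = 15,
                            V_P = 4 / 3 * pi * 0.1^3, L = 50, T = 7200) {
  nonneg <- c(D_P = D_P, D_A = D_A, D_M = D_M, conc_A = conc_A,
              conc_M = conc_M, R0 = R0, a_on = a_on, a_off = a_off,
              k_off = k_off, C = C, V_P = V_P, L = L, T = T)
  bad <- !is.finite(nonneg) & !(names(nonneg) == "conc_M" & is.infinite(nonneg))
  if (any(bad) || any(nonneg < 0, na.rm = TRUE))
    stop("all rates, diffusivities, concentrations and geometry must be finite and >= 0",
         call. = FALSE)
  if (length(N) != 1 || is.na(N) || N < 0 || N != round(N))
    stop("'N' must be a single integer >= 0", call. = FALSE)
  structure(list(D_P = D_P, D_A = D_A, D_M = D_M, conc_A = conc_A,
                 conc_M = conc_M, R0 = R0, a_on = a_on, a_off = a_off,
                 k_off = k_off, C = C, N = as.integer(N), V_P = V_P,
                 L = L, T = T),
            class = "trapping_params")
}

#' @export
print.trapping_params <- function(x, ...) {
  cat("Trapping model parameters\n")
  cat(sprintf("  D_P = %g, D_A = %g, D_M = %g um^2/s\n", x$D_P, x$D_A, x$D_M))
  cat(sprintf("  [A] = %g, [M] = %g per um^3, R0 = %g um\n",
              x$conc_A, x$conc_M, x$R0))
  cat(sprintf("  a_on = %g, a_off = %g, k_off = %g per s; C = %g; N = %d\n",
              x$a_on, x$a_off, x$k_off, x$C, x$N))
  cat(sprintf("  geometry: L = %g um, T = %g s, V_P = %g um^3\n",
              x$L, x$T, x$V_P))
  invisible(x)
}

#' Steady-state free fraction of anchors
#'
#' Fraction of anchors not bound to the matrix at steady state,
#' `phi = a_off / (a_on + a_off)`. `phi = 0` and `phi = 1` are the extremes
#' where all or no anchors are matrix-bound.
#'
#' @param a_on,a_off Anchor-matrix binding/unbinding rates (1/s), both >= 0
#'   and not both zero.
#' @return The free fraction, in `[0, 1]`.
#' @export
#' @examples
#' free_fraction(0.7, 0.3)  # 0.3
free_fraction <- function(a_on, a_off) {
  if (any(a_on < 0) || any(a_off < 0))
    stop("'a_on' and 'a_off' must be >= 0", call. = FALSE)
  if (any(a_on + a_off == 0))
    stop("free fraction undefined: a_on + a_off must be > 0", call. = FALSE)
  a_off / (a_on + a_off)
}

#' Smoluchowski anchor-particle binding rates
#'
#' Diffusion-limited rates at which free anchors (`k_on`) and matrix-bound
#' anchors (`k_on_prime`) bind the particle:
#' `k_on = (D_P + D_A) phi [A] R0` and
#' `k_on_prime = (D_P + D_M) (1 - phi) [A] R0`.
#'
#' @param p A [trapping_params()] object.
#' @return A list with elements `k_on` and `k_on_prime` (1/s).
#' @export
smoluchowski_rates <- function(p) {
  stopifnot(inherits(p, "trapping_params"))
  phi <- free_fraction(p$a_on, p$a_off)
  list(k_on = (p$D_P + p$D_A) * phi * p$conc_A * p$R0,
       k_on_prime = (p$D_P + p$D_M) * (1 - phi) * p$conc_A * p$R0)
}

#' The three timescales of the trapping problem
#'
#' Diffusive passage time `tau_L = L^2 / (2 D_P)`, anchor-matrix kinetic
#' timescale `tau_AM = 1 / (a_on + a_off)`, and anchor-particle kinetic
#' timescale `tau_AP = 1 / (D_A [A] R0 + k_off)`.
#'
#' @param p A [trapping_params()] object.
#' @return An object of class `"timescales"` with fields `tau_L`, `tau_AM`,
#'   `tau_AP` (seconds).
#' @export
timescales <- function(p) {
  stopifnot(inherits(p, "trapping_params"))
  if (p$D_P <= 0)
    stop("tau_L undefined: D_P must be > 0", call. = FALSE)
  if (p$a_on + p$a_off <= 0)
    stop("tau_AM undefined: a_on + a_off must be > 0", call. = FALSE)
  den_ap <- p$D_A * p$conc_A * p$R0 + p$k_off
  if (den_ap <= 0)
    stop("tau_AP undefined: D_A*[A]*R0 + k_off must be > 0", call. = FALSE)
  structure(list(tau_L = p$L^2 / (2 * p$D_P),
                 tau_AM = 1 / (p$a_on + p$a_off),
                 tau_AP = 1 / den_ap),
            class = "timescales")
}

#' @export
print.timescales <- function(x, ...) {
  cat(sprintf("tau_L = %g s, tau_AM = %g s, tau_AP = %g s (tau_AP/tau_AM = %g)\n",
              x$tau_L, x$tau_AM, x$tau_AP, x$tau_AP / x$tau_AM))
  invisible(x)
}

#' Dimensionless parameters of the trapping model
#'
#' The knobs the model is naturally swept over: the diffusivity ratio
#' `D_A/D_P`, binding sites `N`, timescale separation `tau_AP/tau_AM`, the
#' dimensionless anchor concentration `[A](D_P + D_A) R0 / k_off` (the
#' phi-independent concentration scale), the free anchor fraction `phi`, and
#' the intra-complex scale `C`.
#'
#' @param d_ratio `D_A / D_P`.
#' @param N Binding sites per particle (integer >= 0).
#' @param tau_ratio `tau_AP / tau_AM`.
#' @param conc Dimensionless anchor concentration `[A](D_P + D_A) R0 / k_off`.
#' @param phi Free anchor fraction, in `[0, 1]`.
#' @param C Intra-complex rate scale.
#' @return An object of class `"dimensionless_params"`.
#' @seealso [from_dimensionless()], [to_dimensionless()]
#' @export
dimensionless_params <- function(d_ratio = 20, N = 15, tau_ratio = 20,
                                 conc = 2, phi = 0.3, C = 1) {
  vals <- c(d_ratio = d_ratio, tau_ratio = tau_ratio, conc = conc, C = C)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("dimensionless parameters must be finite and >= 0", call. = FALSE)
  if (!is.finite(phi) || phi < 0 || phi > 1)
    stop("'phi' must lie in [0, 1]", call. = FALSE)
  if (length(N) != 1 || N < 0 || N != round(N))
    stop("'N' must be a single integer >= 0", call. = FALSE)
  structure(list(d_ratio = d_ratio, N = as.integer(N), tau_ratio = tau_ratio,
                 conc = conc, phi = phi, C = C),
            class = "dimensionless_params")
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat(sprintf(paste0("Dimensionless trapping parameters: D_A/D_P = %g, N = %d, ",
                     "tau_AP/tau_AM = %g,\n  [A](D_P+D_A)R0/k_off = %g, ",
                     "phi = %g, C = %g\n"),
              x$d_ratio, x$N, x$tau_ratio, x$conc, x$phi, x$C))
  invisible(x)
}

#' Realize dimensionless parameters as physical parameters
#'
#' Inverts the nondimensionalization: fixes the rate scale `k_off` and the
#' diffusivity scale `D_P`, then solves for `D_A`, `[A] R0` and the
#' anchor-matrix rates so that the six dimensionless knobs are reproduced.
#' `[A] R0` is split with `R0 = 1` um by convention. [to_dimensionless()] is
#' its exact inverse.
#'
#' @param dp A [dimensionless_params()] object.
#' @param k_off_scale Physical `k_off` (1/s), > 0.
#' @param D_P_scale Physical `D_P` (um^2/s), > 0.
#' @param ... Further arguments (`conc_M`, `L`, `T`, ...) passed to
#'   [trapping_params()].
#' @return A [trapping_params()] object.
#' @export
#' @examples
#' p <- from_dimensionless(dimensionless_params(tau_ratio = 20, conc = 2))
#' to_dimensionless(p)
from_dimensionless <- function(dp, k_off_scale = 1, D_P_scale = 1, ...) {
  stopifnot(inherits(dp, "dimensionless_params"))
  if (k_off_scale <= 0 || D_P_scale <= 0)
    stop("'k_off_scale' and 'D_P_scale' must be > 0", call. = FALSE)
  D_P <- D_P_scale
  D_A <- dp$d_ratio * D_P
  conc_A <- dp$conc * k_off_scale / (D_P + D_A)  # with R0 = 1 um
  if (dp$tau_ratio <= 0)
    stop("'tau_ratio' must be > 0 to solve for anchor-matrix rates",
         call. = FALSE)
  tau_AP <- 1 / (D_A * conc_A + k_off_scale)
  rate_sum <- dp$tau_ratio / tau_AP  # a_on + a_off = 1/tau_AM
  trapping_params(D_P = D_P, D_A = D_A, conc_A = conc_A, R0 = 1,
                  a_on = (1 - dp$phi) * rate_sum, a_off = dp$phi * rate_sum,
                  k_off = k_off_scale, C = dp$C, N = dp$N, ...)
}

#' @rdname from_dimensionless
#' @param p A [trapping_params()] object.
#' @export
to_dimensionless <- function(p) {
  stopifnot(inherits(p, "trapping_params"))
  ts <- timescales(p)
  dimensionless_params(d_ratio = p$D_A / p$D_P, N = p$N,
                       tau_ratio = ts$tau_AP / ts$tau_AM,
                       conc = p$conc_A * p$R0 * (p$D_P + p$D_A) / p$k_off,
                       phi = free_fraction(p$a_on, p$a_off), C = p$C)
}

#' Convert between anchor mass concentration and number density
#'
#' @param mass_conc Mass concentration in ug/mL.
#' @param molar_mass Anchor molar mass in kDa (150 for IgG).
#' @return Number density in 1/um^3.
#' @export
number_density <- function(mass_conc, molar_mass = 150) {
  if (any(mass_conc < 0) || any(molar_mass <= 0))
    stop("'mass_conc' must be >= 0 and 'molar_mass' > 0", call. = FALSE)
  # ug/mL -> g/mL -> mol/mL -> molecules/mL -> molecules/um^3 (1 mL = 1e12 um^3)
  mass_conc * 1e-6 / (molar_mass * 1e3) * 6.02214076e23 / 1e12
}

#' Mean spacing between anchors at a given concentration
#'
#' The average anchor-to-anchor distance is the inverse cube root of the
#' number density. At 1-3 ug/mL of a 150-kDa IgG this is roughly 630-440 nm,
#' far larger than a 100-200 nm particle, which is why a particle rarely
#' reaches two matrix-immobilized anchors at once.
#'
#' @param mass_conc Anchor mass concentration (ug/mL), > 0.
#' @param molar_mass Anchor molar mass (kDa).
#' @return Mean spacing in nm (`Inf` for zero concentration, with a warning).
#' @seealso [conc_for_spacing()] for the exact inverse.
#' @export
#' @examples
#' anchor_spacing(1, 150)  # ~630 nm
#' anchor_spacing(3, 150)  # ~440 nm
anchor_spacing <- function(mass_conc, molar_mass = 150) {
  nd <- number_density(mass_conc, molar_mass)
  if (any(nd == 0)) {
    warning("zero anchor concentration: spacing is infinite", call. = FALSE)
  }
  nd^(-1 / 3) * 1e3  # um -> nm
}

#' Anchor concentration needed for a target mean spacing
#'
#' Exact inverse of [anchor_spacing()]: the mass concentration at which the
#' mean anchor spacing equals `spacing`. Achieving a 100 nm spacing with a
#' 150-kDa anchor takes roughly 250 ug/mL.
#'
#' @param spacing Target mean spacing (nm), > 0.
#' @param molar_mass Anchor molar mass (kDa).
#' @return Mass concentration in ug/mL.
#' @export
#' @examples
#' conc_for_spacing(100, 150)  # ~250 ug/mL
conc_for_spacing <- function(spacing, molar_mass = 150) {
  if (any(spacing <= 0) || any(molar_mass <= 0))
    stop("'spacing' and 'molar_mass' must be > 0", call. = FALSE)
  nd <- (spacing / 1e3)^(-3)  # 1/um^3
  nd * 1e12 / 6.02214076e23 * (molar_mass * 1e3) * 1e6
}

#' Report on the model's validity conditions C1-C6
#'
#' Evaluates the six regime conditions under which the trapping analysis is
#' derived, each with its numeric ratio:
#' C1 `tau_AM << tau_AP`; C2 `N >> 1`; C3 `D_A >> D_P`;
#' C4 `tau_AP < tau_L`; C5 matrix-bound anchors do not saturate the matrix,
#' `[A](1 - phi) < [M]`; C6 at most one anchor per particle volume,
#' `[A] << 1/V_P`. Strict-separation conditions (C1, C2, C3, C6) must exceed
#' `factor`; C4 and C5 are plain inequalities.
#'
#' @param p A [trapping_params()] object.
#' @param factor How much larger a ratio must be to count as "much greater"
#'   (default 10).
#' @return A data frame with one row per condition: `condition`,
#'   `description`, `ratio`, `satisfied`.
#' @export
regime_report <- function(p, factor = 10) {
  stopifnot(inherits(p, "trapping_params"), factor > 0)
  ts <- timescales(p)
  phi <- free_fraction(p$a_on, p$a_off)
  bound_conc <- p$conc_A * (1 - phi)
  ratios <- c(C1 = ts$tau_AP / ts$tau_AM,
              C2 = as.numeric(p$N),
              C3 = p$D_A / p$D_P,
              C4 = ts$tau_L / ts$tau_AP,
              C5 = if (bound_conc > 0) p$conc_M / bound_conc else Inf,
              C6 = if (p$conc_A > 0) 1 / (p$conc_A * p$V_P) else Inf)
  strict <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  data.frame(
    condition = names(ratios),
    description = c("anchor-matrix kinetics much faster than anchor-particle (tau_AM << tau_AP)",
                    "many binding sites per particle (N >> 1)",
                    "anchors much more mobile than particle (D_A >> D_P)",
                    "anchor-particle binding within the passage time (tau_AP < tau_L)",
                    "matrix-bound anchors do not saturate matrix ([A](1-phi) < [M])",
                    "at most one anchor per particle volume ([A] << 1/V_P)"),
    ratio = unname(ratios),
    satisfied = unname(ifelse(strict, ratios >= factor, ratios > 1)),
    row.names = NULL)
}
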