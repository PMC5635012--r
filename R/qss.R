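#' Intra-complex unbound-site probability alpha
#'
#' `alpha = a_off / (C a_on + a_off)`: the quasi-steady-state probability that
#' a given particle-bound anchor is not crosslinking to the matrix. With
#' `C = 1` it equals the free fraction `phi`.
#'
#' @inheritParams free_fraction
#' @param C Intra-complex binding scale.
#' @return A probability in `[0, 1]`.
#' @export
alpha_kinetic <- function(a_on, a_off, C = 1) {
  if (any(a_on < 0) || any(a_off < 0) || any(C < 0))
    stop("rates and 'C' must be >= 0", call. = FALSE)
  den <- C * a_on + a_off
  if (any(den == 0))
    stop("alpha undefined: C*a_on + a_off must be > 0", call. = FALSE)
  a_off / den
}

#' Quasi-steady-state distribution of crosslinks given n bound anchors
#'
#' On the fast anchor-matrix timescale, the number `s` of matrix bonds
#' equilibrates at fixed `n`:
#' `rho(0|n) = D_A C alpha^n / ((D_A C - D_P) alpha^n + D_P)` and, for
#' `s >= 1`, `rho(s|n) = D_P choose(n,s) (1-alpha)^s alpha^(n-s) /
#' ((D_A C - D_P) alpha^n + D_P)`.
#'
#' @param n Number of particle-bound anchors (integer >= 0).
#' @param alpha Unbound-site probability, in `[0, 1]` (see [alpha_kinetic()]).
#' @param D_A,D_P Anchor and particle diffusivities (> 0).
#' @param C Intra-complex binding scale (> 0).
#' @return Numeric vector of probabilities over `s = 0..n` (sums to 1).
#' @export
#' @examples
#' rho_s_given_n(2, alpha = 0.3)  # c(0.664, 0.155, 0.181)
rho_s_given_n <- function(n, alpha, D_A = 20, D_P = 1, C = 1) {
  if (length(n) != 1 || n < 0 || n != round(n))
    stop("'n' must be a single integer >= 0", call. = FALSE)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  if (D_A <= 0 || D_P <= 0 || C <= 0)
    stop("'D_A', 'D_P' and 'C' must be > 0", call. = FALSE)
  if (n == 0) return(1)
  an <- alpha^n
  den <- (D_A * C - D_P) * an + D_P
  s <- seq_len(n)
  rho <- c(D_A * C * an,
           D_P * exp(lchoose(n, s) + s * log1p(-alpha) + (n - s) * log(alpha))) / den
  # alpha in {0, 1} produces 0 * log(0) terms; resolve the limits exactly
  if (alpha == 0) rho <- c(rep(0, n), D_P) / den
  if (alpha == 1) rho <- c(1, rep(0, n))
  rho
}

#' Quasi-steady-state distribution of the number of bound anchors
#'
#' After the matrix bonds `s` are averaged out, `n` performs a birth-death
#' process with averaged gain rate `kappa(n) = k_on + rho(0|n) k_on_prime`
#' per empty site and loss rate `k_off` per bound anchor: free anchors bind
#' the particle from any state, whereas capture by a matrix-immobilized
#' anchor requires the particle itself to be mobile (`s = 0`), so only that
#' channel is weighted by `rho(0|n)`. The stationary law is
#' `rho(n) propto choose(N, n) prod_{j<n} kappa(j) / k_off^n`, evaluated in
#' log space.
#'
#' @param p A [trapping_params()] object with `k_off > 0`.
#' @return A list with `rho_n` (probabilities over `n = 0..N`), `kappa`
#'   (vector of `kappa(n)`, `n = 0..N-1` padded with `NA` at `n = N`), and
#'   `log_norm` (the log normalization constant).
#' @export
rho_n <- function(p) {
  stopifnot(inherits(p, "trapping_params"))
  if (p$k_off <= 0)
    stop("rho(n) undefined for k_off = 0 (no stationary anchor exchange)",
         call. = FALSE)
  ks <- smoluchowski_rates(p)
  alpha <- alpha_kinetic(p$a_on, p$a_off, p$C)
  N <- p$N
  rho0 <- vapply(0:N, function(n)
    rho_s_given_n(n, alpha, p$D_A, p$D_P, p$C)[1], numeric(1))
  kappa <- ks$k_on + rho0 * ks$k_on_prime
  if (N == 0)
    return(list(rho_n = 1, kappa = NA_real_, rho_0_given_n = rho0, log_norm = 0))
  logw <- lchoose(N, 0:N) +
    c(0, cumsum(log(kappa[1:N]))) - (0:N) * log(p$k_off)
  logw[is.nan(logw)] <- -Inf  # kappa = 0 terminates the ladder
  m <- max(logw)
  w <- exp(logw - m)
  list(rho_n = w / sum(w), kappa = c(kappa[1:N], NA_real_),
       rho_0_given_n = rho0, log_norm = -(m + log(sum(w))))
}

#' Effective diffusivity from the quasi-steady-state reduction
#'
#' The particle diffuses only while entirely free of matrix bonds (`s = 0`),
#' so on timescales long compared to the binding kinetics its motion is
#' Brownian with `D_eff = D_P sum_n rho(0|n) rho(n)`. This is the model's
#' central closed form, valid when `tau_AM << tau_AP << tau_L`.
#'
#' @param p A [trapping_params()] object, or a [dimensionless_params()]
#'   object (realized via [from_dimensionless()] with unit scales).
#' @return `D_eff / D_P`, a number in `[0, 1]`.
#' @seealso [qss()] for the full decomposition, [stationary()] for the exact
#'   chain value, [gillespie()] for the stochastic estimator.
#' @export
#' @examples
#' dp <- dimensionless_params(d_ratio = 20, N = 15, tau_ratio = 20,
#'                            conc = 10, phi = 0.3)
#' d_eff_qss(dp)  # far below 1: a >90% reduction in mobility
d_eff_qss <- function(p) {
  if (inherits(p, "dimensionless_params")) p <- from_dimensionless(p)
  r <- rho_n(p)
  sum(r$rho_0_given_n * r$rho_n)
}

#' Full quasi-steady-state decomposition
#'
#' @inheritParams d_eff_qss
#' @return An object of class `"qss_result"` with fields `alpha`,
#'   `rho_s_given_n` (an `(N+1) x (N+1)` lower-triangular matrix, row `n+1`
#'   holding `rho(s|n)`), `rho_n`, `kappa`, `D_eff_ratio`, `log_norm`.
#' @export
qss <- function(p) {
  if (inherits(p, "dimensionless_params")) p <- from_dimensionless(p)
  stopifnot(inherits(p, "trapping_params"))
  alpha <- alpha_kinetic(p$a_on, p$a_off, p$C)
  N <- p$N
  mat <- matrix(0, N + 1, N + 1,
                dimnames = list(n = 0:N, s = 0:N))
  for (n in 0:N)
    mat[n + 1, 1:(n + 1)] <- rho_s_given_n(n, alpha, p$D_A, p$D_P, p$C)
  r <- rho_n(p)
  structure(list(alpha = alpha, rho_s_given_n = mat, rho_n = r$rho_n,
                 kappa = r$kappa, D_eff_ratio = sum(r$rho_0_given_n * r$rho_n),
                 log_norm = r$log_norm, params = p),
            class = "qss_result")
}

#' @export
print.qss_result <- function(x, ...) {
  cat(sprintf("QSS reduction: alpha = %.4g, D_eff/D_P = %.6g (N = %d)\n",
              x$alpha, x$D_eff_ratio, length(x$rho_n) - 1))
  invisible(x)
}

#' Free-anchor fraction that minimizes the effective diffusivity
#'
#' Grid search over `phi` in `[0, 1]` for the trapping optimum. With a single
#' binding site (`N = 1`) the minimum sits at `phi = 0` (permanent
#' anchor-matrix bonds are best); with many sites and fast matrix exchange
#' the minimum is interior, typically `phi ~ 0.2-0.4`.
#'
#' @param d_ratio,N,tau_ratio,conc,C Dimensionless knobs (see
#'   [dimensionless_params()]); `phi` is the search variable.
#' @param resolution Number of grid points on `[0, 1]`.
#' @param engine `"qss"` (closed form) or `"chain"` (exact stationary solve;
#'   needed when `tau_ratio` is small and the QSS limit is invalid).
#' @return A list with `phi_opt`, `D_eff_min`, `interior` (`TRUE` if the
#'   minimizer is strictly inside `(0, 1)`), `degenerate` (`TRUE` when the
#'   profile is flat, e.g. at zero concentration), and the searched `profile`
#'   data frame.
#' @export
phi_minimizer <- function(d_ratio = 20, N = 15, tau_ratio = 20, conc = 10,
                          C = 1, resolution = 101, engine = c("qss", "chain")) {
  engine <- match.arg(engine)
  stopifnot(resolution >= 3)
  phis <- seq(0, 1, length.out = resolution)
  vals <- vapply(phis, function(phi) {
    dp <- dimensionless_params(d_ratio = d_ratio, N = N, tau_ratio = tau_ratio,
                               conc = conc, phi = phi, C = C)
    switch(engine,
           qss = d_eff_qss(dp),
           chain = stationary(build_chain(from_dimensionless(dp)))$D_eff_ratio)
  }, numeric(1))
  i <- which.min(vals)
  degenerate <- diff(range(vals)) < 1e-12
  list(phi_opt = phis[i], D_eff_min = vals[i],
       interior = !degenerate && i > 1 && i < resolution,
       degenerate = degenerate,
       profile = data.frame(phi = phis, D_eff_ratio = vals))
}

# Eq.-19-style evaluation from raw rate ingredients (log-space product)
d_eff_qss_rates <- function(N, k_on, k_on_prime, k_off, alpha, D_A, D_P, C) {
  if (N == 0) return(1)
  if (k_off <= 0) stop("k_off must be > 0", call. = FALSE)
  rho0 <- vapply(0:N, function(n)
    rho_s_given_n(n, alpha, D_A, D_P, C)[1], numeric(1))
  kappa <- k_on + rho0 * k_on_prime
  logw <- lchoose(N, 0:N) + c(0, cumsum(log(kappa[1:N]))) - (0:N) * log(k_off)
  logw[is.nan(logw)] <- -Inf
  w <- exp(logw - max(logw))
  sum(rho0 * w / sum(w))
}

#' Matrix-site availability under anchor competition
#'
#' When the total anchor pool `[A_T]` (all species combined) competes for a
#' finite matrix-site pool `[M]`, the fraction of unoccupied matrix sites is
#' `xi = a_off / (([A_T]/[M]) a_on + a_off)`; the spec's approximate
#' large-`[A_T]` form is `a_off [M] / (a_on [A_T])`.
#'
#' @param a_on,a_off Anchor-matrix rates (1/s).
#' @param conc_A_total Total anchor concentration `[A_T]` (1/um^3).
#' @param conc_M Matrix binding-site concentration (1/um^3).
#' @return A list with `xi` (exact) and `xi_approx`.
#' @export
saturation_xi <- function(a_on, a_off, conc_A_total, conc_M) {
  if (conc_M <= 0 || conc_A_total < 0)
    stop("'conc_M' must be > 0 and 'conc_A_total' >= 0", call. = FALSE)
  r <- conc_A_total / conc_M
  den <- r * a_on + a_off
  xi <- if (den > 0) a_off / den else 1  # no binding at all: all sites free
  xi_approx <- if (r * a_on > 0) a_off / (r * a_on) else Inf
  list(xi = xi, xi_approx = min(xi_approx, 1), ratio = r)
}

#' Saturated-regime quantities for a crowded anchor pool
#'
#' In the saturated regime `[A_T] >> [M]` the per-anchor matrix binding rate
#' is scaled by the free-site fraction `xi`, giving
#' `a_on' = xi a_on ~ a_off [M]/[A_T]`, the intra-complex rate
#' `a_on'' = C a_off [M]/[A_T]`, the kinetic timescale
#' `tau_AM = 1/((1 + [M]/[A_T]) a_off) ~ 1/a_off`, and effective
#' substitutions `phi ~ 1 - [M]/[A_T]`, `alpha ~ 1 - C [M]/[A_T]` in the
#' effective-diffusivity formula, with `[A]` the focal species' own
#' concentration.
#'
#' @param p A [trapping_params()] object for the focal species (its `conc_A`
#'   is the per-species concentration; `conc_M` supplies `[M]`).
#' @param conc_A_total Total anchor concentration across all species (1/um^3).
#' @return An object of class `"saturated_regime"` with the quantities above
#'   and `D_eff_ratio` computed from the QSS formula under the stated
#'   substitutions.
#' @seealso [saturated_params()] for the smooth all-`[A_T]` rate
#'   modification used by [species_capacity()].
#' @export
saturated_regime <- function(p, conc_A_total) {
  stopifnot(inherits(p, "trapping_params"))
  if (conc_A_total <= 0) stop("'conc_A_total' must be > 0", call. = FALSE)
  if (conc_A_total < p$conc_M)
    warning("[A_T] < [M]: saturated-regime formulas assume [A_T] >> [M]",
            call. = FALSE)
  ratio_MA <- p$conc_M / conc_A_total
  xi <- saturation_xi(p$a_on, p$a_off, conc_A_total, p$conc_M)
  phi_eff <- max(0, min(1, 1 - ratio_MA))
  alpha_eff <- max(0, min(1, 1 - p$C * ratio_MA))
  # QSS evaluation at the substituted values (per-species concentration)
  d_eff <- d_eff_qss_rates(
    N = p$N,
    k_on = (p$D_P + p$D_A) * phi_eff * p$conc_A * p$R0,
    k_on_prime = (p$D_P + p$D_M) * (1 - phi_eff) * p$conc_A * p$R0,
    k_off = p$k_off, alpha = alpha_eff, D_A = p$D_A, D_P = p$D_P, C = p$C)
  structure(list(conc_A_total = conc_A_total, conc_M = p$conc_M,
                 xi = xi$xi, xi_approx = xi$xi_approx,
                 a_on_prime = xi$xi * p$a_on,
                 a_on_intra = p$C * p$a_off * ratio_MA,
                 tau_AM_saturated = 1 / ((1 + ratio_MA) * p$a_off),
                 phi_eff = phi_eff, alpha_eff = alpha_eff,
                 D_eff_ratio = d_eff),
            class = "saturated_regime")
}

#' @export
print.saturated_regime <- function(x, ...) {
  cat(sprintf("Saturated regime: [A_T]/[M] = %.4g, xi = %.4g (approx %.4g)\n",
              x$conc_A_total / x$conc_M, x$xi, x$xi_approx))
  cat(sprintf("  effective phi = %.4g, alpha = %.4g, tau_AM = %.4g s, D_eff/D_P = %.6g\n",
              x$phi_eff, x$alpha_eff, x$tau_AM_saturated, x$D_eff_ratio))
  invisible(x)
}

#' Competition-adjusted chain rates at any total anchor concentration
#'
#' Scales the per-anchor matrix binding rate by the exact free-site fraction
#' `xi` of [saturation_xi()], then recomputes the anchor free fraction and
#' the Smoluchowski capture rates of the focal species. Unlike the asymptotic
#' [saturated_regime()] substitutions, this form is smooth in `[A_T]` and
#' recovers the unmodified model as `[A_T]/[M] -> 0`.
#'
#' The effective bound/free balance is expressed through
#' `u = xi a_on / a_off = (1 - phi) / (ratio (1 - phi) + phi)` with
#' `ratio = [A_T]/[M]`, which stays well defined in the permanent-bond limit
#' `phi = 0` (where `u = 1/ratio`).
#'
#' @inheritParams saturated_regime
#' @return A list of chain rate ingredients (`k_on`, `k_on_prime`, `k_off`,
#'   `a_on`, `a_off`, `C`, `D_A`, `D_P`, `N`) plus `phi_eff` and `alpha_eff`,
#'   suitable for [build_chain_rates()].
#' @export
saturated_params <- function(p, conc_A_total) {
  stopifnot(inherits(p, "trapping_params"))
  if (conc_A_total < 0) stop("'conc_A_total' must be >= 0", call. = FALSE)
  phi <- free_fraction(p$a_on, p$a_off)
  ratio <- conc_A_total / p$conc_M
  den <- ratio * (1 - phi) + phi
  u <- if (den > 0) (1 - phi) / den else 0   # xi * a_on / a_off (limit-safe)
  phi_eff <- 1 / (1 + u)
  alpha_eff <- 1 / (1 + p$C * u)
  list(N = p$N,
       k_on = (p$D_P + p$D_A) * phi_eff * p$conc_A * p$R0,
       k_on_prime = (p$D_P + p$D_M) * (1 - phi_eff) * p$conc_A * p$R0,
       k_off = p$k_off,
       a_on = u * p$a_off, a_off = p$a_off,
       C = p$C, D_A = p$D_A, D_P = p$D_P,
       phi_eff = phi_eff, alpha_eff = alpha_eff)
}

#' Trapping potency against the number of coexisting anchor species
#'
#' Models `m` anchor species with identical kinetics and equal per-species
#' concentration sharing one matrix: the total pool `[A_T] = m [A]` competes
#' for matrix sites, degrading each species' trapping as described by
#' [saturated_params()]. Returns the focal species' `D_eff/D_P` as a
#' function of `m`.
#'
#' @param p A [trapping_params()] object for the focal species.
#' @param m Integer vector of species counts (>= 1).
#' @param engine `"chain"` (exact stationary solve, default: required when
#'   `tau_AP/tau_AM` is small) or `"qss"` (closed form with the effective
#'   `phi`/`alpha`).
#' @return A data frame with columns `m`, `conc_A_total`, `xi`, `phi_eff`,
#'   `D_eff_ratio`.
#' @seealso [species_capacity_limit()] for the capacity summary.
#' @export
species_capacity <- function(p, m = 10^seq(0, 5, by = 0.25),
                             engine = c("chain", "qss")) {
  stopifnot(inherits(p, "trapping_params"))
  engine <- match.arg(engine)
  m <- sort(unique(c(1, m)))
  if (any(m < 1)) stop("'m' must be >= 1", call. = FALSE)
  rows <- lapply(m, function(mi) {
    A_T <- mi * p$conc_A
    sp <- saturated_params(p, A_T)
    d <- if (engine == "chain") {
      stationary(build_chain_rates(N = sp$N, k_on = sp$k_on,
                                   k_on_prime = sp$k_on_prime,
                                   k_off = sp$k_off, a_on = sp$a_on,
                                   a_off = sp$a_off, C = sp$C,
                                   D_A = sp$D_A, D_P = sp$D_P))$D_eff_ratio
    } else {
      d_eff_qss_rates(N = sp$N, k_on = sp$k_on, k_on_prime = sp$k_on_prime,
                      k_off = sp$k_off, alpha = sp$alpha_eff,
                      D_A = sp$D_A, D_P = sp$D_P, C = sp$C)
    }
    data.frame(m = mi, conc_A_total = A_T,
               xi = saturation_xi(p$a_on, p$a_off, A_T, p$conc_M)$xi,
               phi_eff = sp$phi_eff, D_eff_ratio = d)
  })
  do.call(rbind, rows)
}

#' Species capacity of an anchor-matrix system
#'
#' Two notions of capacity are supported. `type = "relative"`: the largest
#' species count `m` whose trapping potency has not degraded beyond
#' `threshold` times its own single-species value
#' (`D_eff_ratio(m) <= threshold * D_eff_ratio(1)`). `type = "absolute"`: the
#' largest `m` at which the species is still effectively trapped in absolute
#' terms (`D_eff_ratio(m) <= threshold`, e.g. 0.1 for a 90% mobility
#' reduction). The relative notion is sensitive to how deep the
#' single-species optimum is; the absolute notion tracks whether additional
#' anchor species can still immobilize their targets, which is what
#' distinguishes rapidly exchanging anchors (large capacity) from permanent
#' ones.
#'
#' @param capacity_df Output of [species_capacity()].
#' @param threshold Fold-increase over the `m = 1` value (`"relative"`,
#'   default 2) or an absolute `D_eff/D_P` ceiling (`"absolute"`).
#' @param type Capacity definition (see above).
#' @return The capacity (a value of `m`), or 0 if even `m = 1` violates the
#'   threshold.
#' @export
species_capacity_limit <- function(capacity_df, threshold = 2,
                                   type = c("relative", "absolute")) {
  stopifnot(is.data.frame(capacity_df),
            all(c("m", "D_eff_ratio") %in% names(capacity_df)))
  type <- match.arg(type)
  ceiling_val <- if (type == "relative") {
    base <- capacity_df$D_eff_ratio[capacity_df$m == 1]
    if (length(base) != 1)
      stop("capacity table must contain m = 1", call. = FALSE)
    threshold * base
  } else threshold
  ok <- capacity_df$D_eff_ratio <= ceiling_val
  if (!any(ok)) return(0)
  max(capacity_df$m[ok])
}
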