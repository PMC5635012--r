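#' Index of state (n, s) in the enumerated chain
#'
#' States are the pairs `(n, s)` with `0 <= s <= n <= N`, enumerated in
#' lexicographic order of `n` then `s`, so state `(n, s)` has index
#' `n(n+1)/2 + s + 1`.
#' @noRd
state_index <- function(n, s) n * (n + 1) / 2 + s + 1

#' Build the exact (n, s) continuous-time Markov chain
#'
#' Constructs the generator of the binding chain of a single particle: `n` is
#' the number of anchors bound to the particle, `s <= n` the number of those
#' anchors simultaneously crosslinking it to the matrix. The six transition
#' channels are
#' \describe{
#'   \item{particle gains a free anchor}{`(n,s) -> (n+1,s)` at `(N-n) k_on`}
#'   \item{matrix-bound anchor captures the particle}{`(n,0) -> (n+1,1)` at
#'     `(N-n) k_on_prime`, only from `s = 0` (a crosslinked particle is
#'     immobile and cannot diffuse onto another immobilized anchor)}
#'   \item{release of a non-crosslinking anchor}{`(n,s) -> (n-1,s)` at
#'     `(n-s) k_off`}
#'   \item{release of a crosslinking anchor}{`(n,s) -> (n-1,s-1)` at
#'     `s k_off`}
#'   \item{anchor in the complex binds the matrix}{`(n,s) -> (n,s+1)` at
#'     `g(s) (n-s) a_on`, with `g(0) = D_P/D_A` (the whole complex must
#'     diffuse to the matrix) and `g(s >= 1) = C` (intra-complex binding)}
#'   \item{an anchor-matrix bond breaks}{`(n,s) -> (n,s-1)` at `s a_off`}
#' }
#'
#' @param p A [trapping_params()] object; `k_on`/`k_on_prime` are derived via
#'   [smoluchowski_rates()].
#' @return An object of class `"chain_spec"`: fields `N`, `states` (data frame
#'   of `n`, `s`), `generator` (dense rate matrix, rows sum to zero), and
#'   `rates` (the six rate ingredients).
#' @seealso [build_chain_rates()] to supply the rates directly,
#'   [stationary()] for the stationary distribution.
#' @export
#' @examples
#' spec <- build_chain(from_dimensionless(dimensionless_params(N = 2)))
#' spec$states
build_chain <- function(p) {
  stopifnot(inherits(p, "trapping_params"))
  ks <- smoluchowski_rates(p)
  build_chain_rates(N = p$N, k_on = ks$k_on, k_on_prime = ks$k_on_prime,
                    k_off = p$k_off, a_on = p$a_on, a_off = p$a_off,
                    C = p$C, D_A = p$D_A, D_P = p$D_P)
}

#' @rdname build_chain
#' @param N Binding sites per particle.
#' @param k_on,k_on_prime Anchor-particle binding rates of free and
#'   matrix-bound anchors (1/s).
#' @param k_off Anchor-particle unbinding rate (1/s).
#' @param a_on,a_off Anchor-matrix rates (1/s).
#' @param C Intra-complex binding scale.
#' @param D_A,D_P Diffusivities, entering only through `g(0) = D_P/D_A`.
#' @export
build_chain_rates <- function(N, k_on, k_on_prime, k_off, a_on, a_off,
                              C = 1, D_A = 20, D_P = 1) {
  if (length(N) != 1 || is.na(N) || N < 0 || N != round(N))
    stop("'N' must be a single integer >= 0", call. = FALSE)
  rates <- c(k_on = k_on, k_on_prime = k_on_prime, k_off = k_off,
             a_on = a_on, a_off = a_off, C = C, D_A = D_A, D_P = D_P)
  if (any(!is.finite(rates)) || any(rates < 0) || D_A <= 0 || D_P <= 0)
    stop("rates must be finite and >= 0; diffusivities > 0", call. = FALSE)
  g0 <- D_P / D_A

  n_states <- (N + 1) * (N + 2) / 2
  states <- do.call(rbind, lapply(0:N, function(n) data.frame(n = n, s = 0:n)))
  Q <- matrix(0, n_states, n_states)
  add <- function(i, j, r) if (r > 0) Q[i, j] <<- Q[i, j] + r

  for (k in seq_len(n_states)) {
    n <- states$n[k]; s <- states$s[k]
    if (n < N) {
      add(k, state_index(n + 1, s), (N - n) * k_on)
      if (s == 0) add(k, state_index(n + 1, 1), (N - n) * k_on_prime)
    }
    if (n > 0) {
      add(k, state_index(n - 1, s), (n - s) * k_off)
      if (s > 0) add(k, state_index(n - 1, s - 1), s * k_off)
    }
    if (s < n) add(k, state_index(n, s + 1), (if (s == 0) g0 else C) * (n - s) * a_on)
    if (s > 0) add(k, state_index(n, s - 1), s * a_off)
  }
  diag(Q) <- -rowSums(Q)
  structure(list(N = as.integer(N), states = states, generator = Q,
                 rates = list(k_on = k_on, k_on_prime = k_on_prime,
                              k_off = k_off, a_on = a_on, a_off = a_off,
                              C = C, g0 = g0, D_A = D_A, D_P = D_P)),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("Binding chain: N = %d sites, %d states (n, s)\n",
              x$N, nrow(x$states)))
  r <- x$rates
  cat(sprintf("  k_on = %g, k_on' = %g, k_off = %g, a_on = %g, a_off = %g, C = %g, g(0) = %g\n",
              r$k_on, r$k_on_prime, r$k_off, r$a_on, r$a_off, r$C, r$g0))
  invisible(x)
}

#' Stationary distribution of the binding chain
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by a dense least-squares solve of the
#' augmented system. The long-run fraction of time the particle is free
#' (`s = 0`) equals `D_eff / D_P`, the exact reference value against which
#' the quasi-steady-state formula and the Gillespie estimator are checked.
#'
#' When `k_off = 0` the crosslinked states are absorbing in `n`; the chain is
#' then reducible and a stationary vector over all states does not describe
#' the long-run behaviour. In that case the absorbing structure is reported
#' (`absorbing = TRUE`) and the long-run free fraction of the terminal
#' `n = N` level (a birth-death chain in `s`) is returned instead.
#'
#' @param spec A `"chain_spec"` from [build_chain()].
#' @return An object of class `"stationary_result"`: `pi` (data frame `n`,
#'   `s`, `prob`), `prob_free` (`= sum over pi(n, 0)`), `D_eff_ratio`
#'   (equal to `prob_free`), `absorbing` flag.
#' @export
#' @examples
#' spec <- build_chain_rates(N = 1, k_on = 0.6, k_on_prime = 0.067,
#'                           k_off = 1, a_on = 40, a_off = 17)
#' stationary(spec)$D_eff_ratio
stationary <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  r <- spec$rates
  n_states <- nrow(spec$states)

  if (spec$N == 0) {
    pi_vec <- 1
  } else if (r$k_off == 0 && (r$k_on > 0 || r$k_on_prime > 0)) {
    # n can only increase: mass accumulates at n = N; report the long-run
    # s-distribution of the terminal birth-death chain
    pi_vec <- rep(0, n_states)
    pi_vec[state_index(spec$N, 0:spec$N)] <-
      bd_stationary(spec$N, r$a_on, r$a_off, r$C, r$g0)
    warning("k_off = 0: chain is absorbing in n; returning the long-run ",
            "s-distribution at n = N", call. = FALSE)
    out <- stationary_result(spec, pi_vec, absorbing = TRUE)
    return(out)
  } else {
    Q <- spec$generator
    A <- rbind(t(Q), rep(1, n_states))
    b <- c(rep(0, n_states), 1)
    pi_vec <- qr.solve(A, b)
    pi_vec[pi_vec < 0 & pi_vec > -1e-12] <- 0
    if (any(pi_vec < 0))
      stop("stationary solve produced negative probabilities; ",
           "the chain may be degenerate for these rates", call. = FALSE)
    pi_vec <- pi_vec / sum(pi_vec)
  }
  stationary_result(spec, pi_vec, absorbing = FALSE)
}

# stationary distribution of the s birth-death chain at fixed n
# (up-rate g(s)(n - s) a_on, down-rate s a_off), by detailed balance
bd_stationary <- function(n, a_on, a_off, C, g0) {
  if (n == 0) return(1)
  if (a_on == 0) return(c(1, rep(0, n)))            # s relaxes to 0
  if (a_off == 0) return(c(rep(0, n), 1))           # s absorbs at n
  w <- numeric(n + 1)  # log detailed-balance weights
  for (s in 0:(n - 1)) {
    up <- (if (s == 0) g0 else C) * (n - s) * a_on
    down <- (s + 1) * a_off
    w[s + 2] <- w[s + 1] + log(up) - log(down)
  }
  p <- exp(w - max(w))
  p / sum(p)
}

stationary_result <- function(spec, pi_vec, absorbing) {
  prob_free <- sum(pi_vec[spec$states$s == 0])
  structure(list(pi = cbind(spec$states, prob = pi_vec),
                 prob_free = prob_free, D_eff_ratio = prob_free,
                 absorbing = absorbing),
            class = "stationary_result")
}

#' @export
print.stationary_result <- function(x, ...) {
  cat(sprintf("Stationary distribution over %d states%s\n", nrow(x$pi),
              if (x$absorbing) " (absorbing chain: terminal-level result)" else ""))
  cat(sprintf("  P[s = 0] = D_eff/D_P = %.6g\n", x$prob_free))
  invisible(x)
}

#' Conditional stationary distribution of s given n from the full chain
#'
#' Utility for comparing the exact chain against the quasi-steady-state
#' factorization: normalizes the stationary probabilities within one level
#' `n`.
#'
#' @param st A `"stationary_result"`.
#' @param n Level to condition on.
#' @return Numeric vector of `P(s | n)`, `s = 0..n`.
#' @export
conditional_s_given_n <- function(st, n) {
  stopifnot(inherits(st, "stationary_result"))
  rows <- st$pi[st$pi$n == n, ]
  if (nrow(rows) == 0) stop("level 'n' not present in the chain", call. = FALSE)
  p <- rows$prob[order(rows$s)]
  if (sum(p) == 0) return(rep(NA_real_, length(p)))
  p / sum(p)
}

#' Export a chain or stationary distribution as a tidy table
#'
#' @param spec A `"chain_spec"`.
#' @param path Optional CSV path; if `NULL` the data frame is only returned.
#' @return A data frame with one row per nonzero transition (`n`, `s`,
#'   `n_to`, `s_to`, `rate`), invisibly if written.
#' @export
chain_as_table <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "chain_spec"))
  Q <- spec$generator
  idx <- which(Q > 0, arr.ind = TRUE)
  df <- data.frame(n = spec$states$n[idx[, 1]], s = spec$states$s[idx[, 1]],
                   n_to = spec$states$n[idx[, 2]], s_to = spec$states$s[idx[, 2]],
                   rate = Q[idx])
  df <- df[order(df$n, df$s, df$n_to, df$s_to), ]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
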