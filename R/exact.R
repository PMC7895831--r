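#' All spin configurations of N units
#'
#' Enumerates the `2^N` configurations in the fixed little-endian encoding
#' used by every enumeration routine in the package: the 0-based state
#' index has bit `i - 1` equal to `(s_i + 1) / 2`, so unit 1 is the
#' fastest-varying (least-significant) bit.
#'
#' @param N number of units.
#' @return `2^N x N` matrix with entries `-1/+1`; row `k + 1` is state `k`.
#' @export
state_matrix <- function(N) {
  S <- matrix(-1, 2^N, N)
  for (i in seq_len(N)) {
    bit <- bitwAnd(seq_len(2^N) - 1L, bitwShiftL(1L, i - 1L)) > 0L
    S[bit, i] <- 1
  }
  S
}

state_index <- function(s) {
  # 1-based index of a -1/+1 configuration under the little-endian encoding
  sum(((s + 1) / 2) * 2^(seq_along(s) - 1)) + 1L
}

#' Exact state distribution
#'
#' A probability vector over all `2^N` configurations in [state_matrix()]
#' order. Convenience constructors: [point_mass_distribution()] and
#' [independent_distribution()].
#'
#' @param p nonnegative vector of length `2^N` summing to 1 (within 1e-12).
#' @return An object of class `exact_distribution`.
#' @export
exact_distribution <- function(p) {
  p <- as.numeric(p)
  N <- round(log2(length(p)))
  if (2^N != length(p)) stop("length(p) must be a power of 2")
  if (any(p < -1e-15) || abs(sum(p) - 1) > 1e-12)
    stop("'p' must be a probability vector summing to 1")
  structure(list(p = pmax(p, 0), N = N), class = "exact_distribution")
}

#' @rdname exact_distribution
#' @param s0 configuration receiving all mass.
#' @export
point_mass_distribution <- function(s0) {
  N <- length(s0)
  p <- numeric(2^N)
  p[state_index(s0)] <- 1
  exact_distribution(p)
}

#' @rdname exact_distribution
#' @param m rate vector; builds the product distribution with
#'   `P(s_i = +1) = (1 + m_i) / 2` independently per unit.
#' @export
independent_distribution <- function(m) {
  N <- length(m)
  stopifnot(all(abs(m) <= 1))
  p <- 1
  for (i in seq_len(N)) p <- c(p * (1 - m[i]) / 2, p * (1 + m[i]) / 2)
  exact_distribution(p)
}

check_enum_guard <- function(N, guard, what) {
  if (N > guard)
    stop(what, " supports N <= ", guard, " (got N = ", N,
         "); exact enumeration is exponential in N")
}

# per-state activation probabilities: 2^N x N matrix of P(s_i=+1 | row state)
activation_table <- function(model, S = state_matrix(model$N)) {
  h <- sweep(S %*% t(model$J), 2L, model$H, "+")
  (1 + tanh(h)) / 2
}

#' Exact transition matrix of the parallel-update chain
#'
#' Entry `[a, b]` is \eqn{P(s_t = b \mid s_{t-1} = a)} under the factorized
#' update rule; rows sum to 1. Memory is `4^N` doubles, hence the guard.
#'
#' @param model an [ising_model] with `N <= 12`.
#' @return `2^N x 2^N` stochastic matrix in [state_matrix()] order.
#' @export
transition_matrix <- function(model) {
  check_enum_guard(model$N, 12L, "transition_matrix")
  P1 <- activation_table(model)
  trans <- matrix(1, 2^model$N, 1L)
  # appending the s_i = +1 block after the s_i = -1 block makes unit i the
  # i-th bit of the column index: the little-endian encoding by construction
  for (i in seq_len(model$N))
    trans <- cbind(trans * (1 - P1[, i]), trans * P1[, i])
  trans
}

#' Propagate an exact distribution forward in time
#'
#' Applies \eqn{p_t(s) = \sum_{s'} P(s \mid s')\, p_{t-1}(s')} for `T`
#' steps. For `N <= 12` the full transition matrix is used; for
#' `12 < N <= 16` states are accumulated row-by-row to avoid `4^N` storage.
#'
#' @param model an [ising_model] with `N <= 16`.
#' @param p0 initial [exact_distribution].
#' @param T_steps number of steps.
#' @return List of `T + 1` [exact_distribution]s (`t = 0..T`).
#' @export
evolve_exact <- function(model, p0, T_steps) {
  check_enum_guard(model$N, 16L, "evolve_exact")
  stopifnot(inherits(p0, "exact_distribution"), p0$N == model$N)
  out <- vector("list", T_steps + 1L)
  out[[1L]] <- p0
  p <- p0$p
  if (model$N <= 12L) {
    trans <- transition_matrix(model)
    for (t in seq_len(T_steps)) {
      p <- drop(p %*% trans)
      out[[t + 1L]] <- exact_distribution(p / sum(p))
    }
  } else {
    P1 <- activation_table(model)
    for (t in seq_len(T_steps)) {
      nxt <- numeric(length(p))
      for (a in which(p > 0)) {
        row <- 1
        for (i in seq_len(model$N))   # same little-endian doubling as above
          row <- c(row * (1 - P1[a, i]), row * P1[a, i])
        nxt <- nxt + p[a] * row
      }
      p <- nxt / sum(nxt)
      out[[t + 1L]] <- exact_distribution(p)
    }
  }
  out
}

#' Exact moments after one transition step
#'
#' Given the exact distribution at `t - 1`, computes the exact `m_t`, `C_t`
#' (from the propagated marginal) and `D_t` (from the one-step joint). This
#' is the ground-truth oracle against which every mean-field approximation
#' in the package is validated.
#'
#' @param model an [ising_model] with `N <= 16`.
#' @param p_prev [exact_distribution] at time `t - 1`.
#' @return A [moment_state] (with `t = NA`; the caller tracks time).
#' @export
exact_moments <- function(model, p_prev) {
  check_enum_guard(model$N, 16L, "exact_moments")
  stopifnot(inherits(p_prev, "exact_distribution"), p_prev$N == model$N)
  S <- state_matrix(model$N)
  h <- sweep(S %*% t(model$J), 2L, model$H, "+")
  TH <- tanh(h)                                   # E[s_i | prev state]
  w <- p_prev$p
  m_prev <- drop(w %*% S)
  m_t <- drop(w %*% TH)
  D_t <- crossprod(TH * w, S) - tcrossprod(m_t, m_prev)
  p_t <- evolve_exact(model, p_prev, 1L)[[2L]]$p
  C_t <- crossprod(S * p_t, S) - tcrossprod(m_t)
  moment_state(t = NA_integer_, m = m_t, C = C_t, D = D_t)
}

#' Exact moment series from an initial distribution
#'
#' Convenience oracle: propagates `p0` for `T` steps, recording exact
#' `m_t`, `C_t`, `D_t` at every step (with `C_0` from `p0` and `D_0 = 0`).
#'
#' @inheritParams evolve_exact
#' @return A [moment_series].
#' @export
exact_moment_series <- function(model, p0, T_steps) {
  check_enum_guard(model$N, 12L, "exact_moment_series")
  S <- state_matrix(model$N)
  ms <- empty_moment_series(model$N, T_steps)
  m0 <- drop(p0$p %*% S)
  ms$m[1L, ] <- m0
  ms$C[, , 1L] <- crossprod(S * p0$p, S) - tcrossprod(m0)
  p <- p0
  for (t in seq_len(T_steps)) {
    st <- exact_moments(model, p)
    ms$m[t + 1L, ] <- st$m
    ms$C[, , t + 1L] <- st$C
    ms$D[, , t + 1L] <- st$D
    p <- evolve_exact(model, p, 1L)[[2L]]
  }
  ms
}

#' Stationary distribution and one-step joint of the chain
#'
#' Finds the fixed point of [evolve_exact()] by power iteration (the chain
#' is irreducible and aperiodic for finite parameters, so the fixed point
#' is unique) and returns it together with the stationary one-step joint
#' \eqn{P(s_{t-1}, s_t) = \pi(s_{t-1}) P(s_t \mid s_{t-1})}.
#'
#' @param model an [ising_model] with `N <= 12`.
#' @param tol L1 convergence tolerance on successive marginals.
#' @param max_iter iteration cap.
#' @return List with `p` (stationary [exact_distribution]), `joint`
#'   (`2^N x 2^N` matrix, rows = `s_{t-1}`, columns = `s_t`) and `trans`
#'   (the transition matrix).
#' @export
stationary_joint <- function(model, tol = 1e-13, max_iter = 100000L) {
  check_enum_guard(model$N, 12L, "stationary_joint")
  trans <- transition_matrix(model)
  p <- rep(1 / 2^model$N, 2^model$N)
  for (it in seq_len(max_iter)) {
    p_new <- drop(p %*% trans)
    p_new <- p_new / sum(p_new)
    if (sum(abs(p_new - p)) < tol) {
      joint <- p_new * trans
      return(list(p = exact_distribution(p_new), joint = joint, trans = trans))
    }
    p <- p_new
  }
  stop("stationary_joint: no convergence after ", max_iter,
       " iterations (residual ", format(sum(abs(p_new - p))), ")")
}
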