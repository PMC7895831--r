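#' @name plefka_pairwise
#' @title Pairwise Plefka expansion
#'
#' @description
#' The pairwise expansion approximates the joint distribution of one spin
#' pair at a time with a reference model that preserves a single coupling:
#' for delayed correlations, the pair \eqn{(s_{i,t}, s_{l,t-1})}; for
#' equal-time correlations, the pair \eqn{(s_{i,t}, s_{k,t})}. The
#' conditioned unit keeps an independent parameter \eqn{\Theta^*}, and the
#' active unit's parameter \eqn{\theta^*_i(s)} is solved separately for the
#' conditioning spin at +1 and -1, giving a pair of implicit scalar
#' equations per ordered pair. The pair marginal then yields `m`, `D`
#' (delayed) or `C` (equal-time) directly. Second order in the expansion
#' parameter; reduces to the TAP family at weak coupling.
NULL

#' Two-step memory for the pairwise delayed update
#'
#' The delayed pairwise equations consume statistics from the two previous
#' steps. `m_prev2`/`C_prev2` may be `NULL` at the first update step, in
#' which case the conditioning parameter is taken as
#' \eqn{\Theta^*_{l} = \mathrm{artanh}(m_{l,\mathrm{prev}})} (exact when
#' the initial distribution is an independent model with known rates).
#'
#' @param m_prev,m_prev2 rate vectors at `t - 1` and `t - 2`.
#' @param C_prev,C_prev2 equal-time covariances at `t - 1` and `t - 2`.
#' @param D_prev delayed covariance at `t - 1` (between `t - 1` and
#'   `t - 2`).
#' @return An object of class `two_step_memory`.
#' @export
two_step_memory <- function(m_prev, C_prev, D_prev,
                            m_prev2 = NULL, C_prev2 = NULL) {
  N <- length(m_prev)
  m_prev <- check_rates(m_prev, N)
  C_prev <- check_cov(C_prev, N)
  stopifnot(all(dim(D_prev) == N))
  if (!is.null(m_prev2)) m_prev2 <- check_rates(m_prev2, N, "'m_prev2'")
  if (!is.null(C_prev2)) C_prev2 <- check_cov(C_prev2, N, "'C_prev2'")
  structure(list(m_prev = m_prev, C_prev = C_prev, D_prev = unname(D_prev),
                 m_prev2 = m_prev2, C_prev2 = C_prev2, N = N),
            class = "two_step_memory")
}

clamp_rate <- function(m) pmin(pmax(m, -1 + 1e-12), 1 - 1e-12)

#' Pairwise delayed update: rates and delayed covariances
#'
#' For every ordered pair `(i, l)` the reference parameters are
#' \deqn{\theta^*_{i,t}(s) = H_i + \sum_j J_{ij} m_{j,t-1}
#'   + \Big(J_{il} + \sum_{j \neq l, n} J_{ij} J_{ln} D_{jn,t-1}\Big)
#'     (s - m_{l,t-1})
#'   - \tanh\theta^*_{i,t}(s) \sum_{j,n \neq l} J_{ij} J_{in} C_{jn,t-1},}
#' solved for the conditioning spin `s = +1` and `s = -1`, and
#' \deqn{\Theta^*_{l,t-1} = H_l + \sum_n J_{ln} m_{n,t-2}
#'   - m_{l,t-1} \sum_{mn} J_{lm} J_{ln} C_{mn,t-2}}
#' (self-consistent through \eqn{m_{l,t-1} = \tanh\Theta^*_{l,t-1}}). The
#' pair marginal gives
#' \eqn{m_{i,t} = \sum_s \tanh\theta^*_i(s) Q^*(s)} and
#' \eqn{D_{il,t} = \sum_s s \tanh\theta^*_i(s) Q^*(s) - m_{i,t} m_{l,t-1}}.
#' The sums exclude the conditioned unit `l` from the variance correction
#' (both indices) and from the first index of the `D`-dependent term.
#'
#' The unit rate is computed once per pair; the returned `m` is the average
#' across conditioning units `l`, and the maximum across-pair spread is
#' reported as the diagnostic `m_spread` (zero when `J = 0`).
#'
#' @param mem a [two_step_memory].
#' @param model an [ising_model].
#' @param opts a [solver_options].
#' @return List with `m` (pair-averaged rates), `D`, `m_spread`
#'   (diagnostic) and `Theta_prev` (conditioning parameters).
#' @export
plefka2_delayed <- function(mem, model, opts = solver_options()) {
  stopifnot(inherits(mem, "two_step_memory"), mem$N == model$N)
  J <- model$J
  N <- model$N
  m1 <- mem$m_prev
  g <- model$H + drop(J %*% m1)
  # Theta*_{l,t-1}: TAP-type solve from the t-2 statistics, or artanh of
  # the known initial rate at the boundary step
  if (is.null(mem$m_prev2)) {
    Theta <- atanh(clamp_rate(m1))
  } else {
    c2 <- model$H + drop(J %*% mem$m_prev2)
    b2 <- rowSums((J %*% mem$C_prev2) * J)
    Theta <- solve_theta_core(c2, b2, opts)
  }
  mQ <- tanh(Theta)
  q_plus <- (1 + mQ) / 2

  # coupling seen by the pair: direct link + D-mediated second-order term
  A <- J %*% mem$D_prev
  u <- rowSums(J * mem$D_prev)               # sum_n J_ln D_ln
  K <- tcrossprod(A, J) - sweep(J, 2L, u, "*")
  eff <- J + K
  # variance correction excluding unit l from both indices
  M <- J %*% mem$C_prev
  W <- rowSums(M * J)
  V <- matrix(W, N, N) - 2 * J * M +
    J^2 * matrix(diag(mem$C_prev), N, N, byrow = TRUE)

  Ml <- matrix(m1, N, N, byrow = TRUE)
  th_plus <- solve_theta_core(g + eff * (1 - Ml), V, opts)
  th_minus <- solve_theta_core(g + eff * (-1 - Ml), V, opts)
  T_plus <- tanh(th_plus); T_minus <- tanh(th_minus)
  Qp <- matrix(q_plus, N, N, byrow = TRUE)
  m_pair <- T_plus * Qp + T_minus * (1 - Qp)
  corr <- T_plus * Qp - T_minus * (1 - Qp)   # sum_s s tanh(theta*) Q*(s)
  D <- corr - m_pair * matrix(mQ, N, N, byrow = TRUE)
  m <- rowMeans(m_pair)
  list(m = m, D = D,
       m_spread = max(abs(m_pair - m)),
       Theta_prev = Theta)
}

#' Pairwise equal-time update: equal-time covariances
#'
#' For every ordered pair `(i, k)` at time `t`:
#' \deqn{\theta^*_{i,t}(s_k) = H_i + \sum_j J_{ij} m_{j,t-1}
#'   + \Big(\sum_{jl} J_{ij} J_{kl} C_{jl,t-1}\Big)(s_k - m_{k,t})
#'   - \tanh\theta^*_{i,t}(s_k) \sum_{jl} J_{ij} J_{il} C_{jl,t-1},}
#' \deqn{\Theta^*_{k,t} = H_k + \sum_l J_{kl} m_{l,t-1}
#'   - m_{k,t} \sum_{jl} J_{kj} J_{kl} C_{jl,t-1},}
#' with \eqn{m_{k,t} = \tanh\Theta^*_{k,t}} solved self-consistently, and
#' \deqn{C_{ik,t} = \sum_{s_k} s_k \tanh\theta^*_i(s_k) Q^*(s_k)
#'       - m_{i,t} m_{k,t}.}
#' The two ordered estimates need not agree exactly; the returned matrix is
#' their average (hence symmetric), with diagonal `1 - m^2`.
#'
#' @inheritParams plefka_t_second
#' @return `N x N` symmetric covariance matrix with attribute `"m"` (the
#'   rates `tanh(Theta*)` used in the construction).
#' @export
plefka2_equal_time <- function(m_prev, C_prev, model, opts = solver_options()) {
  m_prev <- check_rates(m_prev, model$N)
  C_prev <- check_cov(C_prev, model$N)
  J <- model$J
  N <- model$N
  g <- model$H + drop(J %*% m_prev)
  E <- tcrossprod(J %*% C_prev, J)       # sum_{jl} J_ij C_jl J_kl
  W <- diag(E)
  Theta <- solve_theta_core(g, W, opts)
  mQ <- tanh(Theta)
  q_plus <- (1 + mQ) / 2

  Mk <- matrix(mQ, N, N, byrow = TRUE)
  B <- matrix(W, N, N)
  th_plus <- solve_theta_core(g + E * (1 - Mk), B, opts)
  th_minus <- solve_theta_core(g + E * (-1 - Mk), B, opts)
  T_plus <- tanh(th_plus); T_minus <- tanh(th_minus)
  Qp <- matrix(q_plus, N, N, byrow = TRUE)
  m_pair <- T_plus * Qp + T_minus * (1 - Qp)
  C <- (T_plus * Qp - T_minus * (1 - Qp)) - m_pair * Mk
  C <- (C + t(C)) / 2
  C <- with_unit_diag(C, mQ)
  attr(C, "m") <- mQ
  C
}
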