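#' @name plefka_independent
#' @title Mean-field steps from expansions around independent models
#'
#' @description
#' One-step updates of `(m_t, C_t, D_t)` from the previous-step statistics,
#' for the expansions whose reference model is a product of independent
#' spins:
#'
#' * [nmf_step()] / [tap_step()] assume independence at `t - 1` and `t`;
#'   first order gives the naive mean-field (nMF) equations, second order
#'   adds the Onsager reaction term (TAP).
#' * [plefka_t_first()] / [plefka_t_second()] assume independence only at
#'   `t`, conditioning on the known previous covariance `C_prev`; the
#'   second order reduces exactly to TAP when `C_prev` is the covariance of
#'   an independent model, `diag(1 - m_prev^2)`.
#'
#' All steps set `diag(C) = 1 - m^2` (an identity for binary spins); the
#' expansions define off-diagonal entries only.
NULL

check_rates <- function(m, N, what = "'m_prev'") {
  m <- as.numeric(m)
  if (length(m) != N) stop(what, " has length ", length(m), ", expected ", N)
  if (any(abs(m) > 1)) stop(what, " must lie in [-1, 1]")
  m
}

check_cov <- function(C, N, what = "'C_prev'") {
  C <- as.matrix(C)
  if (!all(dim(C) == N)) stop(what, " must be ", N, " x ", N)
  if (max(abs(C - t(C))) > 1e-8) stop(what, " must be symmetric")
  unname(C)
}

with_unit_diag <- function(C, m) {
  diag(C) <- 1 - m^2
  C
}

#' Naive mean-field step
#'
#' First-order update around independent models at `t - 1` and `t`:
#' \deqn{m_{i,t} = \tanh[H_i + \sum_j J_{ij} m_{j,t-1}], \quad
#'       C_{ik,t} = 0 \; (i \neq k), \quad
#'       D_{il,t} = J_{il}(1 - m_{i,t}^2)(1 - m_{l,t-1}^2).}
#'
#' @param m_prev rate vector at `t - 1`.
#' @param model an [ising_model].
#' @return A [moment_state].
#' @export
nmf_step <- function(m_prev, model) {
  m_prev <- check_rates(m_prev, model$N)
  m <- tanh(model$H + drop(model$J %*% m_prev))
  a_i <- 1 - m^2
  D <- model$J * tcrossprod(a_i, 1 - m_prev^2)
  C <- with_unit_diag(matrix(0, model$N, model$N), m)
  moment_state(t = NA_integer_, m = m, C = C, D = D)
}

#' TAP (second-order) mean-field step
#'
#' Adds the Onsager reaction term to the naive mean field. The rates solve
#' the self-consistent equation
#' \deqn{m_{i,t} = \tanh\Big[H_i + \sum_j J_{ij} m_{j,t-1}
#'       - m_{i,t} \sum_j J_{ij}^2 (1 - m_{j,t-1}^2)\Big],}
#' with correlations
#' \deqn{C_{ik,t} = (1 - m_i^2)(1 - m_k^2) \sum_j J_{ij} J_{kj}
#'       (1 - m_{j,t-1}^2) \; (i \neq k),}
#' \deqn{D_{il,t} = J_{il}(1 - m_i^2)(1 - m_{l,t-1}^2)
#'       (1 + 2 J_{il} m_i m_{l,t-1}).}
#'
#' @inheritParams nmf_step
#' @param opts a [solver_options] for the self-consistent rate solve.
#' @return A [moment_state].
#' @export
tap_step <- function(m_prev, model, opts = solver_options()) {
  m_prev <- check_rates(m_prev, model$N)
  v_prev <- 1 - m_prev^2
  g <- model$H + drop(model$J %*% m_prev)
  b <- drop(model$J^2 %*% v_prev)        # Onsager coefficient
  theta <- solve_theta_core(g, b, opts)  # theta = g - b tanh(theta)
  m <- tanh(theta)
  a_i <- 1 - m^2
  C <- tcrossprod(a_i) * (model$J %*% (v_prev * t(model$J)))
  C <- with_unit_diag(C, m)
  D <- model$J * tcrossprod(a_i, v_prev) *
    (1 + 2 * model$J * tcrossprod(m, m_prev))
  moment_state(t = NA_integer_, m = m, C = C, D = D)
}

#' First-order step conditioned on the previous covariance
#'
#' Expansion around an independent model at `t` only: the rate equation is
#' the naive mean field, but the delayed covariance propagates `C_prev`,
#' \deqn{D_{il,t} = (1 - m_{i,t}^2) \sum_j J_{ij} C_{jl,t-1}.}
#'
#' @inheritParams nmf_step
#' @param C_prev equal-time covariance at `t - 1`.
#' @return A [moment_state].
#' @export
plefka_t_first <- function(m_prev, C_prev, model) {
  m_prev <- check_rates(m_prev, model$N)
  C_prev <- check_cov(C_prev, model$N)
  m <- tanh(model$H + drop(model$J %*% m_prev))
  D <- (1 - m^2) * (model$J %*% C_prev)
  C <- with_unit_diag(matrix(0, model$N, model$N), m)
  moment_state(t = NA_integer_, m = m, C = C, D = D)
}

#' Second-order step conditioned on the previous covariance
#'
#' Expansion around an independent model at `t`, second order. The rates
#' solve
#' \deqn{m_{i,t} = \tanh\Big[H_i + \sum_j J_{ij} m_{j,t-1}
#'       - m_{i,t} \sum_{jl} J_{ij} J_{il} C_{jl,t-1}\Big],}
#' and the covariances are
#' \deqn{C_{ik,t} = (1 - m_i^2)(1 - m_k^2) \sum_{jl} J_{ij} J_{kl}
#'       C_{jl,t-1} \; (i \neq k),}
#' \deqn{D_{il,t} = (1 - m_i^2) \Big(\sum_j J_{ij} C_{jl,t-1}\Big)
#'       (1 + 2 J_{il} m_i m_{l,t-1}).}
#' With `C_prev = diag(1 - m_prev^2)` this reproduces [tap_step()] exactly.
#'
#' @inheritParams plefka_t_first
#' @param opts a [solver_options].
#' @return A [moment_state].
#' @export
plefka_t_second <- function(m_prev, C_prev, model, opts = solver_options()) {
  m_prev <- check_rates(m_prev, model$N)
  C_prev <- check_cov(C_prev, model$N)
  J <- model$J
  JC <- J %*% C_prev
  g <- model$H + drop(J %*% m_prev)
  b <- rowSums(JC * J)                   # sum_{jl} J_ij J_il C_jl
  theta <- solve_theta_core(g, b, opts)
  m <- tanh(theta)
  a_i <- 1 - m^2
  C <- tcrossprod(a_i) * tcrossprod(JC, J)
  C <- with_unit_diag(C, m)
  D <- a_i * JC * (1 + 2 * J * tcrossprod(m, m_prev))
  moment_state(t = NA_integer_, m = m, C = C, D = D)
}
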