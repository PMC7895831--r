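#' Gauss-Hermite quadrature rule for standard normal expectations
#'
#' Nodes and weights such that \eqn{E[f(Z)] \approx \sum_j w_j f(z_j)} for
#' `Z ~ N(0, 1)`; a thin transform of the `exp(-x^2)` Gauss-Hermite rule.
#' Integrands here (tanh and powers of it) are smooth and bounded, for
#' which the rule converges rapidly; 40 nodes are ample at the coupling
#' scales of the Sherrington-Kirkpatrick ensemble.
#'
#' @param nodes number of quadrature nodes.
#' @return List with numeric vectors `z` (nodes) and `w` (weights, summing
#'   to 1).
#' @export
gauss_hermite_rule <- function(nodes = 40L) {
  gh <- pracma::gaussHermite(nodes)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

#' Gaussian expectation of tanh-type integrands
#'
#' Computes \eqn{\int \mathrm{D}x\, f(\mu + x\sqrt{v})} with
#' \eqn{\mathrm{D}x} the standard normal measure, for
#' `f = tanh`, `tanh^2` or `1 - tanh^2`. A zero variance returns
#' `f(mean)` exactly (degenerate Gaussian).
#'
#' @param kind one of `"tanh"`, `"tanh_sq"`, `"one_minus_tanh_sq"`.
#' @param mean scalar or vector of field means.
#' @param var scalar or vector of field variances (`>= 0`).
#' @param rule a quadrature rule from [gauss_hermite_rule()].
#' @return Numeric of the same length as `mean`.
#' @export
gauss_expect <- function(kind = c("tanh", "tanh_sq", "one_minus_tanh_sq"),
                         mean, var, rule = gauss_hermite_rule()) {
  kind <- match.arg(kind)
  if (any(var < 0)) stop("'var' must be nonnegative")
  f <- switch(kind,
    tanh = tanh,
    tanh_sq = function(x) tanh(x)^2,
    one_minus_tanh_sq = function(x) 1 - tanh(x)^2)
  n <- max(length(mean), length(var))
  mean <- rep_len(mean, n); var <- rep_len(var, n)
  out <- numeric(n)
  zero <- var == 0
  out[zero] <- f(mean[zero])
  if (any(!zero)) {
    arg <- mean[!zero] + outer(sqrt(var[!zero]), rule$z)
    out[!zero] <- drop(f(arg) %*% rule$w)
  }
  if (!all(is.finite(out))) stop("quadrature produced non-finite values")
  out
}

#' Effective Gaussian field statistics
#'
#' Under the expansion around an independent model at `t - 1`, the local
#' field of unit `i` is a sum of many weakly dependent terms and is treated
#' as Gaussian with mean \eqn{g_i = H_i + \sum_j J_{ij} m_{j,t-1}},
#' variance \eqn{\Delta_i = \sum_j J_{ij}^2 (1 - m_{j,t-1}^2)} and pairwise
#' correlation
#' \eqn{\rho_{ik} = \sum_j J_{ij} J_{kj} (1 - m_{j,t-1}^2) /
#' \sqrt{\Delta_i \Delta_k}}. Where a variance vanishes the field is
#' deterministic; the corresponding off-diagonal `rho` entries are set to 0
#' by convention.
#'
#' @inheritParams nmf_step
#' @return List with `g` (means), `Delta` (variances) and `rho`
#'   (correlation matrix).
#' @export
gaussian_field_stats <- function(m_prev, model) {
  m_prev <- check_rates(m_prev, model$N)
  v_prev <- 1 - m_prev^2
  J <- model$J
  g <- model$H + drop(J %*% m_prev)
  cov_h <- J %*% (v_prev * t(J))         # sum_j J_ij J_kj (1 - m_j^2)
  Delta <- pmax(diag(cov_h), 0)
  sd <- sqrt(Delta)
  denom <- tcrossprod(sd)
  rho <- matrix(0, model$N, model$N)
  pos <- denom > 0
  rho[pos] <- cov_h[pos] / denom[pos]
  rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  diag(rho) <- ifelse(Delta > 0, 1, 0)
  list(g = g, Delta = Delta, rho = rho)
}

#' Gaussian effective-field step (expansion around independence at t - 1)
#'
#' First-order update where the previous-step spins are treated as
#' independent and their summed input as a Gaussian field:
#' \deqn{m_{i,t} = \int \mathrm{D}x \tanh(g_i + x\sqrt{\Delta_i}),}
#' \deqn{C_{ik,t} = \int \mathrm{D}^{\rho_{ik}}_{xy}
#'       \tanh(g_i + x\sqrt{\Delta_i}) \tanh(g_k + y\sqrt{\Delta_k})
#'       - m_i m_k \; (i \neq k),}
#' \deqn{D_{il,t} = \Big(\sum_j J_{ij} C_{jl,t-1}\Big)
#'       \int \mathrm{D}x\, [1 - \tanh^2(g_i + x\sqrt{\Delta_i})].}
#' The bivariate integral uses the correlated Gaussian measure with
#' correlation `rho[i, k]`, evaluated by conditioning (`y = rho x +
#' sqrt(1 - rho^2) y'`) on a tensor product of the univariate rule. The
#' method is exact for fully asymmetric networks in the large-`N` limit.
#'
#' @inheritParams plefka_t_first
#' @param rule quadrature rule from [gauss_hermite_rule()].
#' @return A [moment_state].
#' @export
plefka_tm1_step <- function(m_prev, C_prev, model,
                            rule = gauss_hermite_rule()) {
  m_prev <- check_rates(m_prev, model$N)
  C_prev <- check_cov(C_prev, model$N)
  N <- model$N
  gf <- gaussian_field_stats(m_prev, model)
  sd <- sqrt(gf$Delta)
  m <- gauss_expect("tanh", gf$g, gf$Delta, rule)
  a_i <- gauss_expect("one_minus_tanh_sq", gf$g, gf$Delta, rule)
  D <- a_i * (model$J %*% C_prev)
  # bivariate integral over all pairs at once, conditioning y on x
  Gk <- matrix(gf$g, N, N, byrow = TRUE)
  SDk <- matrix(sd, N, N, byrow = TRUE)
  cfac <- sqrt(pmax(1 - gf$rho^2, 0))
  E <- matrix(0, N, N)
  t1 <- tanh(gf$g + outer(sd, rule$z))    # N x nodes, integrand of unit i
  for (p in seq_along(rule$z)) {
    inner <- matrix(0, N, N)
    shift <- gf$rho * rule$z[p]
    for (q in seq_along(rule$z))
      inner <- inner + rule$w[q] * tanh(Gk + SDk * (shift + cfac * rule$z[q]))
    E <- E + rule$w[p] * (t1[, p] * inner)
  }
  C <- E - tcrossprod(m)
  C[gf$Delta == 0, ] <- 0               # deterministic field: no covariance
  C[, gf$Delta == 0] <- 0
  C <- with_unit_diag(C, m)
  if (!all(is.finite(C)) || !all(is.finite(m)) || !all(is.finite(D)))
    stop("plefka_tm1_step: quadrature produced non-finite values")
  moment_state(t = NA_integer_, m = m, C = C, D = D)
}
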