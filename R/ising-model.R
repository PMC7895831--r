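#' Construct a kinetic Ising model
#'
#' A kinetic Ising model is a discrete-time Markov chain of `N` binary units
#' \eqn{s_i \in \{-1,+1\}} updated in parallel. Given the previous
#' configuration, each unit activates independently with probability
#' \deqn{P(s_{i,t} = +1 \mid s_{t-1}) = \frac{e^{h_i}}{2\cosh h_i}, \qquad
#'       h_i = H_i + \sum_j J_{ij} s_{j,t-1},}
#' where `H` are local external fields and `J[i, j]` couples unit `i` at
#' time `t` to unit `j` at time `t - 1`. `J` need not be symmetric; an
#' asymmetric `J` makes the chain irreversible (a non-equilibrium model).
#'
#' @param H numeric vector of length `N`; local external fields.
#' @param J numeric `N x N` matrix of couplings (row = postsynaptic unit at
#'   time `t`, column = presynaptic unit at time `t - 1`).
#' @return An object of class `ising_model` with elements `H`, `J` and `N`.
#' @examples
#' m <- ising_model(H = c(0, 0.5), J = matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
#' conditional_activation(c(1, 1), m)
#' @export
ising_model <- function(H, J) {
  H <- as.numeric(H)
  N <- length(H)
  J <- as.matrix(J)
  if (!is.numeric(J) || nrow(J) != N || ncol(J) != N)
    stop("'J' must be a numeric ", N, " x ", N, " matrix matching length(H)")
  if (!all(is.finite(H)) || !all(is.finite(J)))
    stop("'H' and 'J' must be finite")
  structure(list(H = H, J = unname(J), N = N), class = "ising_model")
}

#' @export
print.ising_model <- function(x, ...) {
  sym <- if (x$N > 1 && isTRUE(all.equal(x$J, t(x$J)))) "symmetric" else "asymmetric"
  cat(sprintf("Kinetic Ising model: N = %d units, %s couplings\n", x$N, sym))
  cat(sprintf("  fields    H: range [%.4g, %.4g]\n", min(x$H), max(x$H)))
  cat(sprintf("  couplings J: range [%.4g, %.4g]\n", min(x$J), max(x$J)))
  invisible(x)
}

check_spins <- function(s, N, what = "spin configuration") {
  s <- as.numeric(s)
  if (length(s) != N)
    stop(what, " has length ", length(s), ", expected ", N)
  if (!all(s == 1 | s == -1))
    stop(what, " must contain only -1/+1 entries")
  s
}

#' Per-unit activation probabilities given the previous state
#'
#' Evaluates \eqn{P(s_{i,t} = +1 \mid s_{t-1}) = e^{h_i} / (2\cosh h_i)}
#' for every unit, with \eqn{h_i = H_i + \sum_j J_{ij} s_{j,t-1}}. The
#' probability of \eqn{s_i = -1} is the complement.
#'
#' @param prev numeric vector in `{-1, +1}`; the configuration at `t - 1`.
#' @param model an [ising_model].
#' @return numeric vector of probabilities in (0, 1).
#' @export
conditional_activation <- function(prev, model) {
  prev <- check_spins(prev, model$N, "'prev'")
  h <- model$H + drop(model$J %*% prev)
  (1 + tanh(h)) / 2
}

#' Sample an ensemble of spin trajectories
#'
#' Runs `R` independent trajectories of the parallel-update chain for `T`
#' steps from a common initial configuration. Sampling is vectorized over
#' trials; a fixed `seed` reproduces the ensemble bit-exactly.
#'
#' @param model an [ising_model].
#' @param s0 initial configuration (`-1/+1` vector of length `N`).
#' @param T_steps number of update steps (`T >= 1`); the ensemble stores
#'   `T + 1` time slices including `t = 0`.
#' @param R number of trials (`R >= 1`).
#' @param seed integer seed for the sampler.
#' @return A `trajectory_ensemble`: integer array `R x (T + 1) x N` of
#'   `-1/+1` entries with attributes `seed` and `params_id`.
#' @export
sample_trajectories <- function(model, s0, T_steps, R, seed = 1L) {
  s0 <- check_spins(s0, model$N, "'s0'")
  if (T_steps < 1) stop("'T_steps' must be >= 1")
  if (R < 1) stop("'R' must be >= 1")
  N <- model$N
  set.seed(seed)
  data <- array(1L, dim = c(R, T_steps + 1L, N))
  cur <- matrix(rep(s0, each = R), R, N)
  data[, 1L, ] <- cur
  tJ <- t(model$J)
  for (t in seq_len(T_steps)) {
    h <- sweep(cur %*% tJ, 2L, model$H, "+")
    p <- (1 + tanh(h)) / 2
    cur <- matrix(ifelse(stats::runif(R * N) < p, 1L, -1L), R, N)
    data[, t + 1L, ] <- cur
  }
  structure(data, seed = seed,
            params_id = params_digest(model),
            class = c("trajectory_ensemble", "array"))
}

# cheap provenance tag for ensembles (sum-based fingerprint of parameters)
params_digest <- function(model) {
  sprintf("N%d:%.8e:%.8e", model$N, sum(model$H) + sum(model$J),
          sum(model$H^2) + sum(model$J^2))
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Trajectory ensemble: R = %d trials, T = %d steps, N = %d units (seed %s)\n",
              d[1], d[2] - 1L, d[3], format(attr(x, "seed"))))
  invisible(x)
}

#' Simulate and accumulate moment statistics without storing trajectories
#'
#' Streams `R` trajectories through time, accumulating the activation rates
#' `m_t`, equal-time covariances `C_t`, and lag-1 delayed covariances `D_t`
#' at every step. Memory use is `O(RN)` independently of `T`, which permits
#' moment estimation at sizes where storing the full ensemble would be
#' wasteful.
#'
#' @inheritParams sample_trajectories
#' @param final_only if `TRUE`, return a single [moment_state] for the last
#'   step instead of the full series.
#' @return A [moment_series] over `t = 0..T` (or one `moment_state`).
#' @export
simulate_moments <- function(model, s0, T_steps, R, seed = 1L,
                             final_only = FALSE) {
  s0 <- check_spins(s0, model$N, "'s0'")
  if (R < 2) stop("'R' must be >= 2 for covariance estimation")
  N <- model$N
  set.seed(seed)
  cur <- matrix(rep(s0, each = R), R, N)
  ms <- if (final_only) NULL else empty_moment_series(N, T_steps)
  if (!final_only) {
    ms$m[1L, ] <- colMeans(cur)
    ms$C[, , 1L] <- crossprod(cur) / R - tcrossprod(ms$m[1L, ])
  }
  tJ <- t(model$J)
  m_prev <- colMeans(cur)
  for (t in seq_len(T_steps)) {
    h <- sweep(cur %*% tJ, 2L, model$H, "+")
    p <- (1 + tanh(h)) / 2
    nxt <- matrix(ifelse(stats::runif(R * N) < p, 1, -1), R, N)
    m_t <- colMeans(nxt)
    if (!final_only || t == T_steps) {
      C_t <- crossprod(nxt) / R - tcrossprod(m_t)
      D_t <- crossprod(nxt, cur) / R - tcrossprod(m_t, m_prev)
      if (final_only)
        return(moment_state(t = t, m = m_t, C = C_t, D = D_t))
      ms$m[t + 1L, ] <- m_t
      ms$C[, , t + 1L] <- C_t
      ms$D[, , t + 1L] <- D_t
    }
    cur <- nxt
    m_prev <- m_t
  }
  ms
}
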