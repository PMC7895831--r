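#' Moment state at a single time step
#'
#' Bundles the statistics tracked by all approximation methods at time `t`:
#' activation rates \eqn{m_{i,t} = \langle s_{i,t}\rangle}, equal-time
#' covariances \eqn{C_{ik,t} = \langle s_{i,t} s_{k,t}\rangle - m_i m_k},
#' and delayed (lag-1) covariances
#' \eqn{D_{il,t} = \langle s_{i,t} s_{l,t-1}\rangle - m_{i,t} m_{l,t-1}}.
#' For spins in `{-1, +1}` the diagonal of `C` is `1 - m^2` identically.
#'
#' @param t integer time index.
#' @param m numeric rate vector, entries in `[-1, 1]`.
#' @param C `N x N` equal-time covariance matrix.
#' @param D `N x N` delayed covariance matrix (rows index time `t`, columns
#'   time `t - 1`).
#' @return An object of class `moment_state`.
#' @export
moment_state <- function(t, m, C, D) {
  m <- as.numeric(m)
  N <- length(m)
  stopifnot(is.matrix(C), all(dim(C) == N), is.matrix(D), all(dim(D) == N))
  structure(list(t = t, m = m, C = unname(C), D = unname(D)),
            class = "moment_state")
}

#' @export
print.moment_state <- function(x, ...) {
  cat(sprintf("Moment state (t = %s): N = %d\n", format(x$t), length(x$m)))
  cat(sprintf("  <m> = %.5f   <C offdiag> = %.3e   <D> = %.3e\n",
              mean(x$m), mean(offdiag(x$C)), mean(x$D)))
  invisible(x)
}

#' Off-diagonal entries of a matrix
#'
#' Convenience accessor used throughout the comparison experiments, where
#' equal-time covariances are averaged over distinct pairs only.
#'
#' @param M a square matrix.
#' @return Vector of the entries with row index different from column
#'   index.
#' @export
offdiag <- function(M) M[row(M) != col(M)]

empty_moment_series <- function(N, T_steps) {
  structure(list(m = matrix(NA_real_, T_steps + 1L, N),
                 C = array(NA_real_, c(N, N, T_steps + 1L)),
                 D = array(0, c(N, N, T_steps + 1L)),
                 T_steps = T_steps, N = N),
            class = "moment_series")
}

#' Moment series container
#'
#' Stores `m`, `C`, `D` for `t = 0..T`. Slice `t + 1` of each component
#' holds time `t`; `C[, , 1]` and `D[, , 1]` are the supplied initial
#' values (zero for a deterministic start). Extract one step with
#' [moments_at()].
#'
#' @param m `(T + 1) x N` matrix of rates.
#' @param C `N x N x (T + 1)` array of equal-time covariances.
#' @param D `N x N x (T + 1)` array of delayed covariances.
#' @return An object of class `moment_series`.
#' @export
moment_series <- function(m, C, D) {
  stopifnot(is.matrix(m), length(dim(C)) == 3, length(dim(D)) == 3)
  structure(list(m = m, C = C, D = D,
                 T_steps = nrow(m) - 1L, N = ncol(m)),
            class = "moment_series")
}

#' @export
print.moment_series <- function(x, ...) {
  cat(sprintf("Moment series: N = %d units, t = 0..%d\n", x$N, x$T_steps))
  tl <- x$T_steps + 1L
  cat(sprintf("  final <m> = %.5f  <C offdiag> = %.3e  <D> = %.3e\n",
              mean(x$m[tl, ]), mean(offdiag(x$C[, , tl])), mean(x$D[, , tl])))
  invisible(x)
}

#' Extract the moment state at time t
#'
#' @param series a [moment_series].
#' @param t time index in `0..T`.
#' @return A [moment_state].
#' @export
moments_at <- function(series, t) {
  stopifnot(t >= 0, t <= series$T_steps)
  i <- t + 1L
  moment_state(t = t, m = series$m[i, ],
               C = series$C[, , i, drop = TRUE],
               D = series$D[, , i, drop = TRUE])
}

#' Empirical moments of a trajectory ensemble
#'
#' Plug-in estimates over trials at each time step: sample means `m_t`,
#' equal-time covariances `C_t` (denominator `R`, so `diag(C) = 1 - m^2`
#' exactly for binary spins), and lag-1 cross-covariances `D_t`. `D_0` is
#' set to zero (no predecessor step).
#'
#' @param ens a `trajectory_ensemble` from [sample_trajectories()].
#' @return A [moment_series] over `t = 0..T`.
#' @export
empirical_moments <- function(ens) {
  d <- dim(ens)
  R <- d[1]; Tp1 <- d[2]; N <- d[3]
  if (R < 2) stop("need R >= 2 trials to estimate covariances")
  ms <- empty_moment_series(N, Tp1 - 1L)
  prev <- NULL
  for (t in seq_len(Tp1)) {
    S <- matrix(as.numeric(ens[, t, ]), R, N)
    m_t <- colMeans(S)
    ms$m[t, ] <- m_t
    ms$C[, , t] <- crossprod(S) / R - tcrossprod(m_t)
    if (t > 1L)
      ms$D[, , t] <- crossprod(S, prev) / R - tcrossprod(m_t, ms$m[t - 1L, ])
    prev <- S
  }
  ms
}

#' Forward prediction errors against a reference series
#'
#' Mean squared errors of the rates, equal-time covariances (off-diagonal
#' pairs only) and delayed covariances, averaged over units and over time
#' steps `t = 1..T`:
#' \deqn{\epsilon_m = \langle\langle (m^o - m^p)^2 \rangle_i\rangle_t,\quad
#'       \epsilon_C = \langle\langle (C^o - C^p)^2 \rangle_{ik}\rangle_t,\quad
#'       \epsilon_D = \langle\langle (D^o - D^p)^2 \rangle_{il}\rangle_t.}
#'
#' @param ref reference (ground-truth) [moment_series].
#' @param pred predicted [moment_series] on the same grid.
#' @return Named numeric vector `c(eps_m, eps_C, eps_D)`.
#' @export
forward_errors <- function(ref, pred) {
  stopifnot(ref$T_steps == pred$T_steps, ref$N == pred$N)
  ts <- seq.int(2L, ref$T_steps + 1L)
  off <- row(ref$C[, , 1]) != col(ref$C[, , 1])
  eC <- eD <- em <- 0
  for (t in ts) {
    em <- em + mean((ref$m[t, ] - pred$m[t, ])^2)
    dC <- ref$C[, , t] - pred$C[, , t]
    eC <- eC + mean(dC[off]^2)
    eD <- eD + mean((ref$D[, , t] - pred$D[, , t])^2)
  }
  c(eps_m = em, eps_C = eC, eps_D = eD) / length(ts)
}
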