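#' Pooled sufficient statistics for Boltzmann learning
#'
#' The maximum-likelihood equations for stationary parameters depend on the
#' data only through statistics pooled over trials and time steps
#' `t = 1..T` (previous-step statistics pooled over `t - 1 = 0..T-1`):
#' the pooled rates \eqn{\langle S_{i,t}\rangle_{r,t}}, the lag-1 cross
#' moments \eqn{\langle S_{i,t} S_{l,t-1}\rangle_{r,t}}, and the empirical
#' previous-step rates, covariance and lag-1 covariance that feed the
#' mean-field gradient estimates.
#'
#' @param ens a `trajectory_ensemble`.
#' @param compress_states if `TRUE` (default), also store the empirical
#'   distribution of previous-step states as unique rows with weights;
#'   exact-gradient learning consumes this, at cost independent of `R T`
#'   when states repeat.
#' @return An object of class `sufficient_statistics`: list with `mean_s`,
#'   `cross_lag`, `prev_mean`, `prev_cov`, `prev_lag_cov`, `RT`, and (if
#'   requested) `prev_states` / `prev_weights` / `mean_s_by_prev`.
#' @export
pool_statistics <- function(ens, compress_states = TRUE) {
  d <- dim(ens)
  R <- d[1]; Tp1 <- d[2]; N <- d[3]
  T_steps <- Tp1 - 1L
  if (R * T_steps < 2) stop("need R * T >= 2 pooled samples")
  cur <- matrix(as.numeric(ens[, -1L, , drop = FALSE]), R * T_steps, N)
  prev <- matrix(as.numeric(ens[, -Tp1, , drop = FALSE]), R * T_steps, N)
  RT <- R * T_steps
  mean_s <- colMeans(cur)
  cross_lag <- crossprod(cur, prev) / RT
  prev_mean <- colMeans(prev)
  prev_cov <- crossprod(prev) / RT - tcrossprod(prev_mean)
  # pooled lag-1 covariance of the observed states (for two-step methods):
  # pairs (t-1, t-2), available for t >= 2
  if (T_steps >= 2) {
    a <- matrix(as.numeric(ens[, 2:T_steps, , drop = FALSE]), R * (T_steps - 1L), N)
    b <- matrix(as.numeric(ens[, 1:(T_steps - 1L), , drop = FALSE]), R * (T_steps - 1L), N)
    prev_lag_cov <- crossprod(a, b) / nrow(a) - tcrossprod(colMeans(a), colMeans(b))
  } else {
    prev_lag_cov <- matrix(0, N, N)
  }
  out <- list(mean_s = mean_s, cross_lag = cross_lag, prev_mean = prev_mean,
              prev_cov = (prev_cov + t(prev_cov)) / 2,
              prev_lag_cov = prev_lag_cov, RT = RT, N = N)
  if (compress_states) {
    key <- prev %*% 2^(seq_len(N) - 1)
    grp <- match(key, unique(key))
    w <- tabulate(grp) / RT
    uniq <- prev[!duplicated(grp), , drop = FALSE]
    out$prev_states <- uniq
    out$prev_weights <- w
  }
  structure(out, class = "sufficient_statistics")
}

#' Simulate and pool sufficient statistics without storing trajectories
#'
#' Streams `R` trajectories through time, accumulating the pooled
#' statistics of [pool_statistics()] on the fly (`O(RN)` memory). Used for
#' mean-field learning at sizes where the full ensemble would be bulky;
#' does not record unique states, so it supports the mean-field gradient
#' estimators only.
#'
#' @inheritParams sample_trajectories
#' @return A `sufficient_statistics` object (without `prev_states`).
#' @export
simulate_pooled_statistics <- function(model, s0, T_steps, R, seed = 1L) {
  s0 <- check_spins(s0, model$N, "'s0'")
  N <- model$N
  set.seed(seed)
  cur <- matrix(rep(s0, each = R), R, N)
  tJ <- t(model$J)
  sum_cur <- sum_prev <- numeric(N)
  cross <- prev_cross <- matrix(0, N, N)
  lag_a <- lag_b <- numeric(N)
  lag_cross <- matrix(0, N, N)
  for (t in seq_len(T_steps)) {
    h <- sweep(cur %*% tJ, 2L, model$H, "+")
    p <- (1 + tanh(h)) / 2
    nxt <- matrix(ifelse(stats::runif(R * N) < p, 1, -1), R, N)
    sum_cur <- sum_cur + colSums(nxt)
    sum_prev <- sum_prev + colSums(cur)
    cross <- cross + crossprod(nxt, cur)
    prev_cross <- prev_cross + crossprod(cur)
    if (t >= 2) {                     # (t-1, t-2) pairs for the lag term
      lag_a <- lag_a + colSums(cur)
      lag_b <- lag_b + colSums(prv)
      lag_cross <- lag_cross + crossprod(cur, prv)
    }
    prv <- cur
    cur <- nxt
  }
  RT <- R * T_steps
  prev_mean <- sum_prev / RT
  pc <- prev_cross / RT - tcrossprod(prev_mean)
  n_lag <- R * max(T_steps - 1L, 1L)
  structure(list(
    mean_s = sum_cur / RT, cross_lag = cross / RT, prev_mean = prev_mean,
    prev_cov = (pc + t(pc)) / 2,
    prev_lag_cov = if (T_steps >= 2)
      lag_cross / n_lag - tcrossprod(lag_a / n_lag, lag_b / n_lag)
      else matrix(0, N, N),
    RT = RT, N = N), class = "sufficient_statistics")
}

#' @export
print.sufficient_statistics <- function(x, ...) {
  cat(sprintf("Sufficient statistics: N = %d, RT = %d pooled samples\n",
              x$N, x$RT))
  if (!is.null(x$prev_states))
    cat(sprintf("  %d unique previous states\n", nrow(x$prev_states)))
  invisible(x)
}

#' Log-likelihood of a trajectory ensemble
#'
#' \deqn{\ell = \sum_{t,r,i} \big(S_{i,t} h_{i,t} - \log 2\cosh
#'       h_{i,t}\big), \qquad h_{i,t} = H_i + \sum_j J_{ij} S_{j,t-1}.}
#'
#' @param ens a `trajectory_ensemble`.
#' @param model an [ising_model].
#' @return The log-likelihood (a nonpositive number).
#' @export
log_likelihood <- function(ens, model) {
  d <- dim(ens)
  if (d[3] != model$N) stop("ensemble and model dimensions differ")
  R <- d[1]; Tp1 <- d[2]; N <- d[3]
  cur <- matrix(as.numeric(ens[, -1L, , drop = FALSE]), R * (Tp1 - 1L), N)
  prev <- matrix(as.numeric(ens[, -Tp1, , drop = FALSE]), R * (Tp1 - 1L), N)
  h <- sweep(prev %*% t(model$J), 2L, model$H, "+")
  sum(cur * h - log(2 * cosh(h)))
}

#' Learning configuration for the inverse Ising problem
#'
#' Gradient ascent uses effective step sizes `0.1` on the field-moment
#' mismatch and `1/sqrt(N)` on the coupling-moment mismatch (the `RT`
#' prefactor of the raw likelihood gradient is absorbed into the rates),
#' starting from `H = 0`, `J = 0`.
#'
#' @param method gradient estimator: `"exact"` or one of the mean-field
#'   methods accepted by [rollout()].
#' @param max_iter iteration cap.
#' @param grad_tol stop when the max-norm of the moment mismatch falls
#'   below this.
#' @param eta_H,eta_J effective learning rates (defaults as above;
#'   `eta_J = NULL` means `1/sqrt(N)` resolved at fit time).
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(method = "exact", max_iter = 10000L,
                            grad_tol = 1e-6, eta_H = 0.1, eta_J = NULL) {
  methods <- c("exact", "nmf", "tap", "plefka_t1", "plefka_t2",
               "plefka_tm1", "plefka2_t")
  method <- match.arg(method, methods)
  stopifnot(max_iter >= 1, grad_tol > 0, eta_H > 0,
            is.null(eta_J) || eta_J > 0)
  structure(list(method = method, max_iter = max_iter, grad_tol = grad_tol,
                 eta_H = eta_H, eta_J = eta_J), class = "learning_config")
}

#' Likelihood gradients (moment mismatches) for the current parameters
#'
#' Per pooled sample, the ascent directions are
#' \deqn{\partial_{H_i} \propto \langle S_{i,t}\rangle - m_i, \qquad
#'  \partial_{J_{il}} \propto \langle S_{i,t} S_{l,t-1}\rangle -
#'   (D_{il} + m_i \tilde m_l),}
#' where `(m, D)` are the model moments conditioned on the empirical
#' previous-step distribution. `method = "exact"` evaluates them exactly by
#' averaging \eqn{\tanh h_i} over the stored empirical states; the
#' mean-field methods compute them in one shot from the pooled empirical
#' moments \eqn{(\tilde m, \tilde C)} (and \eqn{\tilde D} for the pairwise
#' method), which makes the per-iteration cost independent of `R` and `T`.
#'
#' @param stats a [pool_statistics()] result.
#' @param model current parameter iterate.
#' @param method gradient estimator (see [learning_config()]).
#' @param opts,rule solver and quadrature settings for implicit methods.
#' @return List with `dH` (vector) and `dJ` (matrix).
#' @export
gradients <- function(stats, model, method = "exact",
                      opts = solver_options(), rule = gauss_hermite_rule()) {
  stopifnot(inherits(stats, "sufficient_statistics"), stats$N == model$N)
  if (method == "exact") {
    if (is.null(stats$prev_states))
      stop("exact gradients need pool_statistics(..., compress_states = TRUE)")
    S <- stats$prev_states
    w <- stats$prev_weights
    h <- sweep(S %*% t(model$J), 2L, model$H, "+")
    TH <- tanh(h)
    m <- drop(w %*% TH)
    model_cross <- crossprod(TH * w, S)          # <tanh h_i s~_l>
    dH <- stats$mean_s - m
    dJ <- stats$cross_lag - model_cross
    return(list(dH = dH, dJ = dJ))
  }
  mf <- switch(method,
    nmf = nmf_step(stats$prev_mean, model),
    tap = tap_step(stats$prev_mean, model, opts),
    plefka_t1 = plefka_t_first(stats$prev_mean, stats$prev_cov, model),
    plefka_t2 = plefka_t_second(stats$prev_mean, stats$prev_cov, model, opts),
    plefka_tm1 = plefka_tm1_step(stats$prev_mean, stats$prev_cov, model, rule),
    plefka2_t = {
      mem <- two_step_memory(m_prev = stats$prev_mean,
                             C_prev = stats$prev_cov,
                             D_prev = stats$prev_lag_cov,
                             m_prev2 = stats$prev_mean,
                             C_prev2 = stats$prev_cov)
      del <- plefka2_delayed(mem, model, opts)
      moment_state(NA_integer_, del$m, diag(1 - del$m^2, model$N), del$D)
    },
    stop("unknown gradient method: ", method))
  dH <- stats$mean_s - mf$m
  dJ <- stats$cross_lag - (mf$D + tcrossprod(mf$m, stats$prev_mean))
  list(dH = dH, dJ = dJ)
}

#' Fit a kinetic Ising model by (mean-field) Boltzmann learning
#'
#' Gradient ascent on the log-likelihood from `H = 0`, `J = 0`, using
#' [gradients()] with the configured estimator. Stops when the max-norm of
#' the moment mismatch drops below `grad_tol` or at `max_iter`.
#' Deterministic given the data and configuration.
#'
#' @param ens a `trajectory_ensemble`, or a precomputed
#'   [pool_statistics()] result.
#' @param config a [learning_config].
#' @param opts,rule solver and quadrature settings for implicit methods.
#' @return An [ising_model] with attributes `"iterations"` and
#'   `"grad_norms"` (max-norm trace, one entry per iteration).
#' @export
fit_kinetic_ising <- function(ens, config = learning_config(),
                              opts = solver_options(),
                              rule = gauss_hermite_rule()) {
  stats <- if (inherits(ens, "sufficient_statistics")) ens else
    pool_statistics(ens, compress_states = (config$method == "exact"))
  N <- stats$N
  eta_J <- if (is.null(config$eta_J)) 1 / sqrt(N) else config$eta_J
  H <- numeric(N)
  J <- matrix(0, N, N)
  gnorm <- numeric(config$max_iter)
  it <- 0L
  for (it in seq_len(config$max_iter)) {
    model <- ising_model(H, J)
    gr <- gradients(stats, model, config$method, opts, rule)
    gnorm[it] <- max(max(abs(gr$dH)), max(abs(gr$dJ)))
    if (!is.finite(gnorm[it])) stop("fit diverged at iteration ", it)
    if (gnorm[it] < config$grad_tol) break
    H <- H + config$eta_H * gr$dH
    J <- J + eta_J * gr$dJ
    if (!all(is.finite(H)) || !all(is.finite(J)))
      stop("fit diverged (non-finite parameters) at iteration ", it)
  }
  out <- ising_model(H, J)
  attr(out, "iterations") <- it
  attr(out, "grad_norms") <- gnorm[seq_len(it)]
  out
}

#' Squared-error metrics for inferred parameters
#'
#' \eqn{\epsilon_H = \langle (H^o_i - H^p_i)^2\rangle_i} and
#' \eqn{\epsilon_J = \langle (J^o_{ij} - J^p_{ij})^2\rangle_{ij}}.
#'
#' @param truth,fitted [ising_model]s on the same units.
#' @return Named vector `c(eps_H, eps_J)`.
#' @export
inverse_errors <- function(truth, fitted) {
  stopifnot(truth$N == fitted$N)
  c(eps_H = mean((truth$H - fitted$H)^2),
    eps_J = mean((truth$J - fitted$J)^2))
}
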