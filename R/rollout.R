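#' Recursive forward prediction of the moment dynamics
#'
#' Applies one of the mean-field steps `T` times from initial moments
#' `(m0, C0, D0)`, recording the predicted `(m_t, C_t, D_t)` at every
#' step. Methods that condition on the previous covariance propagate their
#' own `C_t` prediction into the next step; the pairwise method maintains
#' its two-step memory internally. The deterministic all-ones start used in
#' the forward experiments corresponds to `m0 = 1`, `C0 = 0`, `D0 = 0`.
#'
#' @param model an [ising_model].
#' @param method one of `"nmf"`, `"tap"`, `"plefka_t1"`, `"plefka_t2"`,
#'   `"plefka_tm1"`, `"plefka2_t"`.
#' @param m0 initial rates (default all ones).
#' @param C0,D0 initial covariances (default zero matrices).
#' @param T_steps number of steps.
#' @param opts a [solver_options] for implicit solves.
#' @param rule quadrature rule (Gaussian effective-field method only).
#' @return A [moment_series] over `t = 0..T`.
#' @export
rollout <- function(model,
                    method = c("nmf", "tap", "plefka_t1", "plefka_t2",
                               "plefka_tm1", "plefka2_t"),
                    m0 = rep(1, model$N), C0 = NULL, D0 = NULL,
                    T_steps = 128L, opts = solver_options(),
                    rule = gauss_hermite_rule()) {
  method <- match.arg(method)
  N <- model$N
  if (is.null(C0)) C0 <- matrix(0, N, N)
  if (is.null(D0)) D0 <- matrix(0, N, N)
  m0 <- check_rates(m0, N, "'m0'")
  if (method == "plefka2_t")
    return(plefka2_rollout(model, m0, C0, D0, T_steps, opts))
  ms <- empty_moment_series(N, T_steps)
  ms$m[1L, ] <- m0
  ms$C[, , 1L] <- C0
  ms$D[, , 1L] <- D0
  m <- m0; C <- C0
  for (t in seq_len(T_steps)) {
    st <- tryCatch(switch(method,
      nmf = nmf_step(m, model),
      tap = tap_step(m, model, opts),
      plefka_t1 = plefka_t_first(m, C, model),
      plefka_t2 = plefka_t_second(m, C, model, opts),
      plefka_tm1 = plefka_tm1_step(m, C, model, rule)),
      error = function(e)
        stop("rollout (", method, ") failed at t = ", t, ": ",
             conditionMessage(e)))
    m <- st$m; C <- st$C
    ms$m[t + 1L, ] <- m
    ms$C[, , t + 1L] <- C
    ms$D[, , t + 1L] <- st$D
  }
  ms
}

#' Forward prediction with the pairwise expansion
#'
#' Rollout of [plefka2_delayed()] (rates and delayed covariances) and
#' [plefka2_equal_time()] (equal-time covariances), carrying the two-step
#' memory `(m_{t-1}, m_{t-2}, C_{t-1}, C_{t-2}, D_{t-1})` across steps. At
#' the boundary step the conditioning parameter is
#' \eqn{\Theta^* = \mathrm{artanh}(m_0)} and the supplied `C0`, `D0` stand
#' in for the unavailable deeper history. The rates propagated forward are
#' the pair-averaged ones; the per-pair spread is recorded in the
#' `"m_spread"` attribute of the result (one value per step).
#'
#' @inheritParams rollout
#' @return A [moment_series] with attribute `"m_spread"`.
#' @export
plefka2_rollout <- function(model, m0 = rep(1, model$N), C0 = NULL,
                            D0 = NULL, T_steps = 128L,
                            opts = solver_options()) {
  N <- model$N
  if (is.null(C0)) C0 <- matrix(0, N, N)
  if (is.null(D0)) D0 <- matrix(0, N, N)
  m0 <- check_rates(m0, N, "'m0'")
  ms <- empty_moment_series(N, T_steps)
  ms$m[1L, ] <- m0
  ms$C[, , 1L] <- C0
  ms$D[, , 1L] <- D0
  mem <- two_step_memory(m0, C0, D0)
  spread <- numeric(T_steps)
  for (t in seq_len(T_steps)) {
    del <- tryCatch(plefka2_delayed(mem, model, opts),
      error = function(e)
        stop("plefka2 rollout failed at t = ", t, ": ", conditionMessage(e)))
    C_t <- plefka2_equal_time(mem$m_prev, mem$C_prev, model, opts)
    C_t <- with_unit_diag(unname(C_t), del$m)
    spread[t] <- del$m_spread
    ms$m[t + 1L, ] <- del$m
    ms$C[, , t + 1L] <- C_t
    ms$D[, , t + 1L] <- del$D
    mem <- two_step_memory(m_prev = del$m, C_prev = C_t, D_prev = del$D,
                           m_prev2 = mem$m_prev, C_prev2 = mem$C_prev)
  }
  attr(ms, "m_spread") <- spread
  ms
}
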