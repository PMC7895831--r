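#' Forward-problem method comparison over a temperature range
#'
#' For each `beta`, one disorder realization (shared across temperatures:
#' a unit-`beta` instance rescaled) is simulated from the all-ones start
#' and each requested mean-field rollout is scored against the ground
#' truth with [forward_errors()]. Ground truth is a sampled ensemble
#' (`R` trials, streaming moments) or exact enumeration when `N <= 8`.
#'
#' @param spec an [sk_spec]; `spec$beta` is ignored in favour of `betas`.
#' @param betas inverse temperatures to scan.
#' @param methods character vector of [rollout()] methods.
#' @param T_steps,R trajectory length and number of trials.
#' @param seed root seed (disorder and sampling streams derive from it).
#' @param ground_truth `"sampling"` or `"enumeration"`.
#' @return Data frame with columns `beta`, `method`, `eps_m`, `eps_C`,
#'   `eps_D`.
#' @export
compare_forward <- function(spec, betas, methods = c("nmf", "tap",
                              "plefka_t1", "plefka_t2", "plefka_tm1",
                              "plefka2_t"),
                            T_steps = 128L, R = 10000L, seed = 1L,
                            ground_truth = c("sampling", "enumeration")) {
  ground_truth <- match.arg(ground_truth)
  base <- sample_sk(sk_spec(spec$N, 1, spec$H0, spec$J0, spec$Jsigma), seed)
  s0 <- rep(1, spec$N)
  out <- list()
  for (b in seq_along(betas)) {
    model <- rescale_model(base, betas[b])
    ref <- if (ground_truth == "sampling") {
      simulate_moments(model, s0, T_steps, R, seed = seed + b)
    } else {
      check_enum_guard(spec$N, 8L, "enumeration ground truth")
      exact_moment_series(model, point_mass_distribution(s0), T_steps)
    }
    for (method in methods) {
      pred <- rollout(model, method, m0 = s0, T_steps = T_steps)
      err <- forward_errors(ref, pred)
      out[[length(out) + 1L]] <- data.frame(
        beta = betas[b], method = method, eps_m = err[["eps_m"]],
        eps_C = err[["eps_C"]], eps_D = err[["eps_D"]])
    }
  }
  do.call(rbind, out)
}

#' Inverse-problem method comparison over a temperature range
#'
#' For each `beta`, data are simulated from one disorder realization and
#' the parameters are re-inferred with each mean-field gradient estimator;
#' errors are [inverse_errors()] against the generating model.
#'
#' @inheritParams compare_forward
#' @param methods gradient estimators (see [learning_config()]).
#' @param max_iter,grad_tol learning loop controls.
#' @return Data frame with columns `beta`, `method`, `eps_H`, `eps_J`,
#'   `iterations`.
#' @export
compare_inverse <- function(spec, betas, methods = c("tap", "plefka_t2",
                              "plefka_tm1", "plefka2_t"),
                            T_steps = 128L, R = 10000L, seed = 1L,
                            max_iter = 10000L, grad_tol = 1e-6) {
  base <- sample_sk(sk_spec(spec$N, 1, spec$H0, spec$J0, spec$Jsigma), seed)
  s0 <- rep(1, spec$N)
  out <- list()
  for (b in seq_along(betas)) {
    model <- rescale_model(base, betas[b])
    stats <- simulate_pooled_statistics(model, s0, T_steps, R,
                                        seed = seed + b)
    for (method in methods) {
      cfg <- learning_config(method, max_iter = max_iter,
                             grad_tol = grad_tol)
      fitted <- fit_kinetic_ising(stats, cfg)
      err <- inverse_errors(model, fitted)
      out[[length(out) + 1L]] <- data.frame(
        beta = betas[b], method = method, eps_H = err[["eps_H"]],
        eps_J = err[["eps_J"]],
        iterations = attr(fitted, "iterations"))
    }
  }
  do.call(rbind, out)
}

#' Final-step fluctuations and entropy production across temperatures
#'
#' For each `beta`, runs the chosen forward solver for `T` steps from the
#' all-ones start and reports the mean off-diagonal equal-time covariance,
#' the mean delayed covariance and the entropy production
#' [entropy_production_mf()] at the final step. `method = "sampling"`
#' estimates the final-step moments from `R` simulated trials. The same
#' disorder realization (a unit-`beta` instance, or `base_model` if
#' given) is rescaled for every `beta`.
#'
#' @inheritParams compare_forward
#' @param method a [rollout()] method or `"sampling"`.
#' @param base_model optional [ising_model] taken as the unit-`beta`
#'   instance (e.g. a fitted model); defaults to a fresh SK sample.
#' @return Data frame with columns `beta`, `mean_C`, `mean_D`, `ep`,
#'   `method`.
#' @export
beta_scan <- function(spec, betas, method = "plefka2_t", T_steps = 128L,
                      R = 10000L, seed = 1L, base_model = NULL) {
  base <- if (is.null(base_model)) {
    sample_sk(sk_spec(spec$N, 1, spec$H0, spec$J0, spec$Jsigma), seed)
  } else base_model
  s0 <- rep(1, base$N)
  out <- vector("list", length(betas))
  for (b in seq_along(betas)) {
    model <- rescale_model(base, betas[b])
    if (method == "sampling") {
      st <- simulate_moments(model, s0, T_steps, R, seed = seed + b,
                             final_only = TRUE)
      C_f <- st$C; D_f <- st$D
    } else {
      ms <- rollout(model, method, m0 = s0, T_steps = T_steps)
      C_f <- ms$C[, , T_steps + 1L]
      D_f <- ms$D[, , T_steps + 1L]
    }
    out[[b]] <- data.frame(beta = betas[b],
                           mean_C = mean(offdiag(C_f)),
                           mean_D = mean(D_f),
                           ep = entropy_production_mf(model, D_f),
                           method = method)
  }
  do.call(rbind, out)
}

#' Reconstruct the phase transition from data sampled at one temperature
#'
#' Fits `(H, J)` from trajectories simulated at `spec$beta` (typically the
#' critical point), then rescales the fitted parameters by each fictitious
#' inverse temperature and reruns [beta_scan()] on them. A faithful
#' reconstruction places the fluctuation and entropy-production maxima of
#' the rescaled model family near the rescaling factor 1 times the
#' original `beta`.
#'
#' @inheritParams beta_scan
#' @param betas_tilde fictitious inverse temperatures (multiples of 1).
#' @param fit_method gradient estimator for the inverse step.
#' @param scan_method forward solver for the rescaled scans.
#' @param max_iter,grad_tol learning loop controls.
#' @return Data frame as [beta_scan()], with `beta` holding `beta_tilde`.
#' @export
reconstruction_experiment <- function(spec, betas_tilde,
                                      fit_method = "plefka2_t",
                                      scan_method = "plefka2_t",
                                      T_steps = 128L, R = 10000L, seed = 1L,
                                      max_iter = 10000L, grad_tol = 1e-6) {
  truth <- sample_sk(spec, seed)
  s0 <- rep(1, spec$N)
  stats <- if (fit_method == "exact") {
    pool_statistics(sample_trajectories(truth, s0, T_steps, R, seed + 1L))
  } else {
    simulate_pooled_statistics(truth, s0, T_steps, R, seed = seed + 1L)
  }
  fitted <- fit_kinetic_ising(stats, learning_config(fit_method,
                                                     max_iter = max_iter,
                                                     grad_tol = grad_tol))
  beta_scan(spec, betas_tilde, method = scan_method, T_steps = T_steps,
            R = R, seed = seed + 2L, base_model = fitted)
}
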