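#' Sample an asymmetric SK model instance
#'
#' Draws one realization of the disorder ensemble described by [sk_spec()]:
#' `H` i.i.d. uniform on `[-beta * H0, beta * H0]` and `J` i.i.d. Gaussian
#' with mean `beta * J0 / N` and variance `beta^2 * Jsigma^2 / N`. No
#' symmetrization is applied, and the diagonal is sampled like any other
#' entry (set `self_coupling = FALSE` to zero it). Deterministic per seed.
#'
#' Because `beta` multiplies the sampled parameters, rescaling a `beta = 1`
#' instance with [rescale_model()] is distributionally identical to
#' sampling at that `beta`; pinning one unit-`beta` instance and deriving
#' all temperatures by rescaling keeps the disorder shared across a
#' temperature scan.
#'
#' @param spec an [sk_spec].
#' @param seed integer seed.
#' @param self_coupling sample the diagonal of `J` (default `TRUE`).
#' @return An [ising_model].
#' @export
sample_sk <- function(spec, seed = 1L, self_coupling = TRUE) {
  stopifnot(inherits(spec, "sk_spec"))
  N <- spec$N
  set.seed(seed)
  H <- stats::runif(N, -spec$beta * spec$H0, spec$beta * spec$H0)
  J <- matrix(stats::rnorm(N * N, mean = spec$beta * spec$J0 / N,
                           sd = spec$beta * spec$Jsigma / sqrt(N)), N, N)
  if (spec$beta == 0) { H <- numeric(N); J <- matrix(0, N, N) }
  if (!self_coupling) diag(J) <- 0
  ising_model(H, J)
}

#' Rescale model parameters by a fictitious inverse temperature
#'
#' Returns the model with `(beta_tilde * H, beta_tilde * J)`. Used to probe
#' a fitted model's sensitivity by scanning the rescaling factor.
#'
#' @param model an [ising_model].
#' @param beta_tilde nonnegative scale factor.
#' @return An [ising_model].
#' @export
rescale_model <- function(model, beta_tilde) {
  stopifnot(beta_tilde >= 0)
  ising_model(beta_tilde * model$H, beta_tilde * model$J)
}
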