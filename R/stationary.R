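#' Specification of the asymmetric SK ensemble
#'
#' The disorder ensemble used throughout the comparison experiments:
#' fields \eqn{H_i \sim U(-\beta H_0, \beta H_0)} and couplings
#' \eqn{J_{ij} \sim N(\beta J_0 / N, \beta^2 J_\sigma^2 / N)} with no
#' symmetrization (the kinetic analogue of the Sherrington-Kirkpatrick
#' model with fully asymmetric couplings). Defaults `H0 = 0.5`, `J0 = 1`,
#' `Jsigma = 0.1` place the ensemble near a ferromagnetic transition at
#' `beta` near 1.11.
#'
#' @param N system size.
#' @param beta inverse temperature (scales both fields and couplings).
#' @param H0 field half-width scale.
#' @param J0 coupling mean scale.
#' @param Jsigma coupling standard-deviation scale.
#' @return An object of class `sk_spec`.
#' @export
sk_spec <- function(N, beta = 1, H0 = 0.5, J0 = 1, Jsigma = 0.1) {
  stopifnot(N >= 1, beta >= 0, H0 >= 0, Jsigma >= 0)
  structure(list(N = as.integer(N), beta = beta, H0 = H0, J0 = J0,
                 Jsigma = Jsigma), class = "sk_spec")
}

# nested disorder quadrature: outer Gauss-Legendre over the uniform field,
# inner Gauss-Hermite over Gaussian variables; returns <f(H + sd * z)>
disorder_average <- function(f, beta, H0, sd, n_field = 64L,
                             rule = gauss_hermite_rule()) {
  if (H0 > 0) {
    gl <- pracma::gaussLegendre(n_field, -beta * H0, beta * H0)
    Hn <- gl$x; Hw <- gl$w / (2 * beta * H0)
  } else {
    Hn <- 0; Hw <- 1
  }
  if (sd > 0) {
    arg <- outer(Hn, sd * rule$z, "+")
    sum(Hw * drop(f(arg) %*% rule$w))
  } else {
    sum(Hw * f(Hn))
  }
}

#' Stationary mean-field solution of the asymmetric SK ensemble
#'
#' Solves the coupled self-consistency for the population-average
#' magnetization \eqn{\bar m} and its square \eqn{q} in the thermodynamic
#' limit. Each unit sees a Gaussian effective field with mean
#' \eqn{H + \beta J_0 \bar m}, a quenched component of variance
#' \eqn{\beta^2 J_\sigma^2 q} (frozen coupling disorder acting on
#' magnetized units) and a dynamic component of variance
#' \eqn{\beta^2 J_\sigma^2 (1 - q)} (fluctuating inputs):
#' \deqn{\bar m = \Big\langle \int \mathrm{D}z \int \mathrm{D}x
#'   \tanh\big(H + \beta J_0 \bar m + \beta J_\sigma \sqrt{q}\, z +
#'   \beta J_\sigma \sqrt{1 - q}\, x\big) \Big\rangle_H,}
#' \deqn{q = \Big\langle \int \mathrm{D}z \Big[\int \mathrm{D}x
#'   \tanh(\cdot)\Big]^2 \Big\rangle_H,}
#' with \eqn{H \sim U(-\beta H_0, \beta H_0)}. Damped fixed-point
#' iteration from a positive initial magnetization returns the stable
#' ordered solution where one exists and \eqn{\bar m = 0} otherwise.
#'
#' @param spec an [sk_spec] (`N` is irrelevant; the solution is the
#'   thermodynamic limit).
#' @param tol fixed-point tolerance.
#' @param max_iter iteration cap.
#' @param n_field Gauss-Legendre nodes for the field-disorder average.
#' @param rule Gauss-Hermite rule for the Gaussian integrals.
#' @return List with `m_bar`, `q` and `Delta` (the dynamic field variance
#'   \eqn{\beta^2 J_\sigma^2 (1 - q)}).
#' @export
stationary_mf <- function(spec, tol = 1e-12, max_iter = 5000L,
                          n_field = 64L, rule = gauss_hermite_rule()) {
  stopifnot(inherits(spec, "sk_spec"))
  beta <- spec$beta
  if (beta == 0)
    return(list(m_bar = 0, q = 0, Delta = 0))
  bJs <- beta * spec$Jsigma
  if (spec$H0 > 0) {
    gl <- pracma::gaussLegendre(n_field, -beta * spec$H0, beta * spec$H0)
    Hn <- gl$x; Hw <- gl$w / (2 * beta * spec$H0)
  } else {
    Hn <- 0; Hw <- 1
  }
  inner_moments <- function(m_bar, q) {
    # inner integral over the dynamic noise x for each (H, z) node pair,
    # then z-average of the value and of its square
    mu0 <- Hn + beta * spec$J0 * m_bar
    if (bJs == 0) {
      v <- tanh(mu0)
      return(list(m = sum(Hw * v), q = sum(Hw * v^2)))
    }
    sq <- bJs * sqrt(max(q, 0))
    sd_dyn <- bJs * sqrt(max(1 - q, 0))
    mu <- outer(mu0, sq * rule$z, "+")          # field x z nodes
    if (sd_dyn > 0) {
      g <- matrix(0, length(Hn), length(rule$z))
      for (p in seq_along(rule$z))
        g <- g + rule$w[p] * tanh(mu + sd_dyn * rule$z[p])
    } else {
      g <- tanh(mu)
    }
    list(m = sum(Hw * drop(g %*% rule$w)),
         q = sum(Hw * drop(g^2 %*% rule$w)))
  }
  m_bar <- 0.9; q <- 0.9
  damp <- 0.5
  for (it in seq_len(max_iter)) {
    mo <- inner_moments(m_bar, q)
    m_new <- (1 - damp) * mo$m + damp * m_bar
    q_new <- (1 - damp) * mo$q + damp * q
    if (max(abs(m_new - m_bar), abs(q_new - q)) < tol) {
      m_bar <- m_new; q <- q_new
      return(list(m_bar = m_bar, q = q,
                  Delta = bJs^2 * (1 - q)))
    }
    m_bar <- m_new; q <- q_new
  }
  stop("stationary_mf: no convergence after ", max_iter, " iterations")
}

#' Critical inverse temperature of the stationary ferromagnetic transition
#'
#' Locates the `beta` at which the zero-magnetization stationary solution
#' loses stability. Linearizing the \eqn{\bar m} equation of
#' [stationary_mf()] at \eqn{\bar m = 0}, where the quenched and dynamic
#' Gaussian components combine to total variance \eqn{\beta^2 J_\sigma^2},
#' the instability condition is
#' \deqn{\beta J_0 \big\langle \int \mathrm{D}w\,
#'   \mathrm{sech}^2(H + \beta J_\sigma w) \big\rangle_H = 1,}
#' solved for `beta` by bracketed root finding. With `H0 = 0` and
#' `Jsigma = 0` this reduces to the Curie-Weiss condition
#' \eqn{\beta J_0 = 1}; the default disorder (`H0 = 0.5`,
#' `Jsigma = 0.1`) shifts the transition to `beta` of about 1.1108.
#'
#' @param H0,J0,Jsigma ensemble scales (see [sk_spec()]); `J0 > 0`.
#' @param interval search bracket for `beta`.
#' @param tol root tolerance.
#' @param n_field,rule disorder quadrature settings.
#' @return The critical inverse temperature.
#' @examples
#' critical_beta(H0 = 0, Jsigma = 0)    # 1 exactly (Curie-Weiss)
#' critical_beta()                      # about 1.1108
#' @export
critical_beta <- function(H0 = 0.5, J0 = 1, Jsigma = 0.1,
                          interval = c(0.05, 20), tol = 1e-10,
                          n_field = 64L, rule = gauss_hermite_rule()) {
  stopifnot(J0 > 0, H0 >= 0, Jsigma >= 0)
  slope <- function(beta)
    beta * J0 * disorder_average(function(x) 1 / cosh(x)^2,
                                 beta, H0, beta * Jsigma,
                                 n_field = n_field, rule = rule)
  f <- function(beta) slope(beta) - 1
  if (f(interval[1]) > 0 || f(interval[2]) < 0)
    stop("critical_beta: instability condition not bracketed on ",
         "[", interval[1], ", ", interval[2], "]")
  stats::uniroot(f, interval, tol = tol)$root
}
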