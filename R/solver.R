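#' Solver options for self-consistent mean-field equations
#'
#' The TAP-type and pairwise equations place the unknown inside a `tanh` on
#' their own right-hand side; they are solved by fixed-point iteration with
#' optional damping and a guarded bisection fallback.
#'
#' @param tol fixed-point residual tolerance.
#' @param max_iter maximum iterations per solve.
#' @param damping damping factor in `[0, 1)` for the plain iteration
#'   (`x <- (1 - damping) * g(x) + damping * x`); `0` is undamped, `0.5` is
#'   used automatically on retry after a failed plain pass.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(tol = 1e-12, max_iter = 200L, damping = 0) {
  stopifnot(tol > 0, max_iter >= 1, damping >= 0, damping < 1)
  structure(list(tol = tol, max_iter = max_iter, damping = damping),
            class = "solver_options")
}

# Vectorized solve of x = a - b * tanh(x), elementwise over a, b (matrices
# or vectors of equal shape). Monotone in x for b > -1, hence a unique root
# bracketed by a -/+ |b|. Fixed-point iteration (contraction factor <= |b|)
# with damped retry; any stragglers go to elementwise bisection, which
# always terminates.
solve_theta_core <- function(a, b, opts = solver_options()) {
  g <- function(x) a - b * tanh(x)
  run <- function(x, damping) {
    for (it in seq_len(opts$max_iter)) {
      x_new <- (1 - damping) * g(x) + damping * x
      if (max(abs(x_new - x)) < opts$tol) return(list(x = x_new, ok = TRUE))
      x <- x_new
    }
    list(x = x, ok = FALSE)
  }
  res <- run(a, opts$damping)
  if (!res$ok) res <- run(res$x, max(opts$damping, 0.5))
  x <- res$x
  resid <- abs(x - g(x))
  bad <- resid >= opts$tol
  if (any(bad)) {
    ab <- a[bad]; bb <- b[bad]
    lo <- ab - abs(bb) - 1; hi <- ab + abs(bb) + 1
    f <- function(x) x + bb * tanh(x) - ab
    if (any(f(lo) > 0 | f(hi) < 0))
      stop("self-consistent solve failed: root not bracketed (b <= -1?), ",
           "max residual ", format(max(resid)))
    for (it in seq_len(200L)) {
      mid <- (lo + hi) / 2
      pos <- f(mid) > 0
      hi[pos] <- mid[pos]
      lo[!pos] <- mid[!pos]
      if (max(hi - lo) < opts$tol) break
    }
    x[bad] <- (lo + hi) / 2
  }
  x
}

#' Solve the scalar self-consistent equation x = a - b tanh(x)
#'
#' Workhorse for all implicit mean-field updates. For `b > -1` the equation
#' is strictly monotone in `x` and has a unique root; it is located by
#' damped fixed-point iteration with a bracketed bisection fallback.
#'
#' @param a,b finite real coefficients.
#' @param opts a [solver_options].
#' @return The root, to residual below `opts$tol`.
#' @examples
#' solve_theta_scalar(1, 0.5)  # root of x + 0.5 tanh(x) = 1
#' @export
solve_theta_scalar <- function(a, b, opts = solver_options()) {
  stopifnot(is.finite(a), is.finite(b))
  solve_theta_core(a, b, opts)
}
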