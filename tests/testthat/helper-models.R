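# shared fixtures, built in code

# a small random model with couplings of a given typical scale
random_model <- function(N, h_scale = 0.5, j_scale = 0.3, seed = 1) {
  set.seed(seed)
  ising_model(runif(N, -h_scale, h_scale),
              matrix(rnorm(N * N, 0, j_scale / sqrt(N)), N, N))
}

# one disorder draw of the near-critical asymmetric SK ensemble
near_critical_model <- function(N, seed = 1, beta = 1.11084)
  sample_sk(sk_spec(N, beta), seed = seed)

# exact chained previous-step statistics: start from an independent
# distribution with rates m0, take one exact step, and return everything a
# method needs to predict step two (plus the exact step-two target)
chained_setup <- function(model, m0) {
  p0 <- independent_distribution(m0)
  ex1 <- exact_moments(model, p0)
  p1 <- evolve_exact(model, p0, 1L)[[2L]]
  list(m0 = m0, p1 = p1, m1 = ex1$m, C1 = ex1$C, D1 = ex1$D,
       target = exact_moments(model, p1))
}

set_unit_diag <- function(C, m) {
  diag(C) <- 1 - m^2
  C
}

expect_moment_close <- function(st, ref, tol, label = "") {
  expect_lt(max(abs(st$m - ref$m)), tol, label = paste(label, "m"))
  expect_lt(max(abs(st$C - ref$C)), tol, label = paste(label, "C"))
  expect_lt(max(abs(st$D - ref$D)), tol, label = paste(label, "D"))
}
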