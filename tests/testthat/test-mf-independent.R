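test_that("scalar self-consistent solver matches bracketed bisection", {
  expect_equal(solve_theta_scalar(2.3, 0), 2.3)
  expect_equal(solve_theta_scalar(0, 0.7), 0)
  # oracle: high-precision bisection on x + 0.5 tanh(x) - 1
  f <- function(x) x + 0.5 * tanh(x) - 1
  lo <- 0; hi <- 2
  for (i in 1:60) { mid <- (lo + hi) / 2; if (f(mid) > 0) hi <- mid else lo <- mid }
  expect_equal(solve_theta_scalar(1, 0.5), (lo + hi) / 2, tolerance = 1e-11)
  # negative b below the monotonicity bound still has the bracketed root
  expect_equal(solve_theta_scalar(0.4, -0.9),
               uniroot(function(x) x - 0.9 * tanh(x) - 0.4, c(-2, 4),
                       tol = 1e-13)$root, tolerance = 1e-10)
})

test_that("naive mean field has its closed-form limits", {
  N <- 4
  mod0 <- ising_model(c(0.4, -0.2, 0.1, 0), matrix(0, N, N))
  st <- nmf_step(rep(0.3, N), mod0)
  expect_equal(st$m, tanh(mod0$H))
  expect_true(all(st$D == 0))
  mod <- random_model(N, seed = 2)
  st2 <- nmf_step(rep(0, N), ising_model(rep(0, N), mod$J))
  expect_equal(st2$m, rep(0, N))
  expect_equal(st2$D, mod$J)            # all variance factors are one
})

test_that("TAP reduces to nMF without couplings and subtracts a reaction term", {
  N <- 5
  mod0 <- ising_model(runif(N, -1, 1), matrix(0, N, N))
  expect_moment_close(tap_step(rep(0.2, N), mod0), nmf_step(rep(0.2, N), mod0),
                      1e-12, "J=0")
  # Onsager correction lowers positive rates when m_prev = 0
  set.seed(6)
  mod <- ising_model(rep(0.8, N), matrix(rnorm(N * N, 0, 0.4), N, N))
  expect_true(all(tap_step(rep(0, N), mod)$m <= nmf_step(rep(0, N), mod)$m))
})

test_that("TAP beats nMF against the oracle at moderate coupling", {
  errs <- sapply(1:100, function(r) {
    mod <- near_critical_model(4, seed = 1000 + r)
    set.seed(r); mp <- runif(4, -0.6, 0.6)
    ex <- exact_moments(mod, independent_distribution(mp))
    c(nmf = max(abs(nmf_step(mp, mod)$m - ex$m)),
      tap = max(abs(tap_step(mp, mod)$m - ex$m)))
  })
  expect_lt(mean(errs["tap", ]), mean(errs["nmf", ]))
})

test_that("correlation-conditioned first order propagates C_prev into D", {
  N <- 4
  mod <- near_critical_model(N, seed = 3)
  mp <- runif(N, -0.5, 0.5)
  expect_true(all(plefka_t_first(mp, matrix(0, N, N), mod)$D == 0))
  # independent-model covariance reduces to the nMF delayed covariance
  st <- plefka_t_first(mp, diag(1 - mp^2), mod)
  expect_equal(st$D, nmf_step(mp, mod)$D, tolerance = 1e-14)
  # fed the exact previous covariance, D improves on the nMF value on
  # average over disorder realizations
  errs <- sapply(1:30, function(r) {
    modr <- near_critical_model(4, seed = 600 + r)
    set.seed(r)
    cs <- chained_setup(modr, runif(4, -0.6, 0.6))
    c(nmf = max(abs(nmf_step(cs$m1, modr)$D - cs$target$D)),
      t1 = max(abs(plefka_t_first(cs$m1, cs$C1, modr)$D - cs$target$D)))
  })
  expect_lt(mean(errs["t1", ]), mean(errs["nmf", ]))
})

test_that("correlation-conditioned second order reduces exactly to TAP", {
  for (r in 1:20) {
    mod <- near_critical_model(4, seed = 300 + r)
    set.seed(r); mp <- runif(4, -0.8, 0.8)
    expect_moment_close(plefka_t_second(mp, diag(1 - mp^2), mod),
                        tap_step(mp, mod), 1e-10, "reduction")
  }
  # C_prev = 0 kills every correction
  mod <- near_critical_model(4, seed = 5)
  mp <- runif(4, -0.5, 0.5)
  st <- plefka_t_second(mp, matrix(0, 4, 4), mod)
  expect_equal(st$m, tanh(mod$H + drop(mod$J %*% mp)), tolerance = 1e-12)
  expect_true(all(offdiag(st$C) == 0) && all(st$D == 0))
})

test_that("second order in C_prev beats TAP on equal-time correlations", {
  # moderate zero-mean couplings: within mean-field validity at N = 4 (the
  # near-critical SK mean coupling beta * J0 / N is itself order one there)
  errs <- sapply(1:50, function(r) {
    mod <- random_model(4, j_scale = 0.5, seed = 700 + r)
    set.seed(r)
    cs <- chained_setup(mod, runif(4, -0.6, 0.6))
    c(tap = mean((tap_step(cs$m1, mod)$C - cs$target$C)^2),
      t2 = mean((plefka_t_second(cs$m1, cs$C1, mod)$C - cs$target$C)^2))
  })
  expect_lt(mean(errs["t2", ]), mean(errs["tap", ]))
})

test_that("rollout composes steps and keeps rates strictly inside (-1, 1)", {
  mod <- near_critical_model(6, seed = 9)
  ms <- rollout(mod, "tap", T_steps = 10)
  st <- moment_state(0, rep(1, 6), matrix(0, 6, 6), matrix(0, 6, 6))
  for (t in 1:10) st <- tap_step(st$m, mod)
  expect_equal(ms$m[11, ], st$m, tolerance = 1e-14)
  expect_true(all(abs(ms$m[-1, ]) < 1))
  # no couplings: constant at tanh(H) from the first step on
  mod0 <- ising_model(c(0.5, -0.3), matrix(0, 2, 2))
  ms0 <- rollout(mod0, "nmf", T_steps = 5)
  expect_equal(ms0$m[-1, ], matrix(tanh(mod0$H), 5, 2, byrow = TRUE),
               tolerance = 1e-14)
})
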