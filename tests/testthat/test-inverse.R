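make_ens <- function(data, R, Tp1, N) {
  structure(array(data, c(R, Tp1, N)), seed = 0L, params_id = "test",
            class = c("trajectory_ensemble", "array"))
}

test_that("pooled statistics have their degenerate and single-step limits", {
  # all-ones data
  ens1 <- make_ens(1, 20, 4, 3)
  st <- pool_statistics(ens1)
  expect_equal(st$mean_s, rep(1, 3))
  expect_equal(st$cross_lag, matrix(1, 3, 3))
  expect_true(all(st$prev_cov == 0))
  # fair-coin i.i.d. data
  set.seed(2)
  R <- 600; Tp1 <- 11; N <- 4
  ens <- make_ens(sample(c(-1, 1), R * Tp1 * N, TRUE), R, Tp1, N)
  st2 <- pool_statistics(ens)
  RT <- R * (Tp1 - 1)
  expect_lt(max(abs(st2$mean_s)), 5 / sqrt(RT))
  expect_lt(max(abs(st2$cross_lag)), 5 / sqrt(RT))
  expect_lt(max(abs(st2$prev_cov - diag(N))), 5 / sqrt(RT) + 1e-3)
  # pooling a single transition equals the per-step empirical moments
  mod <- random_model(3, seed = 5)
  e <- sample_trajectories(mod, rep(1, 3), 1, 500, seed = 9)
  em <- empirical_moments(e)
  sp <- pool_statistics(e)
  expect_equal(sp$mean_s, em$m[2, ])
  expect_equal(sp$cross_lag - tcrossprod(em$m[2, ], em$m[1, ]), em$D[, , 2],
               tolerance = 1e-12)
})

test_that("streamed pooling matches ensemble pooling", {
  mod <- random_model(4, j_scale = 0.6, seed = 3)
  ens <- sample_trajectories(mod, rep(1, 4), 6, 300, seed = 4)
  a <- pool_statistics(ens, compress_states = FALSE)
  b <- simulate_pooled_statistics(mod, rep(1, 4), 6, 300, seed = 4)
  for (f in c("mean_s", "cross_lag", "prev_mean", "prev_cov", "prev_lag_cov"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12, label = f)
})

test_that("log-likelihood matches direct per-term summation", {
  mod0 <- ising_model(rep(0, 2), matrix(0, 2, 2))
  ens <- make_ens(sample(c(-1, 1), 5 * 4 * 2, TRUE), 5, 4, 2)
  expect_equal(log_likelihood(ens, mod0), -5 * 3 * 2 * log(2))
  # hand loop oracle on a small random model
  mod <- random_model(2, seed = 6)
  ll <- 0
  for (r in 1:5) for (t in 2:4) for (i in 1:2) {
    h <- mod$H[i] + sum(mod$J[i, ] * ens[r, t - 1, ])
    ll <- ll + ens[r, t, i] * h - log(2 * cosh(h))
  }
  expect_equal(log_likelihood(ens, mod), ll, tolerance = 1e-10)
  # invariant to permuting trials
  perm <- make_ens(ens[c(3, 1, 5, 2, 4), , ], 5, 4, 2)
  expect_equal(log_likelihood(perm, mod), log_likelihood(ens, mod))
})

test_that("exact gradients equal finite differences of the likelihood", {
  mod_true <- random_model(3, j_scale = 0.8, seed = 7)
  ens <- sample_trajectories(mod_true, rep(1, 3), 5, 200, seed = 8)
  stats <- pool_statistics(ens)
  mod <- random_model(3, j_scale = 0.5, seed = 9)
  gr <- gradients(stats, mod, "exact")
  RT <- stats$RT
  eps <- 1e-5
  for (i in 1:3) {
    Hp <- mod$H; Hp[i] <- Hp[i] + eps
    Hm <- mod$H; Hm[i] <- Hm[i] - eps
    fd <- (log_likelihood(ens, ising_model(Hp, mod$J)) -
           log_likelihood(ens, ising_model(Hm, mod$J))) / (2 * eps)
    expect_equal(RT * gr$dH[i], fd, tolerance = 1e-4)
  }
  for (idx in list(c(1, 2), c(3, 1))) {
    Jp <- mod$J; Jp[idx[1], idx[2]] <- Jp[idx[1], idx[2]] + eps
    Jm <- mod$J; Jm[idx[1], idx[2]] <- Jm[idx[1], idx[2]] - eps
    fd <- (log_likelihood(ens, ising_model(mod$H, Jp)) -
           log_likelihood(ens, ising_model(mod$H, Jm))) / (2 * eps)
    expect_equal(RT * gr$dJ[idx[1], idx[2]], fd, tolerance = 1e-4)
  }
})

test_that("mean-field gradients converge to the exact ones at weak coupling", {
  mod_true <- random_model(4, j_scale = 0.5, seed = 10)
  ens <- sample_trajectories(mod_true, rep(1, 4), 8, 400, seed = 11)
  stats <- pool_statistics(ens)
  base <- random_model(4, j_scale = 1, seed = 12)
  dev <- sapply(c(0.2, 0.1, 0.05), function(eps) {
    mod <- ising_model(base$H, base$J * eps)
    ex <- gradients(stats, mod, "exact")
    mf <- gradients(stats, mod, "plefka_t2")
    max(max(abs(ex$dJ - mf$dJ)), max(abs(ex$dH - mf$dH)))
  })
  expect_true(all(diff(dev) < 0))
  slope <- coef(lm(log(dev) ~ log(c(0.2, 0.1, 0.05))))[2]
  expect_gt(slope, 1.5)               # deviation is O(J^2)
})

test_that("learning recovers an uncoupled model from its own data", {
  mod_true <- ising_model(c(0.6, -0.4, 0.2), matrix(0, 3, 3))
  ens <- sample_trajectories(mod_true, rep(1, 3), 20, 2000, seed = 13)
  fit <- fit_kinetic_ising(ens, learning_config("exact", grad_tol = 1e-9))
  stats <- pool_statistics(ens)
  # the free couplings absorb a little sampling noise, so the fitted fields
  # match the pooled-rate projection only up to that slack
  expect_equal(fit$H, atanh(stats$mean_s), tolerance = 0.05)
  expect_lt(max(abs(fit$J)), 0.05)
  # gradient vanishes at the recovered parameters
  gr <- gradients(stats, fit, "exact")
  expect_lt(max(abs(gr$dH)), 1e-8)
})

test_that("coupling error decreases with the number of trials", {
  mod_true <- sample_sk(sk_spec(10, 0.8 * 1.11084), seed = 15)
  errs <- sapply(c(500, 5000, 50000), function(R) {
    stats <- simulate_pooled_statistics(mod_true, rep(1, 10), 64, R, seed = 16)
    fit <- fit_kinetic_ising(stats, learning_config("plefka_t2",
                                                    max_iter = 4000,
                                                    grad_tol = 1e-7))
    inverse_errors(mod_true, fit)[["eps_J"]]
  })
  expect_true(all(diff(errs) < 0))
})
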