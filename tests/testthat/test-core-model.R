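test_that("conditional activation matches the logistic closed form", {
  N <- 3
  m0 <- ising_model(rep(0, N), matrix(0, N, N))
  expect_equal(conditional_activation(c(1, -1, 1), m0), rep(0.5, N))

  m2 <- ising_model(c(0, 0), matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  p <- conditional_activation(c(1, 1), m2)
  expect_equal(p[1], exp(1) / (exp(1) + exp(-1)), tolerance = 1e-12)
  expect_equal(p[2], 0.5)

  # negating fields and the previous state flips every probability
  mod <- random_model(4, seed = 3)
  prev <- c(1, -1, -1, 1)
  neg <- ising_model(-mod$H, mod$J)
  expect_equal(conditional_activation(prev, mod),
               1 - conditional_activation(-prev, neg), tolerance = 1e-14)

  expect_error(conditional_activation(c(1, 1), m0), "length")
  expect_error(conditional_activation(c(1, 0, 1), m0), "-1/\\+1")
})

test_that("model constructor validates its inputs", {
  expect_error(ising_model(c(0, 0), matrix(0, 3, 3)), "matching")
  expect_error(ising_model(c(0, Inf), matrix(0, 2, 2)), "finite")
})

test_that("sampler is seed-deterministic and respects strong fields", {
  mod <- ising_model(rep(10, 3), matrix(0, 3, 3))
  ens <- sample_trajectories(mod, rep(-1, 3), T_steps = 3, R = 10000, seed = 5)
  expect_identical(dim(ens), c(10000L, 4L, 3L))
  expect_true(all(ens[, 1, ] == -1))
  expect_gt(mean(ens[, 2:4, ] == 1), 0.9999)

  ens2 <- sample_trajectories(mod, rep(-1, 3), T_steps = 3, R = 10000, seed = 5)
  expect_identical(ens, ens2)
  expect_error(sample_trajectories(mod, c(0, 1, 1), 2, 2), "-1/\\+1")
})

test_that("empirical moments agree with enumeration within sampling error", {
  mod <- random_model(3, j_scale = 0.8, seed = 11)
  Rtrials <- 40000
  ens <- sample_trajectories(mod, rep(1, 3), T_steps = 4, R = Rtrials, seed = 2)
  em <- empirical_moments(ens)
  exs <- exact_moment_series(mod, point_mass_distribution(rep(1, 3)), 4)
  for (t in 1:4) {
    se <- sqrt((1 - exs$m[t + 1, ]^2) / Rtrials)
    expect_true(all(abs(em$m[t + 1, ] - exs$m[t + 1, ]) < 4 * se + 1e-12))
    expect_lt(max(abs(em$C[, , t + 1] - exs$C[, , t + 1])), 5 / sqrt(Rtrials))
    expect_lt(max(abs(em$D[, , t + 1] - exs$D[, , t + 1])), 5 / sqrt(Rtrials))
  }
  # degenerate all-ones data: unit rates, zero covariance
  modp <- ising_model(rep(20, 2), matrix(0, 2, 2))
  ep <- empirical_moments(sample_trajectories(modp, c(1, 1), 2, 50, seed = 1))
  expect_equal(ep$m, matrix(1, 3, 2))
  expect_true(all(ep$C == 0) && all(ep$D == 0))
})

test_that("sampling error contracts toward the oracle as trials grow", {
  mod <- random_model(4, j_scale = 0.6, seed = 7)
  ex <- exact_moment_series(mod, point_mass_distribution(rep(1, 4)), 2)
  errs <- sapply(c(1e3, 1e4, 1e5), function(R) {
    em <- empirical_moments(sample_trajectories(mod, rep(1, 4), 2, R, seed = 3))
    max(abs(em$m[3, ] - ex$m[3, ]))
  })
  expect_lt(errs[3], errs[1])          # O(1/sqrt(R)) contraction
  expect_lt(errs[3], 5 / sqrt(1e5))
})

test_that("exact evolution is normalized and factorizes without couplings", {
  mod <- ising_model(c(0.3, -0.2, 0.5), matrix(0, 3, 3))
  ps <- evolve_exact(mod, point_mass_distribution(c(1, 1, -1)), 3)
  S <- state_matrix(3)
  indep <- apply((1 + S * rep(tanh(mod$H), each = 8)) / 2, 1, prod)
  for (t in 2:4) {
    expect_equal(sum(ps[[t]]$p), 1, tolerance = 1e-12)
    expect_equal(ps[[t]]$p, indep, tolerance = 1e-12)
  }
  # transition rows sum to one for every previous state (exhaustive, N = 6)
  mod6 <- random_model(6, j_scale = 1, seed = 9)
  expect_equal(rowSums(transition_matrix(mod6)), rep(1, 64), tolerance = 1e-12)
  expect_error(evolve_exact(random_model(2), point_mass_distribution(c(1, 1, 1)), 1))
})

test_that("two-unit hand-computed distribution is reproduced", {
  mod <- ising_model(c(0, 0), matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  p1 <- evolve_exact(mod, point_mass_distribution(c(1, 1)), 1)[[2]]$p
  pe <- exp(1) / (exp(1) + exp(-1))  # both units see field +1
  expect_equal(p1, c((1 - pe)^2, pe * (1 - pe), (1 - pe) * pe, pe^2),
               tolerance = 1e-12)
})

test_that("exact delayed covariance has the weak-coupling form", {
  # D -> J_il (1 - m_i^2)(1 - m_l^2) as couplings go to zero
  set.seed(4)
  N <- 4
  mod <- ising_model(runif(N, -0.3, 0.3), matrix(rnorm(N * N), N, N) * 1e-4)
  mp <- runif(N, -0.5, 0.5)
  em <- exact_moments(mod, independent_distribution(mp))
  D_lin <- mod$J * tcrossprod(1 - em$m^2, 1 - mp^2)
  expect_lt(max(abs(em$D - D_lin)) / max(abs(D_lin)), 1e-3)
  # and without couplings both covariances vanish exactly
  mod0 <- ising_model(runif(N), matrix(0, N, N))
  em0 <- exact_moments(mod0, independent_distribution(mp))
  expect_lt(max(abs(em0$D)), 1e-14)
  expect_equal(em0$C, diag(1 - em0$m^2), tolerance = 1e-14)
})

test_that("stationary distribution matches the leading eigenvector", {
  mod <- near_critical_model(5, seed = 11)
  sj <- stationary_joint(mod)
  ev <- eigen(t(sj$trans))
  v <- Re(ev$vectors[, 1]); v <- v / sum(v)
  expect_lt(max(abs(sj$p$p - v)), 1e-10)
  # fixed under one further exact step
  p_next <- evolve_exact(mod, sj$p, 1)[[2]]$p
  expect_lt(sum(abs(p_next - sj$p$p)), 1e-11)
  expect_equal(sum(sj$joint), 1, tolerance = 1e-12)
})

test_that("symmetric couplings give a time-reversible stationary state", {
  mod <- random_model(4, j_scale = 0.8, seed = 21)
  Jsym <- (mod$J + t(mod$J)) / 2
  msym <- ising_model(mod$H, Jsym)
  D <- stationary_delayed_covariance(msym)
  expect_lt(max(abs(D - t(D))), 1e-10)
})

test_that("moment containers expose per-step states", {
  ms <- empirical_moments(
    sample_trajectories(random_model(3), rep(1, 3), 3, 100, seed = 8))
  st <- moments_at(ms, 2)
  expect_s3_class(st, "moment_state")
  expect_identical(st$m, ms$m[3, ])
  expect_error(moments_at(ms, 9))
})
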