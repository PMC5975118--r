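test_that("release probability follows the coefficient-4 Hill law", {
  expect_equal(release_probability(0, ctrl), 0)
  expect_equal(release_probability(Inf, ctrl), ctrl$p_max)
  # direct arithmetic: 0.85 * 1 / (1 + 0.2^4)
  expect_equal(release_probability(1, ctrl), 0.85 / (1 + 0.2^4), tolerance = 1e-12)
  expect_equal(release_probability(1, ctrl), 0.8486, tolerance = 1e-4)
  C <- seq(0, 10, by = 0.05)
  p <- release_probability(C, ctrl)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= ctrl$p_max))
  expect_error(release_probability(-0.1, ctrl), "calcium")
})

test_that("recovery rate follows the coefficient-1 Hill law", {
  expect_equal(recovery_rate(0, ctrl), ctrl$k_min)
  expect_equal(recovery_rate(Inf, ctrl), ctrl$k_max)
  # midpoint at C = K_r: k_min + delta_k / 2
  expect_equal(recovery_rate(ctrl$K_r, ctrl), 0.0267, tolerance = 1e-12)
  r <- recovery_rate(seq(0, 10, by = 0.05), ctrl)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= ctrl$k_min & r <= ctrl$k_max))
  expect_error(recovery_rate(-1, ctrl), "calcium")
})

test_that("one map step reproduces hand-evaluated values", {
  s0 <- list(C = 0, P = 0, R = 1)
  step1 <- advance_state(s0, 10, ctrl)
  # (1 - (1 - P0) R0) = 0 forces R = 1; C jumps to delta = 1
  expect_equal(step1$state$C, 1)
  expect_equal(step1$state$R, 1)
  expect_equal(step1$state$P, 0.8486, tolerance = 1e-4)
  expect_equal(step1$Pr, 0.8486, tolerance = 1e-4)

  # second step, T = 10 ms, hand evaluation of the printed formulas
  step2 <- advance_state(step1$state, 10, ctrl)
  C2 <- exp(-10 / 1.5) + 1
  P2 <- 0.85 * C2^4 / (C2^4 + 0.2^4)
  R2 <- 1 - (1 - (1 - step1$state$P) * 1) *
    ((exp(-10 / 1.5) + 0.1) / 1.1)^0.05 * exp(-0.0017 * 10)
  expect_equal(step2$state$C, C2, tolerance = 1e-12)
  expect_equal(step2$Pr, P2 * R2, tolerance = 1e-12)
  expect_equal(step2$Pr, 0.22, tolerance = 1e-2)

  expect_error(advance_state(s0, 0, ctrl), "positive")
  expect_error(advance_state(list(C = -1, P = 0, R = 1), 10, ctrl), "invariants")
})

test_that("simulated trains are deterministic, bounded and match the R-level step", {
  train <- poisson_isis(20, 500, seed = 8)
  ser1 <- simulate_fd_train(ctrl, train, discard = 0)
  ser2 <- simulate_fd_train(ctrl, train, discard = 0)
  expect_identical(ser1, ser2)
  expect_true(all(ser1$Pr >= 0 & ser1$Pr <= ctrl$p_max))
  expect_true(all(ser1$R >= 0 & ser1$R <= 1))
  expect_true(all(ser1$C >= 0))

  # compiled path agrees with the vectorized R step
  state <- list(C = 0, P = 0, R = 1)
  for (i in 1:20) {
    nxt <- advance_state(state, train$isis[i], ctrl)
    expect_equal(nxt$Pr, ser1$Pr[i], tolerance = 1e-12)
    state <- nxt$state
  }

  expect_error(simulate_fd_train(ctrl, numeric(0)), "empty")
  expect_error(simulate_fd_train(ctrl, train, discard = 500), "discard")
})

test_that("fixed-frequency stimulation shows pure depression toward the fixed point", {
  for (params in list(ctrl, musc)) {
    ser <- simulate_fd_train(params, fixed_isis(10, 250), discard = 0)
    expect_true(all(diff(ser$Pr) < 1e-12))  # monotone nonincreasing
    fp <- fd_fixed_point(params, 10)
    expect_lt(abs(ser$Pr[250] - fp$Pr), 1e-8)
  }
  # very slow stimulation: full recovery, Pr ~ p_max * Rbar(T)
  ser <- simulate_fd_train(ctrl, fixed_isis(2000, 40), discard = 10)
  expect_equal(mean(ser$Pr), ctrl$p_max * fixed_point_R_limit(ctrl, 2000),
               tolerance = 5e-3)
})

test_that("map preserves state invariants over random states and intervals", {
  set.seed(14)
  n <- 1e6
  state <- list(C = runif(n, 0, 5), P = runif(n, 0, ctrl$p_max),
                R = runif(n))
  T <- 10^runif(n, 0, 3.7)  # 1 ms .. ~5 s
  out <- advance_state(state, T, ctrl)
  expect_true(all(out$state$C >= 0))
  expect_true(all(out$state$P >= 0 & out$state$P <= ctrl$p_max))
  expect_true(all(out$state$R >= 0 & out$state$R <= 1))
  expect_true(all(out$Pr >= 0 & out$Pr <= ctrl$p_max))
})

test_that("deterministic fixed point converges rapidly with closed-form calcium", {
  for (params in list(ctrl, musc)) {
    for (T in c(1, 5, 20, 100, 500, 2000, 5000)) {
      fp <- fd_fixed_point(params, T, tol = 1e-10)
      # convergence is geometric with factor ~(1 - P*) exp(-k_min T): a
      # handful of iterations for control, O(100) for the shallow muscarine
      # release probability at short intervals
      expect_lte(fp$iterations, 150)
      # calcium component: geometric series of the linear map
      expect_equal(fp$state$C, params$delta / (1 - exp(-T / params$tau_ca)),
                   tolerance = 1e-8)
      # one more application moves nothing
      nxt <- advance_state(fp$state, T, params)
      expect_lt(max(abs(unlist(nxt$state) - unlist(fp$state))), 1e-9)
    }
  }
  # full recovery limit: R -> 1, P -> p_max delta^4 / (delta^4 + K^4)
  fp <- fd_fixed_point(ctrl, 1e6)
  expect_equal(fp$state$R, 1, tolerance = 1e-6)
  expect_equal(fp$state$P, ctrl$p_max / (1 + ctrl$K^4), tolerance = 1e-6)
})

test_that("fixed-point response decreases with frequency and tracks simulation", {
  freqs <- c(0.5, 2, 8, 30, 100)
  fp_pr <- sapply(freqs, function(f) fd_fixed_point(ctrl, 1000 / f)$Pr)
  expect_true(all(diff(fp_pr) < 0))
  sim_mean <- sapply(freqs, function(f) {
    mean(simulate_fd_train(ctrl, poisson_isis(f, 2^12 + 100, seed = 3),
                           discard = 100)$Pr)
  })
  # the stationary mean tracks the fixed-point curve (closely at gamma
  # rates; at theta rates the spread of the distribution pulls the mean
  # below the fixed point)
  expect_lt(max(abs(sim_mean - fp_pr)), 0.15)
  expect_true(all(sim_mean <= fp_pr + 0.01))
})

test_that("large-interval ready-pool limit matches its closed form", {
  expect_equal(fixed_point_R_limit(ctrl, 2000), 0.9715, tolerance = 1e-4)
  # exact evaluation with k_min = 0.0017
  e <- exp(-0.0017 * 2000)
  expect_equal(fixed_point_R_limit(ctrl, 2000), (1 - e) / (1 - 0.15 * e),
               tolerance = 1e-12)
  T <- c(1, 10, 100, 1000, 1e4)
  r <- fixed_point_R_limit(ctrl, T)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 1))
  expect_equal(fixed_point_R_limit(ctrl, 1e-9), 0, tolerance = 1e-8)
  # p_max = 1 reduction
  expect_equal(fixed_point_R_limit(fd_params("control", p_max = 1), 500),
               1 - exp(-0.0017 * 500), tolerance = 1e-12)
})

test_that("ODE-consistent exponent removes the residual recovery factor at small tau_ca", {
  p <- fd_params("control", tau_ca = 0.001)
  for (T in c(50, 200, 1000, 5000)) {
    fp <- fd_fixed_point(p, T, exponent = "ode")
    expect_lt(abs(fp$state$R - fixed_point_R_limit(p, T)), 1e-3)
  }
})
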