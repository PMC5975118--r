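test_that("calcium stationary law is the stated gamma distribution", {
  # 50 Hz: lam = 0.05 / ms, shape = 1.075
  expect_equal(calcium_gamma_shape(0.05, 1.5), 1.075)
  expect_true(all(calcium_stationary_pdf(seq(0, 20, 0.1), 0.05, 1.5) >= 0))
  I <- integrate(calcium_stationary_pdf, 0, Inf, lam = 0.05, tau_ca = 1.5)
  expect_equal(I$value, 1, tolerance = 1e-6)
  # written-out density agrees with the gamma form
  lamtau <- 0.05 * 1.5
  expect_equal(calcium_stationary_pdf(2, 0.05, 1.5),
               2^lamtau * exp(-2) / gamma(lamtau + 1), tolerance = 1e-12)
  # lam -> 0: unit-rate exponential
  expect_equal(calcium_stationary_pdf(c(0.5, 1, 3), 1e-12, 1.5),
               exp(-c(0.5, 1, 3)), tolerance = 1e-9)
  expect_error(calcium_stationary_pdf(-1, 0.05, 1.5), ">= 0")
})

test_that("simulated stationary calcium matches the gamma law in mean and distribution", {
  lam <- 0.05
  C <- simulate_calcium(lam, 1.5, n = 2^14, seed = 11)
  se <- stats::sd(C) / sqrt(length(C))
  expect_lt(abs(mean(C) - 1.075), 3 * se)
  # CV = 1 / sqrt(lam tau + 1)
  expect_equal(stats::sd(C) / mean(C), 1 / sqrt(1.075), tolerance = 0.03)
  ks <- suppressWarnings(stats::ks.test(C, stats::pgamma, shape = 1.075, scale = 1))
  expect_gt(ks$p.value, 0.01)
  # fixed influx shifts the support and breaks the gamma form
  Cfix <- simulate_calcium(lam, 1.5, n = 2^12, influx = "fixed", seed = 11)
  expect_true(all(Cfix >= 1))
})

test_that("ready-pool fixed-point density integrates to one and reduces at a = 0", {
  for (prm in list(c(0.005, 0.15), c(0.005, 0.73), c(0.0005, 0), c(0.02, 0.5))) {
    I <- integrate(fixed_point_R_pdf, 0, 1, lam = prm[1], a = prm[2],
                   k_min = 0.0017, rel.tol = 1e-10)
    expect_equal(I$value, 1, tolerance = 1e-8)
  }
  # a = 0: Beta(1, lam/k_min) density (lam/k)(1-x)^(lam/k - 1)
  x <- seq(0, 0.99, by = 0.01)
  r <- 0.005 / 0.0017
  expect_equal(fixed_point_R_pdf(x, 0.005, 0, 0.0017),
               r * (1 - x)^(r - 1), tolerance = 1e-10)
  expect_error(fixed_point_R_pdf(1.5, 0.005, 0.15, 0.0017), "\\[0, 1\\]")
})

test_that("transform sampling through Rbar reproduces the fixed-point density", {
  set.seed(21)
  lam <- 1 / 330
  T <- rexp(2^14, rate = lam)
  x <- fixed_point_R_limit(ctrl, T)
  ks <- stats::ks.test(x, function(q)
    # closed-form CDF: P(X <= x) = u^(lam/k) with u = (1-x)/(1-a x)
    1 - ((1 - q) / (1 - 0.15 * q))^(lam / 0.0017))
  expect_gt(ks$p.value, 0.01)
  # quantile function inverts the CDF
  q <- c(0.1, 0.5, 0.9)
  xq <- fixed_point_R_quantile(q, lam, 0.15, 0.0017)
  expect_equal(1 - ((1 - xq) / (1 - 0.15 * xq))^(lam / 0.0017), q,
               tolerance = 1e-12)
})

test_that("hypergeometric mean agrees with quadrature over a parameter grid", {
  for (lam in c(0.0005, 0.002, 0.005, 0.02, 0.05)) {
    for (a in c(0, 0.15, 0.4, 0.73)) {
      # quadrature of the density (endpoint-singular when lam < k_min) and
      # of the equivalent Exp(lam) expectation of the Rbar transform
      m_quad <- integrate(function(x) x * fixed_point_R_pdf(x, lam, a, 0.0017),
                          0, 1, rel.tol = 1e-10)$value
      m_exp <- integrate(function(t) {
        e <- exp(-0.0017 * t)
        (1 - e) / (1 - a * e) * lam * exp(-lam * t)
      }, 0, Inf, rel.tol = 1e-10)$value
      m_hyp <- fixed_point_R_mean(lam, a, 0.0017)
      expect_lt(abs(m_hyp - m_quad), 1e-6)
      expect_lt(abs(m_hyp - m_exp), 1e-6)
    }
  }
  # a = 0 closed form k/(k + lam)
  expect_equal(fixed_point_R_mean(0.005, 0, 0.0017), 0.0017 / 0.0067,
               tolerance = 1e-12)
  # lam -> infinity: no recovery time
  expect_lt(fixed_point_R_mean(10, 0.15, 0.0017), 1e-3)
})

test_that("response fixed-point density is the p_max-scaled ready-pool density", {
  y <- seq(0, 0.84, by = 0.02)
  expect_equal(fixed_point_pr_pdf(y, 0.005, 0.85, 0.0017),
               fixed_point_R_pdf(y / 0.85, 0.005, 0.15, 0.0017) / 0.85,
               tolerance = 1e-12)
  I <- integrate(fixed_point_pr_pdf, 0, 0.85, lam = 0.005, p_max = 0.85,
                 k_min = 0.0017, rel.tol = 1e-10)
  expect_equal(I$value, 1, tolerance = 1e-8)
  expect_error(fixed_point_pr_pdf(0.9, 0.005, 0.85, 0.0017), "p_max")
  expect_equal(fixed_point_pr_quantile(0.5, 0.005, 0.85, 0.0017),
               0.85 * fixed_point_R_quantile(0.5, 0.005, 0.15, 0.0017))
})

test_that("hypergeometric series matches independent closed forms", {
  # 2F1(1, 1; 2; z) = -log(1 - z) / z
  for (z in c(-0.5, 0.2, 0.7, 0.95)) {
    expect_equal(hyp2f1(1, 1, 2, z), -log(1 - z) / z, tolerance = 1e-10)
  }
  # 2F1(a, b; b; z) = (1 - z)^(-a)
  expect_equal(hyp2f1(2.5, 3, 3, 0.4), 0.6^(-2.5), tolerance = 1e-10)
  expect_equal(hyp2f1(1, 2, 4, 0), 1)
  expect_error(hyp2f1(1, 2, 3, 1.2), "\\|z\\| < 1")
  expect_error(hyp2f1(1, 2, -1, 0.5), "non-positive")
})

test_that("QQ comparison is self-consistent and flags misfit", {
  set.seed(31)
  s <- rgamma(5000, shape = 2, scale = 1)
  qq <- qq_points(s, function(q) qgamma(q, shape = 2, scale = 1))
  expect_gt(qq$r_squared, 0.99)
  expect_gt(qq$r_squared_linear, 0.99)
  bad <- qq_points(s, function(q) qgamma(q, shape = 6, scale = 1))
  expect_lt(bad$r_squared, qq$r_squared)
  expect_error(qq_points(s[1:50], identity), "100")
})

test_that("simulated calcium quantiles align with the gamma reference", {
  C <- simulate_calcium(0.025, 1.5, n = 2^14, seed = 41)  # 25 Hz
  qq <- qq_points(C, function(q) qgamma(q, shape = 0.025 * 1.5 + 1, scale = 1))
  expect_gt(qq$r_squared, 0.99)
})
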