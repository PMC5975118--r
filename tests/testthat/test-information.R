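test_that("Freedman-Diaconis bin count follows the rule and its invariances", {
  # evenly spaced grid on [0, 1], n = 1000: range 1, Iqr 0.5, n^(-1/3) = 0.1
  x <- seq(0, 1, length.out = 1000)
  expect_equal(freedman_diaconis_nbins(x), 10L)
  # translation and scale invariance
  expect_equal(freedman_diaconis_nbins(x + 17.3), freedman_diaconis_nbins(x))
  expect_equal(freedman_diaconis_nbins(x * 250), freedman_diaconis_nbins(x))
  set.seed(1)
  y <- runif(4096)
  expect_equal(freedman_diaconis_nbins(y + 2), freedman_diaconis_nbins(y))
  expect_equal(freedman_diaconis_nbins(y * 1e3), freedman_diaconis_nbins(y))
  # degenerate spread falls back to the square-root rule
  expect_warning(nb <- freedman_diaconis_nbins(rep(1, 100)), "square-root")
  expect_equal(nb, 10L)
  expect_error(freedman_diaconis_nbins(c(1, 2)), "4 samples")
})

test_that("entropy of simple distributions matches closed forms", {
  expect_equal(entropy_bits(rep(1 / 16, 16)), 4)
  expect_equal(entropy_bits(c(1, rep(0, 7))), 0)
  expect_equal(entropy_bits(c(0.5, 0.5)), 1)
  d <- bin_fixed(c(0.05, 0.15, 0.25, 0.35), nbins = 10, range = c(0, 1))
  expect_equal(entropy_bits(d), 2)  # four equally occupied bins
  expect_error(entropy_bits(c(0.5, 0.6)), "sum to 1")
})

test_that("binned distributions are normalized with strictly increasing edges", {
  set.seed(2)
  x <- rnorm(2048)
  d <- bin_samples(x)
  expect_s3_class(d, "binned_distribution")
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
  expect_true(all(diff(d$edges) > 0))
  expect_equal(d$n, 2048L)
  # every sample lands in exactly one bin, extremes included
  expect_equal(sum(d$probs > 0), length(unique(bin_index(x, d$edges))))
})

test_that("joint entropy honors its bounds and the enumeration oracle", {
  set.seed(3)
  x <- runif(4096)
  y <- runif(4096)
  hx <- entropy_bits(bin_samples(x))
  hy <- entropy_bits(bin_samples(y))
  hxy <- joint_entropy_bits(x, y)
  expect_gte(hxy + 1e-9, max(hx, hy))
  expect_lte(hxy, hx + hy + 1e-9)
  # independent uniforms: near-additive
  expect_equal(hxy, hx + hy, tolerance = 0.05)
  # identical variables: H(X, X) = H(X)
  expect_equal(joint_entropy_bits(x, x), hx, tolerance = 1e-12)
  expect_error(joint_entropy_bits(x, y[1:10]), "equal length")

  # explicit 4x4 joint table, including a checkerboard coupling
  tables <- list(
    matrix(c(40, 0, 10, 0, 0, 40, 0, 10, 10, 0, 40, 0, 0, 10, 0, 40), 4, 4),
    matrix(1:16, 4, 4)
  )
  for (counts in tables) {
    s <- joint_table_samples(counts)
    expect_equal(joint_entropy_bits(s$x, s$y, s$edges, s$edges),
                 entropy_enumeration_bits(counts), tolerance = 1e-12)
    expect_equal(mutual_information_hist(s$x, s$y, s$edges, s$edges),
                 mi_enumeration_bits(counts), tolerance = 1e-12)
  }
})

test_that("histogram mutual information is symmetric, nonnegative and exact on toy cases", {
  set.seed(4)
  x <- rnorm(4096)
  y <- x + rnorm(4096, sd = 0.5)
  expect_equal(mutual_information_hist(x, y), mutual_information_hist(y, x),
               tolerance = 1e-12)
  expect_gte(mutual_information_hist(x, y), 0)
  # independence: small positive value, the plug-in bias ~ cells / (2 N ln 2)
  z <- rnorm(4096)
  expect_lt(mutual_information_hist(x, z), 0.25)
  # deterministic relation: I equals the entropy of either variable
  expect_equal(mutual_information_hist(x, x),
               entropy_bits(bin_samples(x)), tolerance = 1e-12)
})

test_that("nonnegativity of histogram MI holds across random couplings", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(500:2000, 1)
    x <- rnorm(n)
    y <- sample(c(-1, 1), 1) * x^sample(1:2, 1) + rnorm(n, sd = runif(1, 0.1, 2))
    expect_gte(mutual_information_hist(x, y), -1e-12)
  }
})

test_that("response/preceding-ISI mutual information needs aligned series", {
  ser <- simulate_fd_train(ctrl, poisson_isis(5, 1200, seed = 6), discard = 100)
  psr <- generate_psr_series(ser, response_model(), seed = 7)
  mi <- mi_psr_vs_preceding_isi(psr)
  expect_gt(mi, 0)
  expect_equal(mi, mi_psr_vs_preceding_isi(psr$amplitude, psr$isi_ms))
  expect_error(mi_psr_vs_preceding_isi(psr$amplitude, psr$isi_ms[-1]),
               "aligned")
  # constant response carries no information about the interval
  flat <- psr
  flat$amplitude <- rep(0.5, nrow(flat))
  expect_warning(expect_equal(mi_psr_vs_preceding_isi(flat), 0, tolerance = 1e-9),
                 "square-root")
})

test_that("sum-history MI starts at the single-ISI value and handles short input", {
  ser <- simulate_fd_train(ctrl, poisson_isis(5, 3000, seed = 8), discard = 100)
  psr <- generate_psr_series(ser, response_model(), seed = 9)
  hist_mi <- mi_vs_sum_history(psr, max_depth = 4)
  expect_equal(nrow(hist_mi), 4)
  expect_equal(hist_mi$mi_bits[1], mi_psr_vs_preceding_isi(psr),
               tolerance = 1e-12)
  expect_true(all(hist_mi$mi_bits >= 0))
  expect_error(mi_vs_sum_history(psr[1:500, ], max_depth = 4), "too short")
})
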