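#' Stationary distribution of the presynaptic calcium concentration
#'
#' Sampled at spike times, the calcium recurrence
#' \eqn{C_n = C_{n-1} e^{-T_n/\tau_{ca}} + \Delta} with exponential ISIs of
#' rate \eqn{\lambda} (1/ms) and unit influx has the stationary gamma law
#' \deqn{f_C(c) = \frac{1}{\Gamma(\lambda\tau_{ca} + 1)}
#'   c^{\lambda\tau_{ca}} e^{-c},}
#' i.e. shape \eqn{\lambda\tau_{ca} + 1} and scale 1. The mean is the shape
#' and the coefficient of variation is \eqn{1/\sqrt{\lambda\tau_{ca} + 1}}.
#'
#' @param c Calcium concentration(s), >= 0.
#' @param lam Mean Poisson rate, 1/ms.
#' @param tau_ca Calcium decay time constant, ms.
#' @return Density values; `calcium_gamma_shape()` returns the shape
#'   parameter \eqn{\lambda\tau_{ca} + 1}.
#' @examples
#' calcium_gamma_shape(0.05, 1.5)       # 50 Hz: 1.075
#' calcium_stationary_pdf(1, 0.05, 1.5)
#' @export
calcium_stationary_pdf <- function(c, lam, tau_ca) {
  if (any(c < 0)) stop("calcium concentration must be >= 0", call. = FALSE)
  stats::dgamma(c, shape = calcium_gamma_shape(lam, tau_ca), scale = 1)
}

#' @rdname calcium_stationary_pdf
#' @export
calcium_gamma_shape <- function(lam, tau_ca) {
  if (any(lam <= 0) || any(tau_ca <= 0)) {
    stop("`lam` and `tau_ca` must be positive", call. = FALSE)
  }
  lam * tau_ca + 1
}

#' Simulate stationary calcium samples
#'
#' Iterates the calcium recurrence
#' \eqn{C_n = C_{n-1} e^{-T_n/\tau_{ca}} + \Delta_n} alone over a Poisson
#' train, discarding a transient, for goodness-of-fit comparison against
#' [calcium_stationary_pdf()]. In the stochastic-recurrence analysis the
#' per-spike influx \eqn{\Delta_n} is an i.i.d. random variable; with
#' exponentially distributed influx of unit mean the stationary law is
#' *exactly* the gamma distribution with shape \eqn{\lambda\tau_{ca} + 1}
#' and scale 1 (the decayed shot noise contributes a Gamma(\eqn{\lambda\tau_{ca}}, 1)
#' component and the last influx an independent Exp(1)). With a fixed
#' (degenerate) influx the law is shifted to the support
#' \eqn{[\Delta, \infty)} and the gamma form is only a mean/CV-matching
#' approximation; `influx = "fixed"` exposes that variant.
#'
#' @param lam Mean Poisson rate, 1/ms.
#' @param tau_ca Calcium decay constant, ms.
#' @param delta Mean per-spike influx (1 for the control normalization under
#'   which the stationary scale is 1).
#' @param n Number of stationary samples.
#' @param discard Transient spikes to discard.
#' @param influx `"exponential"` (i.i.d. Exp(mean `delta`), default) or
#'   `"fixed"` (constant `delta`, as in the deterministic map).
#' @param seed Optional seed.
#' @return Numeric vector of `n` stationary calcium values.
#' @export
simulate_calcium <- function(lam, tau_ca, delta = 1, n = 2^14,
                             discard = 100L,
                             influx = c("exponential", "fixed"),
                             seed = NULL) {
  influx <- match.arg(influx)
  total <- n + discard
  draws <- local_seed(seed, {
    isis <- rexp(total, rate = lam)
    deltas <- if (influx == "exponential") rexp(total, rate = 1 / delta)
              else rep(delta, total)
    list(isis = isis, deltas = deltas)
  })
  C <- calcium_recurrence_cpp(draws$isis, draws$deltas, 0, tau_ca)
  C[(discard + 1L):total]
}

check_fp_params <- function(lam, a, k_min) {
  if (lam <= 0 || k_min <= 0) stop("`lam` and `k_min` must be positive",
                                   call. = FALSE)
  if (a < 0 || a >= 1) stop("`a` = 1 - p_max must lie in [0, 1)",
                            call. = FALSE)
}

#' Density, mean and quantiles of the stochastic fixed point
#'
#' For calcium decay much faster than the mean ISI, the normalized response
#' settles to the fixed point \eqn{\bar R(T)} of [fixed_point_R_limit()]
#' within an interval, so exponential ISIs \eqn{T \sim Exp(\lambda)} induce a
#' closed-form law on \eqn{X = \bar R}:
#' \deqn{f(x \mid \lambda, a, k_{min}) = \frac{\lambda (1-a)}{k_{min}}
#'   (1 - x)^{-(1 - \lambda/k_{min})} (1 - a x)^{-(1 + \lambda/k_{min})},
#'   \quad 0 \le x \le 1,}
#' with \eqn{a = 1 - P_{max}}. The response fixed point
#' \eqn{Y = \overline{PR} = P_{max} X} (the *stochastic fixed point*) has the
#' scaled density supported on \eqn{[0, P_{max}]}:
#' \deqn{f(y) = \frac{\lambda P_{max} (1-a)}{k_{min}}
#'   (P_{max} - y)^{-(1 - \lambda/k_{min})}
#'   (P_{max} - a y)^{-(1 + \lambda/k_{min})}.}
#' The mean of `X` involves the Gauss hypergeometric function:
#' \deqn{E(X) = (1-a)\lambda\Bigl(\frac{1}{\lambda(1-a)} -
#'   \frac{{}_2F_1(1, (k_{min}+\lambda)/k_{min};\, 2 + \lambda/k_{min};\, a)}
#'        {k_{min}+\lambda}\Bigr).}
#' Because \eqn{\bar R(T)} is monotone in `T`, the CDF and quantile function
#' are available in closed form through the exponential law of `T`; the
#' quantile functions are exact, not numeric inversions.
#'
#' Densities are evaluated in log space: near the upper support endpoint the
#' factor \eqn{(1-x)^{\lambda/k_{min}-1}} under- or overflows for extreme
#' rate ratios.
#'
#' @param x,y Evaluation points (`x` in \[0, 1\], `y` in \[0, p_max\]).
#' @param q Probabilities in \[0, 1\] for the quantile functions.
#' @param lam Mean Poisson rate, 1/ms.
#' @param a `1 - p_max`, in \[0, 1).
#' @param k_min Baseline recovery rate, 1/ms.
#' @param p_max Maximal release probability.
#' @return Densities, means, or quantiles as named.
#' @examples
#' # control at 5 Hz: lam = 0.005/ms
#' integrate(fixed_point_R_pdf, 0, 1, lam = 0.005, a = 0.15, k_min = 0.0017)
#' fixed_point_R_mean(0.005, 0.15, 0.0017)
#' @export
fixed_point_R_pdf <- function(x, lam, a, k_min) {
  check_fp_params(lam, a, k_min)
  if (any(x < 0 | x > 1)) stop("`x` must lie in [0, 1]", call. = FALSE)
  r <- lam / k_min
  logf <- log(lam) + log1p(-a) - log(k_min) +
    (r - 1) * log1p(-x) - (1 + r) * log1p(-a * x)
  out <- exp(logf)
  # endpoint x = 1: density 0 when r > 1, +Inf when r < 1 (integrable)
  at1 <- x == 1
  if (any(at1)) out[at1] <- if (r > 1) 0 else if (r < 1) Inf else
    exp(log(lam) + log1p(-a) - log(k_min) - 2 * log1p(-a))
  out
}

#' @rdname fixed_point_R_pdf
#' @export
fixed_point_pr_pdf <- function(y, lam, p_max, k_min) {
  a <- 1 - p_max
  check_fp_params(lam, a, k_min)
  if (any(y < 0 | y > p_max)) {
    stop("`y` must lie in [0, p_max]", call. = FALSE)
  }
  fixed_point_R_pdf(y / p_max, lam, a, k_min) / p_max
}

#' @rdname fixed_point_R_pdf
#' @export
fixed_point_R_mean <- function(lam, a, k_min) {
  check_fp_params(lam, a, k_min)
  h <- hyp2f1(1, (k_min + lam) / k_min, 2 + lam / k_min, a)
  (1 - a) * lam * (1 / (lam * (1 - a)) - h / (k_min + lam))
}

#' @rdname fixed_point_R_pdf
#' @export
fixed_point_R_quantile <- function(q, lam, a, k_min) {
  check_fp_params(lam, a, k_min)
  if (any(q < 0 | q > 1)) stop("`q` must lie in [0, 1]", call. = FALSE)
  # X = (1 - U)/(1 - a U) with U = e^{-k_min T} and T ~ Exp(lam):
  # U has CDF P(U <= u) = u^{lam/k_min}, so U_q = (1 - q)^{k_min/lam}
  u <- (1 - q)^(k_min / lam)
  (1 - u) / (1 - a * u)
}

#' @rdname fixed_point_R_pdf
#' @export
fixed_point_pr_quantile <- function(q, lam, p_max, k_min) {
  p_max * fixed_point_R_quantile(q, lam, 1 - p_max, k_min)
}

#' Gauss hypergeometric function by power series
#'
#' Evaluates \eqn{{}_2F_1(a, b; c; z)} for \eqn{|z| < 1} by direct summation
#' of the hypergeometric series with term recurrence, to absolute tolerance
#' `tol`. The arguments arising in [fixed_point_R_mean()] (`z = 1 - p_max`,
#' well inside the unit disc) converge in a few dozen terms.
#'
#' @param a,b,c Function parameters; `c` must not be a non-positive integer.
#' @param z Argument with `|z| < 1`.
#' @param tol Absolute tolerance on the truncated tail.
#' @param max_terms Series length cap.
#' @return The function value.
#' @export
hyp2f1 <- function(a, b, c, z, tol = 1e-12, max_terms = 1e5) {
  if (abs(z) >= 1) stop("series evaluation requires |z| < 1", call. = FALSE)
  if (c <= 0 && c == round(c)) {
    stop("`c` must not be a non-positive integer", call. = FALSE)
  }
  term <- 1
  total <- 1
  for (n in 0:max_terms) {
    term <- term * (a + n) * (b + n) / ((c + n) * (n + 1)) * z
    total <- total + term
    if (abs(term) < tol) return(total)
  }
  stop("hypergeometric series did not converge", call. = FALSE)
}

#' Quantile-quantile comparison of samples against a reference law
#'
#' Computes paired empirical and theoretical quantiles and the coefficient of
#' determination of the identity-line fit, the linearity diagnostic used to
#' judge agreement between simulated distributions and the analytic laws.
#'
#' @param samples Numeric samples (>= 100).
#' @param reference_quantile_fn Function mapping probabilities to theoretical
#'   quantiles (e.g. `function(q) qgamma(q, shape, scale = 1)`).
#' @param n_quantiles Number of probability points (default 100).
#' @return A list with a tibble `points` (`prob`, `empirical`,
#'   `theoretical`), `r_squared` — the identity-line statistic
#'   \eqn{1 - \sum (e_i - t_i)^2 / \sum (e_i - \bar e)^2}, which penalizes
#'   any departure from `empirical = theoretical` — and
#'   `r_squared_linear`, the squared Pearson correlation of the quantile
#'   pairs, which measures only straightness of the QQ plot (the usual
#'   visual criterion for "same distribution up to location/scale").
#' @export
qq_points <- function(samples, reference_quantile_fn, n_quantiles = 100) {
  if (length(samples) < 100) {
    stop("need at least 100 samples for a quantile comparison", call. = FALSE)
  }
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  emp <- as.numeric(quantile(samples, probs, names = FALSE, type = 7))
  theo <- reference_quantile_fn(probs)
  ss_res <- sum((emp - theo)^2)
  ss_tot <- sum((emp - mean(emp))^2)
  list(points = tibble::tibble(prob = probs, empirical = emp,
                               theoretical = theo),
       r_squared = 1 - ss_res / ss_tot,
       r_squared_linear = stats::cor(emp, theo)^2)
}
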