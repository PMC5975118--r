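#' Katz-style stochastic postsynaptic response model
#'
#' The variability of the postsynaptic response around the deterministic map
#' output is modelled in two stages. Given the release probability `Pr` at a
#' spike, the number of vesicles released from `n_sites` independent release
#' sites is binomial, \eqn{K \sim B(N, Pr)}. Each released vesicle evokes a
#' quantal response drawn from a normal law with mean `mu` and s.d. `sigma`,
#' two-sided truncated to the interval \eqn{(0, 2\mu)}; the response amplitude
#' is the sum of the `K` quantal amplitudes, and exactly 0 on failure
#' (`K = 0`).
#'
#' The number of release sites is not constrained by the fitted map, so it is
#' an explicit model choice here (default 10); the quantal constants default
#' to the fitted `mu = 0.5`, `sigma = 0.1`.
#'
#' @param n_sites Number of independent release sites `N` (>= 1).
#' @param mu Quantal mean amplitude (> 0), response units.
#' @param sigma Quantal standard deviation (> 0), response units.
#' @return An object of class `response_model` with fields `n_sites`, `mu`,
#'   `sigma` and `n_cts`, the normalization constant of the truncated quantal
#'   density \eqn{N_{cts} = \Phi(\mu/\sigma) - \Phi(-\mu/\sigma)}.
#' @examples
#' response_model()
#' @export
response_model <- function(n_sites = 10L, mu = 0.5, sigma = 0.1) {
  if (n_sites < 1 || n_sites != round(n_sites)) {
    stop("`n_sites` must be a positive integer", call. = FALSE)
  }
  if (mu <= 0 || sigma <= 0) stop("`mu` and `sigma` must be positive",
                                  call. = FALSE)
  structure(list(n_sites = as.integer(n_sites), mu = mu, sigma = sigma,
                 n_cts = pnorm(mu / sigma) - pnorm(-mu / sigma)),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf(
    "quantal response model: N = %d sites, mu = %g, sigma = %g (N_cts = %.6f)\n",
    x$n_sites, x$mu, x$sigma, x$n_cts))
  invisible(x)
}

#' Draw vesicle release counts
#'
#' \eqn{K \sim B(N, Pr)} per spike.
#'
#' @param pr Release probability (vectorized), each in \[0, 1\].
#' @param model A [response_model].
#' @return Integer release counts in `[0, n_sites]`, one per element of `pr`.
#' @export
draw_release_count <- function(pr, model) {
  if (any(pr < 0 | pr > 1)) stop("`pr` must lie in [0, 1]", call. = FALSE)
  rbinom(length(pr), size = model$n_sites, prob = pr)
}

#' Draw truncated-normal quantal amplitudes
#'
#' Samples the quantal response density
#' \deqn{f(s) = \frac{1}{\sqrt{2\pi\sigma^2} N_{cts}}
#'   e^{-(s - \mu)^2 / (2\sigma^2)}, \quad 0 < s < 2\mu,}
#' by inverse-CDF transformation (exact, no rejection loop).
#'
#' @param n Number of samples.
#' @param model A [response_model].
#' @return Amplitudes strictly inside `(0, 2 * mu)`.
#' @export
draw_quantal <- function(n, model) {
  lo <- pnorm(-model$mu / model$sigma)
  hi <- pnorm(model$mu / model$sigma)
  u <- runif(n, lo, hi)
  model$mu + model$sigma * qnorm(u)
}

#' Draw postsynaptic response amplitudes
#'
#' Combines [draw_release_count()] and [draw_quantal()]: the amplitude is 0
#' when no site releases and otherwise the sum of `K` independent truncated
#' quantal draws. The untruncated shortcut \eqn{S \sim N(K\mu, \sqrt{K}\sigma)}
#' is available via `method = "normal"`; it differs slightly from the
#' generative sum because the truncation is applied per vesicle.
#'
#' @param pr Release probabilities (vectorized), each in \[0, 1\].
#' @param model A [response_model].
#' @param method `"sum"` (default, sum of truncated draws) or `"normal"`.
#' @return A list with `amplitude` and the integer `k_released`, both aligned
#'   with `pr`.
#' @export
draw_psr <- function(pr, model, method = c("sum", "normal")) {
  method <- match.arg(method)
  k <- draw_release_count(pr, model)
  amp <- numeric(length(pr))
  pos <- which(k > 0)
  if (length(pos)) {
    if (method == "sum") {
      total <- sum(k[pos])
      q <- draw_quantal(total, model)
      amp[pos] <- vapply(split(q, rep.int(seq_along(pos), k[pos])), sum, 0)
    } else {
      amp[pos] <- stats::rnorm(length(pos),
                               mean = k[pos] * model$mu,
                               sd = sqrt(k[pos]) * model$sigma)
    }
  }
  list(amplitude = amp, k_released = k)
}

#' Generate a stochastic postsynaptic response series
#'
#' Applies the quantal response model to every spike of a simulated FD
#' trajectory, producing the response amplitudes used by the
#' mutual-information analyses.
#'
#' @param pr_series A `pr_series` tibble from [simulate_fd_train()].
#' @param model A [response_model].
#' @param seed Optional seed for reproducible draws.
#' @param method Passed to [draw_psr()].
#' @return A tibble of class `psr_series` with columns `spike_index`,
#'   `isi_ms`, `pr`, `k_released`, `amplitude`.
#' @examples
#' ser <- simulate_fd_train(fd_params("control"), poisson_isis(5, 500, seed = 1),
#'                          discard = 100)
#' psr <- generate_psr_series(ser, response_model(), seed = 2)
#' @export
generate_psr_series <- function(pr_series, model, seed = NULL,
                                method = c("sum", "normal")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(pr_series), "Pr" %in% names(pr_series))
  draw <- local_seed(seed, draw_psr(pr_series$Pr, model, method))
  out <- tibble::tibble(
    spike_index = pr_series$spike_index,
    isi_ms = pr_series$isi_ms,
    pr = pr_series$Pr,
    k_released = draw$k_released,
    amplitude = draw$amplitude
  )
  class(out) <- c("psr_series", class(out))
  out
}

#' Write a postsynaptic response series to CSV
#'
#' @param series A `psr_series` from [generate_psr_series()].
#' @param path CSV file path.
#' @export
write_psr_series <- function(series, path) {
  utils::write.csv(
    series[c("spike_index", "isi_ms", "pr", "k_released", "amplitude")],
    path, row.names = FALSE)
  invisible(path)
}
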