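#' Calcium-dependent release probability and recovery rate
#'
#' The FD map couples facilitation and depression through the presynaptic
#' calcium concentration `C`. Release probability follows a Hill function of
#' coefficient 4 (synaptotagmin-1 cooperativity),
#' \deqn{P_{rel}(C) = P_{max} \frac{C^4}{C^4 + K^4},}
#' and the recovery rate of the readily releasable pool follows a Hill
#' function of coefficient 1,
#' \deqn{k_{recov}(C) = k_{min} + \Delta k \frac{C}{C + K_r},}
#' with \eqn{\Delta k = k_{max} - k_{min}}.
#'
#' @param C Dimensionless calcium concentration(s), >= 0. Vectorized.
#' @param params An [fd_params] object.
#' @return `release_probability()` returns values in `[0, p_max]`;
#'   `recovery_rate()` returns rates in `[k_min, k_max]` (1/ms).
#' @examples
#' p <- fd_params("control")
#' release_probability(1, p)   # ~0.8486
#' recovery_rate(p$K_r, p)     # midpoint (k_min + k_max) / 2
#' @export
release_probability <- function(C, params) {
  validate_fd_params(params)
  if (any(C < 0)) stop("calcium concentration must be >= 0", call. = FALSE)
  c4 <- C^4
  out <- params$p_max * c4 / (c4 + params$K^4)
  out[is.infinite(C)] <- params$p_max
  out
}

#' @rdname release_probability
#' @export
recovery_rate <- function(C, params) {
  validate_fd_params(params)
  if (any(C < 0)) stop("calcium concentration must be >= 0", call. = FALSE)
  out <- params$k_min + params$delta_k * C / (C + params$K_r)
  out[is.infinite(C)] <- params$k_max
  out
}

#' Advance the FD map by one inter-spike interval
#'
#' One step of the discrete facilitation-depression map. Starting from the
#' state just after spike `n` (calcium `C`, release probability `P`, ready
#' pool `R`, with the pool already depleted by the factor `1 - P` at release),
#' an interval `T` elapses and spike `n + 1` arrives:
#' \deqn{C_{n+1} = C_n e^{-T/\tau_{ca}} + \Delta,}
#' \deqn{P_{n+1} = P_{max} C_{n+1}^4 / (C_{n+1}^4 + K^4),}
#' \deqn{R_{n+1} = 1 - \bigl(1 - (1 - P_n) R_n\bigr)
#'   \Bigl(\frac{C_n e^{-T/\tau_{ca}} + K_r}{K_r + C_n}\Bigr)^{\Delta k}
#'   e^{-k_{min} T}.}
#' The normalized postsynaptic response at spike `n + 1` is
#' `Pr = P_{n+1} * R_{n+1}`, evaluated before the pool is depleted again.
#'
#' The exponent on the calcium-ratio factor is the printed `delta_k`
#' (a rate, numerically 0.05 with the fitted constants). The exact solution of
#' the recovery ODE gives the dimensionless exponent `delta_k * tau_ca`
#' instead; set `exponent = "ode"` for that variant. The default reproduces
#' the printed map.
#'
#' @param state Named list or vector with components `C`, `P`, `R`. Components
#'   may be vectors of equal length for batched stepping.
#' @param T Inter-spike interval(s), ms, > 0.
#' @param params An [fd_params] object.
#' @param exponent `"printed"` (default) or `"ode"`.
#' @return A list with the new `state` (list `C`, `P`, `R`) and `Pr`, the
#'   normalized postsynaptic response at the new spike.
#' @examples
#' p <- fd_params("control")
#' s0 <- list(C = 0, P = 0, R = 1)
#' step1 <- advance_state(s0, 10, p)   # Pr ~0.8486 on the first spike
#' advance_state(step1$state, 10, p)$Pr  # ~0.22: depression
#' @export
advance_state <- function(state, T, params, exponent = c("printed", "ode")) {
  validate_fd_params(params)
  exponent <- match.arg(exponent)
  if (any(T <= 0)) stop("inter-spike interval must be positive", call. = FALSE)
  C <- state$C; P <- state$P; R <- state$R
  if (any(C < 0) || any(P < 0) || any(P > params$p_max + 1e-12) ||
      any(R < 0) || any(R > 1)) {
    stop("state violates invariants (C >= 0, 0 <= P <= p_max, 0 <= R <= 1)",
         call. = FALSE)
  }
  ex <- if (exponent == "ode") params$delta_k * params$tau_ca else params$delta_k
  decay <- exp(-T / params$tau_ca)
  C_dec <- C * decay
  C_new <- C_dec + params$delta
  P_new <- release_probability(C_new, params)
  R_new <- 1 - (1 - (1 - P) * R) *
    ((C_dec + params$K_r) / (params$K_r + C))^ex * exp(-params$k_min * T)
  list(state = list(C = C_new, P = P_new, R = R_new), Pr = P_new * R_new)
}

#' Simulate the FD map along a spike train
#'
#' Iterates the FD map over a full ISI sequence and records the trajectory.
#' The initial state is `(C = 0, P = 0, R = 1)`: baseline calcium and a full
#' readily releasable pool. The first `discard` responses (the transient
#' approach to the stationary regime) are dropped from the result.
#'
#' @param params An [fd_params] object.
#' @param isis An `isi_train` (see [poisson_isis()]) or numeric vector of
#'   ISIs in ms.
#' @param discard Number of initial spikes to discard as transient
#'   (default 100).
#' @param init Optional initial state, list with `C`, `P`, `R`.
#' @param exponent `"printed"` or `"ode"`, see [advance_state()].
#' @return A tibble of class `pr_series` with columns `spike_index` (index in
#'   the undiscarded train), `isi_ms`, `C`, `P`, `R`, `Pr`. The number of
#'   discarded spikes is kept in the `discard` attribute.
#' @examples
#' ser <- simulate_fd_train(fd_params("control"), fixed_isis(10, 25), discard = 0)
#' ser$Pr # strictly decreasing: depression at 100 Hz
#' @export
simulate_fd_train <- function(params, isis, discard = 100L, init = NULL,
                              exponent = c("printed", "ode")) {
  validate_fd_params(params)
  exponent <- match.arg(exponent)
  T <- as_isis(isis)
  n <- length(T)
  if (n == 0) stop("ISI train is empty", call. = FALSE)
  if (any(T <= 0)) stop("all ISIs must be positive", call. = FALSE)
  discard <- as.integer(discard)
  if (discard < 0 || discard >= n) {
    stop("`discard` must be in [0, length(isis) - 1]", call. = FALSE)
  }
  if (is.null(init)) init <- list(C = 0, P = 0, R = 1)
  ex <- if (exponent == "ode") params$delta_k * params$tau_ca else params$delta_k
  tr <- fd_simulate_cpp(T, init$C, init$P, init$R,
                        params$tau_ca, params$delta, params$p_max, params$K,
                        params$K_r, params$k_min, ex)
  keep <- (discard + 1L):n
  out <- tibble::tibble(
    spike_index = keep,
    isi_ms = T[keep],
    C = tr$C[keep], P = tr$P[keep], R = tr$R[keep],
    Pr = tr$Pr[keep]
  )
  attr(out, "discard") <- discard
  attr(out, "condition") <- params$condition
  class(out) <- c("pr_series", class(out))
  out
}

#' Write a simulated FD trajectory to CSV
#'
#' @param series A `pr_series` tibble from [simulate_fd_train()].
#' @param path CSV file path.
#' @export
write_pr_series <- function(series, path) {
  utils::write.csv(series[c("spike_index", "isi_ms", "C", "P", "R", "Pr")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Attracting fixed point of the deterministic FD map
#'
#' For constant inter-spike interval `T` the map has a single attracting fixed
#' point, reached within a few iterations from physiological initial
#' conditions. The calcium component has the closed form
#' \eqn{C^* = \Delta / (1 - e^{-T/\tau_{ca}})}; the remaining components are
#' found by iterating the map from `(C = 0, P = 0, R = 1)` until successive
#' states differ by less than `tol` in every component.
#'
#' @param params An [fd_params] object.
#' @param T Constant ISI in ms, > 0.
#' @param tol Convergence tolerance on every state component.
#' @param max_iter Iteration cap.
#' @param exponent `"printed"` or `"ode"`, see [advance_state()].
#' @return A list with the fixed-point `state` (`C`, `P`, `R`), its response
#'   `Pr`, and the iteration count `iterations`.
#' @examples
#' fp <- fd_fixed_point(fd_params("control"), T = 200)
#' fp$Pr  # stationary response at 5 Hz stimulation
#' @export
fd_fixed_point <- function(params, T, tol = 1e-10, max_iter = 1e4,
                           exponent = c("printed", "ode")) {
  validate_fd_params(params)
  exponent <- match.arg(exponent)
  if (length(T) != 1 || T <= 0) stop("`T` must be a single positive ISI",
                                     call. = FALSE)
  state <- list(C = 0, P = 0, R = 1)
  for (i in seq_len(max_iter)) {
    nxt <- advance_state(state, T, params, exponent)
    delta <- max(abs(nxt$state$C - state$C), abs(nxt$state$P - state$P),
                 abs(nxt$state$R - state$R))
    state <- nxt$state
    if (delta < tol) {
      return(list(state = state, Pr = nxt$Pr, iterations = i))
    }
  }
  stop("fixed-point iteration did not converge within `max_iter`",
       call. = FALSE)
}

#' Large-interval limit of the fixed-point ready pool
#'
#' When the calcium decay time is much shorter than the inter-spike interval,
#' calcium relaxes to its fixed point \eqn{\bar C \to \Delta} and the release
#' probability to \eqn{P_{max}\Delta^4/(\Delta^4 + K^4)}. With `delta = 1`
#' the recovery between spikes proceeds essentially at `k_min`, giving the
#' ready-pool fixed point the closed form
#' \deqn{\bar R(T) = \frac{1 - e^{-k_{min} T}}{1 - (1 - P_{max}) e^{-k_{min} T}}.}
#' This is the transform underlying the analytic stochastic fixed-point
#' densities (see [fixed_point_pr_pdf()]).
#'
#' @param params An [fd_params] object (only `k_min` and `p_max` enter).
#' @param T Inter-spike interval(s), ms, > 0. Vectorized.
#' @return \eqn{\bar R(T)} in (0, 1).
#' @examples
#' fixed_point_R_limit(fd_params("control"), 2000)  # ~0.9715
#' @export
fixed_point_R_limit <- function(params, T) {
  validate_fd_params(params)
  if (any(T <= 0)) stop("`T` must be positive", call. = FALSE)
  e <- exp(-params$k_min * T)
  (1 - e) / (1 - (1 - params$p_max) * e)
}
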