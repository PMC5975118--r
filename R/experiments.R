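#' Stationary Pr statistics across a frequency grid
#'
#' The workhorse behind the frequency sweeps: for every rate on the grid it
#' generates a seeded Poisson train, iterates the FD map, discards the
#' transient, and summarizes the stationary distribution of the normalized
#' postsynaptic response `Pr` on the fixed 100-bin partition of \[0, 1\]
#' (entropies are only comparable across frequencies and conditions on a
#' common partition). Sub-seeds are derived per frequency from `seed`, so a
#' sweep is reproducible element-wise regardless of grid order or length.
#'
#' @param params An [fd_params] object (or condition name).
#' @param freqs_hz Frequency grid, Hz, all > 0.
#' @param n Stationary samples per frequency (default `2^14`).
#' @param discard Transient spikes discarded per frequency (default 100).
#' @param nbins Bins of the fixed Pr partition (default 100).
#' @param seed Experiment seed.
#' @param keep_histograms Keep the per-frequency `binned_distribution`s.
#' @return A list with `summary`, a tibble (`condition`, `frequency_hz`,
#'   `mean_pr`, `peak_pr`, `entropy_bits`, `fixed_point_pr`, `n`, `seed`),
#'   and (optionally) `histograms`. `peak_pr` is the midpoint of the fullest
#'   bin; `fixed_point_pr` is the deterministic fixed-point response at the
#'   mean ISI, the curve the stationary mean tracks.
#' @examples
#' sw <- run_pr_sweep(fd_params("control"), c(0.5, 5, 50), n = 2^12, seed = 1)
#' sw$summary
#' @export
run_pr_sweep <- function(params, freqs_hz, n = 2^14, discard = 100L,
                         nbins = 100L, seed = 1L, keep_histograms = FALSE) {
  if (is.character(params)) params <- fd_params(params)
  validate_fd_params(params)
  if (length(freqs_hz) == 0 || any(freqs_hz <= 0)) {
    stop("frequency grid must be nonempty and positive", call. = FALSE)
  }
  if (n < 2^10) stop("need at least 2^10 samples per frequency", call. = FALSE)
  seeds <- derive_seeds(seed, length(freqs_hz))
  per_freq <- lapply(seq_along(freqs_hz), function(i) {
    f <- freqs_hz[i]
    train <- poisson_isis(f, n + discard, seed = seeds[i])
    ser <- simulate_fd_train(params, train, discard = discard)
    h <- bin_fixed(ser$Pr, nbins = nbins, range = c(0, 1))
    mids <- (h$edges[-1] + h$edges[-length(h$edges)]) / 2
    row <- tibble::tibble(
      condition = params$condition,
      frequency_hz = f,
      mean_pr = mean(ser$Pr),
      peak_pr = mids[which.max(h$probs)],
      entropy_bits = entropy_bits(h),
      fixed_point_pr = fd_fixed_point(params, 1000 / f)$Pr,
      n = n, seed = seeds[i]
    )
    list(row = row, hist = h)
  })
  out <- list(summary = do.call(rbind, lapply(per_freq, `[[`, "row")))
  if (keep_histograms) {
    out$histograms <- stats::setNames(lapply(per_freq, `[[`, "hist"),
                                      sprintf("%g_hz", freqs_hz))
  }
  out
}

#' Entropy of the stationary Pr distribution versus mean rate
#'
#' Runs [run_pr_sweep()] over the grid and locates the local maxima of the
#' entropy-rate curve. The control curve has two: an interior maximum at low
#' (theta-range) rates where the distribution spreads over all of
#' \[0, P_max\], and a high-frequency maximum where the peak slides into
#' zero. Maxima are located and refined by [locate_entropy_maxima()], since
#' a coarse grid cannot honestly place a maximum between its points.
#'
#' @inheritParams run_pr_sweep
#' @return A list with `curve` (the sweep summary tibble) and `maxima`, a
#'   tibble (`frequency_hz`, `entropy_bits`) of refined interior local
#'   maxima ordered by frequency (see [locate_entropy_maxima()]).
#' @export
run_entropy_curve <- function(params, freqs_hz, n = 2^14, discard = 100L,
                              nbins = 100L, seed = 1L) {
  sweep <- run_pr_sweep(params, sort(freqs_hz), n = n, discard = discard,
                        nbins = nbins, seed = seed)
  curve <- sweep$summary
  list(curve = curve,
       maxima = locate_entropy_maxima(curve$frequency_hz, curve$entropy_bits))
}

#' Locate interior local maxima of an entropy-rate curve
#'
#' Monte-Carlo noise of a few hundredths of a bit rides on the entropy
#' estimates, and the high-frequency maximum is a broad bump, so raw
#' three-point maxima are unreliable. The curve is first smoothed with a
#' centered running mean, interior local maxima of the smoothed curve are
#' found (a point that is the maximum of its `flank`-point neighborhood on
#' both sides, away from the grid edges), and each is then refined by a
#' least-squares quadratic fitted to the raw curve over `refine_halfwidth`
#' grid points on either side of the maximum. The quadratic vertex is the
#' reported location; it is clamped into its fitting window.
#'
#' @param freq_hz Ordered frequency grid, Hz.
#' @param entropy_bits Entropy at each grid frequency.
#' @param smooth_window Running-mean half-width in grid points (default 2,
#'   i.e. a 5-point window).
#' @param flank Neighborhood half-width defining a local maximum (default 3).
#' @param refine_halfwidth Half-width of the quadratic fitting window
#'   (default 8 grid points).
#' @param log_x Fit the refining parabola in `log10(frequency)`; appropriate
#'   on logarithmically spaced grids, where a window symmetric in grid
#'   points is asymmetric in Hz.
#' @return A tibble (`frequency_hz`, `entropy_bits`) of refined maxima,
#'   ordered by frequency; zero rows when the curve has no interior maximum.
#' @export
locate_entropy_maxima <- function(freq_hz, entropy_bits, smooth_window = 2L,
                                  flank = 3L, refine_halfwidth = 8L,
                                  log_x = FALSE) {
  n <- length(freq_hz)
  stopifnot(length(entropy_bits) == n)
  if (is.unsorted(freq_hz, strictly = TRUE)) {
    stop("`freq_hz` must be strictly increasing", call. = FALSE)
  }
  if (n < 2 * flank + 1) return(tibble::tibble(frequency_hz = numeric(0),
                                               entropy_bits = numeric(0)))
  ys <- running_mean(entropy_bits, smooth_window)
  idx <- integer(0)
  for (i in (flank + 1):(n - flank)) {
    window <- ys[(i - flank):(i + flank)]
    if (ys[i] == max(window) && ys[i] > window[1] && ys[i] > window[2 * flank + 1]) {
      # collapse plateau runs to their center
      if (length(idx) == 0 || i - idx[length(idx)] > flank) idx <- c(idx, i)
    }
  }
  rows <- lapply(idx, function(i) {
    lo <- max(1, i - refine_halfwidth)
    hi <- min(n, i + refine_halfwidth)
    x <- if (log_x) log10(freq_hz[lo:hi]) else freq_hz[lo:hi]
    x0 <- if (log_x) log10(freq_hz[i]) else freq_hz[i]
    ref <- refine_ls_quadratic(x, entropy_bits[lo:hi], x0)
    if (log_x) ref[1] <- 10^ref[1]
    ref
  })
  if (length(rows) == 0) {
    return(tibble::tibble(frequency_hz = numeric(0), entropy_bits = numeric(0)))
  }
  out <- do.call(rbind, rows)
  tibble::tibble(frequency_hz = out[, 1], entropy_bits = out[, 2])
}

running_mean <- function(y, half) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - half):min(n, i + half)])
  }, 0)
}

# Least-squares parabola over (x, y); returns c(vertex_x, vertex_y), the
# vertex clamped into the window (fallback: the raw grid point).
refine_ls_quadratic <- function(x, y, x_center) {
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  b <- unname(fit$coefficients)
  if (any(!is.finite(b)) || b[3] >= 0) {
    return(c(x_center, y[which.min(abs(x - x_center))]))
  }
  xv <- -b[2] / (2 * b[3])
  xv <- min(max(xv, min(x)), max(x))
  c(xv, b[1] + b[2] * xv + b[3] * xv^2)
}

#' Mean and peak of the Pr distribution versus mean rate
#'
#' Convenience wrapper around [run_pr_sweep()] returning the mean-response
#' and modal-response curves (and the deterministic fixed-point overlay) for
#' one condition.
#'
#' @inheritParams run_pr_sweep
#' @return The sweep summary tibble.
#' @export
run_mean_peak_curve <- function(params, freqs_hz, n = 2^14, discard = 100L,
                                nbins = 100L, seed = 1L) {
  run_pr_sweep(params, freqs_hz, n = n, discard = discard, nbins = nbins,
               seed = seed)$summary
}

#' Mutual information between response and preceding ISI versus mean rate
#'
#' For each rate: simulate the FD map over a Poisson train, draw stochastic
#' response amplitudes from the quantal model, and estimate
#' \eqn{I(S; T)} by histograms with Freedman-Diaconis binning
#' ([mi_psr_vs_preceding_isi()]).
#'
#' @inheritParams run_pr_sweep
#' @param model A [response_model()] (records `n_sites`, `mu`, `sigma`).
#' @return A tibble (`condition`, `frequency_hz`, `mi_bits`, `n`, `n_sites`,
#'   `seed`).
#' @export
run_mi_curve <- function(params, freqs_hz, model = response_model(),
                         n = 2^14, discard = 100L, seed = 1L) {
  if (is.character(params)) params <- fd_params(params)
  validate_fd_params(params)
  seeds <- derive_seeds(seed, 2L * length(freqs_hz))
  rows <- lapply(seq_along(freqs_hz), function(i) {
    f <- freqs_hz[i]
    train <- poisson_isis(f, n + discard, seed = seeds[2 * i - 1])
    ser <- simulate_fd_train(params, train, discard = discard)
    psr <- generate_psr_series(ser, model, seed = seeds[2 * i])
    tibble::tibble(
      condition = params$condition,
      frequency_hz = f,
      mi_bits = mi_psr_vs_preceding_isi(psr),
      n = n, n_sites = model$n_sites, seed = seeds[2 * i - 1]
    )
  })
  do.call(rbind, rows)
}

#' History-dependence of the response: MI versus history depth
#'
#' Measures how far back the synapse "remembers" its stimulation history at
#' one mean rate. In `"sum"` mode the history is collapsed to
#' \eqn{t_k = \sum_{i=1}^k T_i} and \eqn{I(S; t_k)} is estimated by
#' histograms from the stochastic response amplitudes
#' ([mi_vs_sum_history()]). In `"tuple"` mode the ordered n-tuple of
#' preceding ISIs is kept and \eqn{I(\langle T_1..T_n \rangle; Pr)} is
#' estimated with the KSG k-nearest-neighbor estimator on the deterministic
#' response ([mi_ntuple_history()]).
#'
#' @inheritParams run_mi_curve
#' @param freq_hz Single mean rate, Hz.
#' @param mode `"sum"` or `"tuple"`.
#' @param max_depth Largest history depth (`<= 8` in tuple mode).
#' @param k Neighbor order for the KSG estimator (tuple mode).
#' @return A tibble (`condition`, `frequency_hz`, `depth`, `mi_bits`,
#'   `estimator`, `seed`), plus `mi_nats` in tuple mode.
#' @export
run_history_mi <- function(params, freq_hz, mode = c("sum", "tuple"),
                           max_depth = 6L, model = response_model(),
                           n = 2^14, discard = 100L, k = 4L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(params)) params <- fd_params(params)
  validate_fd_params(params)
  if (length(freq_hz) != 1 || freq_hz <= 0) {
    stop("`freq_hz` must be a single positive rate", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 3L)
  train <- poisson_isis(freq_hz, n + discard, seed = seeds[1])
  ser <- simulate_fd_train(params, train, discard = discard)
  if (mode == "sum") {
    psr <- generate_psr_series(ser, model, seed = seeds[2])
    res <- mi_vs_sum_history(psr, max_depth)
    tibble::tibble(condition = params$condition, frequency_hz = freq_hz,
                   depth = res$depth, mi_bits = res$mi_bits,
                   estimator = "histogram_fd", seed = seeds[1])
  } else {
    res <- mi_ntuple_history(ser, depths = seq_len(max_depth), k = k,
                             seed = seeds[3])
    tibble::tibble(condition = params$condition, frequency_hz = freq_hz,
                   depth = res$depth, mi_bits = res$mi_bits,
                   mi_nats = res$mi_nats,
                   estimator = sprintf("ksg_k%d", k), seed = seeds[1])
  }
}

#' Default frequency grids for the sweeps
#'
#' `freq_grid_physio()`: 60 logarithmically spaced points on 0.1-100 Hz, the
#' physiological range (theta through gamma). `freq_grid_high()`: linear
#' 5 Hz steps on 50-1000 Hz for locating the high-frequency entropy maxima.
#'
#' @param n_points Number of points of the log grid.
#' @param from,to,by Range and step of the linear high-frequency grid.
#' @return Numeric frequency vector, Hz.
#' @export
freq_grid_physio <- function(n_points = 60) {
  10^seq(log10(0.1), log10(100), length.out = n_points)
}

#' @rdname freq_grid_physio
#' @export
freq_grid_high <- function(from = 50, to = 1000, by = 5) {
  seq(from, to, by = by)
}
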