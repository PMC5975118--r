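#' Freedman-Diaconis bin count
#'
#' Number of histogram bins from the Freedman-Diaconis rule,
#' \deqn{nbins = \frac{\max(x) - \min(x)}{2 \cdot Iqr \cdot n^{-1/3}},}
#' rounded up. The interquartile range makes the rule resistant to outliers.
#' When the interquartile range is zero (more than half the mass on one
#' value) the rule degenerates; the square-root rule is used instead, with a
#' warning.
#'
#' @param x Numeric samples (>= 4).
#' @return A positive integer bin count.
#' @examples
#' freedman_diaconis_nbins(runif(1000))
#' @export
freedman_diaconis_nbins <- function(x) {
  if (length(x) < 4) stop("need at least 4 samples", call. = FALSE)
  iqr <- stats::IQR(x)
  if (iqr == 0) {
    warning("zero interquartile range; falling back to square-root rule")
    return(max(1L, as.integer(ceiling(sqrt(length(x))))))
  }
  width <- 2 * iqr * length(x)^(-1 / 3)
  max(1L, as.integer(ceiling((max(x) - min(x)) / width)))
}

#' Bin samples into a normalized histogram
#'
#' `bin_samples()` produces the `binned_distribution` object consumed by the
#' entropy and mutual-information estimators: bin edges plus relative
#' frequencies. The `binning` argument is either the string `"fd"`
#' (Freedman-Diaconis, the default for response and ISI axes), a single bin
#' count, or an explicit vector of edges. `bin_fixed()` is the fixed
#' partition used for the normalized response `Pr`: `nbins` evenly spaced
#' bins spanning `range` (default 100 bins on \[0, 1\]), held constant across
#' conditions and frequencies so that entropies are comparable.
#'
#' @param x Numeric samples.
#' @param binning `"fd"`, a bin count, or an edge vector.
#' @param nbins Bin count for `bin_fixed()`.
#' @param range Support covered by the fixed partition.
#' @return A `binned_distribution`: list with `edges`, `probs`, `n`.
#' @export
bin_samples <- function(x, binning = "fd") {
  edges <- resolve_edges(x, binning)
  idx <- bin_index(x, edges)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  new_binned(edges, counts / length(x), length(x))
}

#' @rdname bin_samples
#' @export
bin_fixed <- function(x, nbins = 100, range = c(0, 1)) {
  bin_samples(x, seq(range[1], range[2], length.out = nbins + 1L))
}

new_binned <- function(edges, probs, n) {
  structure(list(edges = edges, probs = probs, n = n),
            class = "binned_distribution")
}

resolve_edges <- function(x, binning) {
  if (is.character(binning)) {
    binning <- match.arg(binning, "fd")
    nb <- freedman_diaconis_nbins(x)
    rng <- range(x)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    return(seq(rng[1], rng[2], length.out = nb + 1L))
  }
  if (length(binning) == 1) {
    nb <- as.integer(binning)
    if (nb < 1) stop("bin count must be >= 1", call. = FALSE)
    rng <- range(x)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    return(seq(rng[1], rng[2], length.out = nb + 1L))
  }
  if (is.unsorted(binning, strictly = TRUE)) {
    stop("explicit edges must be strictly increasing", call. = FALSE)
  }
  as.numeric(binning)
}

# Map samples to 1-based bin indices; both extremes clamped into the
# outer bins so that every sample is counted exactly once.
bin_index <- function(x, edges) {
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Shannon entropy of a binned distribution, in bits
#'
#' \deqn{H(X) = -\sum_x p(X = x) \log_2 p(X = x),}
#' with the convention \eqn{0 \log 0 = 0}. Accepts a `binned_distribution`
#' (see [bin_samples()]) or a bare probability vector.
#'
#' @param dist A `binned_distribution` or a numeric probability vector
#'   summing to 1.
#' @return Entropy in bits, between 0 and log2(number of occupied bins).
#' @examples
#' entropy_bits(rep(1 / 16, 16)) # 4 bits
#' @export
entropy_bits <- function(dist) {
  p <- if (inherits(dist, "binned_distribution")) dist$probs else dist
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("probabilities must be nonnegative and sum to 1", call. = FALSE)
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Joint entropy and mutual information from histograms, in bits
#'
#' `joint_entropy_bits()` bins the paired samples on a 2-D grid (each axis
#' binned independently per `binning`) and evaluates
#' \deqn{H(X, Y) = -\sum_x \sum_y p(x, y) \log_2 p(x, y).}
#' `mutual_information_hist()` combines marginal and joint entropies computed
#' on the *same* marginal partitions:
#' \eqn{I(X; Y) = H(X) + H(Y) - H(X, Y)}. It is symmetric in its arguments
#' and zero (in expectation) for independent inputs.
#'
#' @param x,y Paired numeric samples of equal length.
#' @param binning_x,binning_y Per-axis binning specs (see [bin_samples()]).
#' @return Entropy / mutual information in bits.
#' @examples
#' x <- runif(4096); y <- x + rnorm(4096, sd = 0.1)
#' mutual_information_hist(x, y)
#' @export
joint_entropy_bits <- function(x, y, binning_x = "fd", binning_y = "fd") {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  ex <- resolve_edges(x, binning_x)
  ey <- resolve_edges(y, binning_y)
  joint_entropy_from_edges(x, y, ex, ey)
}

joint_entropy_from_edges <- function(x, y, ex, ey) {
  ix <- bin_index(x, ex)
  iy <- bin_index(y, ey)
  nx <- length(ex) - 1L
  ny <- length(ey) - 1L
  counts <- tabulate(ix + nx * (iy - 1L), nbins = nx * ny)
  entropy_bits(counts / length(x))
}

#' @rdname joint_entropy_bits
#' @export
mutual_information_hist <- function(x, y, binning_x = "fd", binning_y = "fd") {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  ex <- resolve_edges(x, binning_x)
  ey <- resolve_edges(y, binning_y)
  hx <- entropy_bits(bin_samples(x, ex))
  hy <- entropy_bits(bin_samples(y, ey))
  hxy <- joint_entropy_from_edges(x, y, ex, ey)
  hx + hy - hxy
}

#' Mutual information between response and the preceding ISI
#'
#' Histogram estimate of \eqn{I(S; T) = H(S) + H(T) - H(S, T)} between the
#' stochastic postsynaptic response amplitude at each spike and the
#' inter-spike interval immediately preceding that spike, with
#' Freedman-Diaconis binning on both axes. This is the per-frequency quantity
#' behind the MI-versus-rate comparison of the two conditions.
#'
#' @param psr A `psr_series` (see [generate_psr_series()]), which carries the
#'   aligned `amplitude` and `isi_ms` columns, or a numeric vector of
#'   responses when `isis` is given.
#' @param isis Numeric ISIs aligned with `psr` (only when `psr` is a bare
#'   vector).
#' @return Mutual information in bits.
#' @export
mi_psr_vs_preceding_isi <- function(psr, isis = NULL) {
  if (is.data.frame(psr)) {
    s <- psr$amplitude
    t <- psr$isi_ms
  } else {
    s <- as.numeric(psr)
    t <- as.numeric(isis)
  }
  if (is.null(t) || length(s) != length(t)) {
    stop("response and preceding-ISI series must be aligned", call. = FALSE)
  }
  mutual_information_hist(s, t)
}

#' Mutual information between response and the sum of preceding ISIs
#'
#' For each history depth `k`, forms \eqn{t_k = \sum_{i=1}^{k} T_i}, the sum
#' of the `k` ISIs preceding each response, and estimates
#' \eqn{I(S; t_k) = H(S) + H(t_k) - H(S, t_k)} by histograms
#' (Freedman-Diaconis on both axes). Depth 1 coincides with
#' [mi_psr_vs_preceding_isi()]. The symmetric three-entropy form is used
#' rather than \eqn{H(S) - H(S \mid t_k)}; they are algebraically identical.
#'
#' @param psr A `psr_series` with aligned `amplitude` and `isi_ms`.
#' @param max_depth Largest history depth `M` (>= 1).
#' @return A tibble with columns `depth` and `mi_bits`.
#' @export
mi_vs_sum_history <- function(psr, max_depth) {
  stopifnot(is.data.frame(psr), max_depth >= 1)
  s <- psr$amplitude
  t <- psr$isi_ms
  n <- length(s)
  if (n - max_depth < 1000) {
    stop("series too short for the requested history depth", call. = FALSE)
  }
  csum <- cumsum(c(0, t))
  mi <- vapply(seq_len(max_depth), function(k) {
    idx <- k:n
    tk <- csum[idx + 1L] - csum[idx + 1L - k]  # sum of T_{i-k+1..i}
    mutual_information_hist(s[idx], tk)
  }, 0)
  tibble::tibble(depth = seq_len(max_depth), mi_bits = mi)
}
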