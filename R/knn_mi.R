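#' k-nearest-neighbor (Kozachenko-Leonenko) differential entropy
#'
#' Nonparametric entropy estimate from k-nearest-neighbor distances in the
#' max-norm,
#' \deqn{\hat H(X) = \psi(N) - \psi(k) + \log c_d +
#'   \frac{d}{N} \sum_{i=1}^{N} \log \epsilon(i),}
#' where \eqn{\epsilon(i)} is twice the distance from point `i` to its k-th
#' neighbor, \eqn{\psi} the digamma function and \eqn{c_d} the volume of the
#' d-dimensional unit ball (1 for the max-norm used here). No density
#' estimate is ever formed, which is what makes the estimator usable for the
#' higher-dimensional spike-history vectors.
#'
#' @param x Numeric matrix of `N` points in `d` columns (a vector is treated
#'   as one column).
#' @param k Neighbor order (default 4), `1 <= k < N`.
#' @param jitter Half-width of uniform noise added to break ties (default 0;
#'   duplicate points give a zero neighbor distance and an error).
#' @return Differential entropy in nats.
#' @examples
#' h <- kl_knn_entropy(matrix(runif(4096)), k = 4) # ~0 nats for U[0,1]
#' @export
kl_knn_entropy <- function(x, k = 4, jitter = 0) {
  x <- as_point_matrix(x, jitter)
  n <- nrow(x)
  if (k < 1 || k >= n) stop("need 1 <= k < number of points", call. = FALSE)
  eps <- 2 * knn_dist_cpp(x, as.integer(k))
  if (any(eps == 0)) {
    stop("duplicate points give zero neighbor distance; set `jitter` > 0",
         call. = FALSE)
  }
  digamma(n) - digamma(k) + ncol(x) / n * sum(log(eps))
}

#' KSG mutual information estimator
#'
#' Kraskov-Stoegbauer-Grassberger (variant 1) k-nearest-neighbor estimate of
#' the mutual information between `x` and `y`, in nats:
#' \deqn{\hat I(X; Y) = \psi(k) + \psi(N) -
#'   \bigl\langle \psi(n_x + 1) + \psi(n_y + 1) \bigr\rangle,}
#' where for each point the k-th neighbor is found in the joint space under
#' the max-norm and \eqn{n_x, n_y} count marginal neighbors strictly within
#' that distance. The estimator is approximately unbiased for independent
#' inputs and invariant under strictly monotone transformations of each
#' marginal.
#'
#' @param x,y Numeric matrices (or vectors) with the same number of rows.
#' @param k Neighbor order (default 4).
#' @param jitter Half-width of uniform tie-breaking noise (default 0).
#' @return Mutual information in nats (divide by `log(2)` for bits).
#' @examples
#' z <- matrix(rnorm(2000), ncol = 2)
#' ksg_mi(z[, 1], z[, 1] * 0.6 + z[, 2] * 0.8, k = 4)
#' @export
ksg_mi <- function(x, y, k = 4, jitter = 0) {
  x <- as_point_matrix(x, jitter)
  y <- as_point_matrix(y, jitter)
  n <- nrow(x)
  if (nrow(y) != n) stop("`x` and `y` must have the same number of points",
                         call. = FALSE)
  if (k < 1 || k >= n) stop("need 1 <= k < number of points", call. = FALSE)
  eps <- knn_dist_cpp(cbind(x, y), as.integer(k))
  if (any(eps == 0)) {
    stop("duplicate points give zero neighbor distance; set `jitter` > 0",
         call. = FALSE)
  }
  nx <- range_count_cpp(x, eps)
  ny <- range_count_cpp(y, eps)
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

as_point_matrix <- function(x, jitter = 0) {
  m <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  storage.mode(m) <- "double"
  if (jitter > 0) m <- m + runif(length(m), -jitter, jitter)
  m
}

#' Mutual information between response and the ordered n-tuple of
#' preceding ISIs
#'
#' Estimates \eqn{I(\langle T_1, \ldots, T_n \rangle; S)} — the information
#' the ordered sequence of the `n` ISIs preceding a spike carries about the
#' response at that spike — with the KSG estimator ([ksg_mi()]), which keeps
#' the full sequence structure that the sum-history measure
#' ([mi_vs_sum_history()]) collapses. The deterministic map output `Pr` is
#' used as the response, since it is a deterministic function of the entire
#' preceding history and therefore fixes the response side without
#' additional sampling noise.
#'
#' Every coordinate (each history ISI and the response) is standardized to
#' zero mean and unit variance before the k-nearest-neighbor search. The
#' estimator is invariant under such marginal rescaling only asymptotically;
#' at finite sample size a max-norm over raw coordinates is dominated by the
#' ISI axes (hundreds of ms against a response of order one), which starves
#' the response coordinate of resolution and collapses the estimate.
#'
#' @param pr_series A `pr_series` from [simulate_fd_train()] (columns
#'   `isi_ms`, `Pr`).
#' @param depths History depths to evaluate, each `<= 8` (the estimator
#'   degrades in higher dimension at these sample sizes).
#' @param k Neighbor order for [ksg_mi()].
#' @param jitter Tie-breaking jitter half-width (default `1e-10`).
#' @param seed Optional seed for the jitter.
#' @return A tibble with columns `depth`, `mi_nats`, `mi_bits`.
#' @export
mi_ntuple_history <- function(pr_series, depths = 1:6, k = 4,
                              jitter = 1e-10, seed = NULL) {
  stopifnot(is.data.frame(pr_series),
            all(c("isi_ms", "Pr") %in% names(pr_series)))
  if (any(depths < 1) || any(depths > 8)) {
    stop("history depths must lie in 1..8", call. = FALSE)
  }
  t <- pr_series$isi_ms
  pr <- pr_series$Pr
  n <- length(t)
  if (n - max(depths) < 100) {
    stop("series too short for the requested history depth", call. = FALSE)
  }
  res <- local_seed(seed, {
    vapply(depths, function(d) {
      idx <- d:n
      # ordered history: column j holds T_{i-d+j}, oldest first
      X <- vapply(seq_len(d), function(j) t[idx - d + j], numeric(length(idx)))
      ksg_mi(scale(matrix(X, ncol = d)), scale(pr[idx]), k = k,
             jitter = jitter)
    }, 0)
  })
  tibble::tibble(depth = as.integer(depths), mi_nats = res,
                 mi_bits = res / log(2))
}
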