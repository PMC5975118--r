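#' Synthetic presynaptic spike trains
#'
#' Generators for the inter-spike-interval (ISI) sequences that drive the FD
#' map. `poisson_isis()` draws i.i.d. exponential ISIs (a homogeneous Poisson
#' train) with the requested mean rate; `fixed_isis()` builds a constant-period
#' train for fixed-frequency stimulation protocols.
#'
#' Rates are specified in Hz at the interface and converted internally to
#' 1/ms, so a 5 Hz train has mean ISI 200 ms.
#'
#' @param rate_hz Mean firing rate in Hz (> 0).
#' @param n Number of ISIs to generate (>= 1).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and does not disturb the caller's RNG state.
#' @return An `isi_train` object: a list with elements `isis` (numeric, ms),
#'   `rate_hz`, `kind` (`"poisson"` or `"fixed"`) and `seed`.
#' @examples
#' tr <- poisson_isis(5, 1000, seed = 1)
#' mean(tr$isis) # close to 200 ms
#' @export
poisson_isis <- function(rate_hz, n, seed = NULL) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  isis <- local_seed(seed, rexp(n, rate = rate_hz / 1000))
  new_isi_train(isis, rate_hz = rate_hz, kind = "poisson", seed = seed)
}

#' @rdname poisson_isis
#' @param period_ms Constant inter-spike interval in ms (> 0).
#' @export
fixed_isis <- function(period_ms, n) {
  if (!is.numeric(period_ms) || length(period_ms) != 1 || period_ms <= 0) {
    stop("`period_ms` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  new_isi_train(rep(period_ms, as.integer(n)),
                rate_hz = 1000 / period_ms, kind = "fixed", seed = NULL)
}

new_isi_train <- function(isis, rate_hz, kind, seed) {
  structure(list(isis = as.numeric(isis), rate_hz = rate_hz,
                 kind = kind, seed = seed),
            class = "isi_train")
}

#' @export
print.isi_train <- function(x, ...) {
  cat(sprintf("%s ISI train: %d intervals, nominal rate %g Hz, mean ISI %.3g ms\n",
              x$kind, length(x$isis), x$rate_hz, mean(x$isis)))
  invisible(x)
}

as_isis <- function(x) {
  if (inherits(x, "isi_train")) return(x$isis)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected an `isi_train` or a numeric vector of ISIs", call. = FALSE)
}

#' Export or import an ISI train as CSV
#'
#' Writes two columns, `spike_index` and `isi_ms`.
#'
#' @param train An `isi_train` or numeric vector of ISIs in ms.
#' @param path CSV file path.
#' @return `write_isis()` returns `path` invisibly; `read_isis()` an
#'   `isi_train` of kind `"imported"`.
#' @export
write_isis <- function(train, path) {
  isis <- as_isis(train)
  utils::write.csv(data.frame(spike_index = seq_along(isis), isi_ms = isis),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isis
#' @export
read_isis <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("spike_index", "isi_ms") %in% names(df))) {
    stop("expected columns `spike_index` and `isi_ms`", call. = FALSE)
  }
  isis <- df$isi_ms[order(df$spike_index)]
  if (any(isis <= 0)) stop("ISIs must be positive", call. = FALSE)
  new_isi_train(isis, rate_hz = 1000 / mean(isis), kind = "imported",
                seed = NULL)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive per-task sub-seeds from one experiment seed, so that sweeps are
# reproducible element-wise regardless of grid order.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max, n))
}
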