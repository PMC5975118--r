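# Shared fixtures for the test suite. Everything is generated in code; the
# canonical parameter sets come from the package itself.

ctrl <- fd_params("control")
musc <- fd_params("muscarine")
# Frequency-sweep comparisons use the release-only muscarine variant
# (calcium dynamics shared with control, p_max reduced); see the methods
# vignette.
musc_sweep <- fd_params("muscarine", delta = 1)

# Build paired samples realizing an explicit 4x4 joint count table, with
# values placed at cell centers of the unit-spaced grid [0, 4] x [0, 4].
joint_table_samples <- function(counts) {
  stopifnot(nrow(counts) == 4, ncol(counts) == 4)
  x <- rep(rep(seq_len(4) - 0.5, times = 4), times = as.vector(counts))
  y <- rep(rep(seq_len(4) - 0.5, each = 4), times = as.vector(counts))
  list(x = x, y = y, edges = 0:4)
}

# Enumeration oracle: mutual information of a joint count table in bits,
# straight from the definition sum p log2(p / (px py)).
mi_enumeration_bits <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  total
}

# Entropy oracle for the same table, in bits.
entropy_enumeration_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}
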