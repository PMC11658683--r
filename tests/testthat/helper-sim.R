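# Small simulation configurations shared across test files.

small_marker_table <- function(markers_per_type = 10, effect = 1.5) {
  default_marker_table(markers_per_type = markers_per_type, effect = effect)
}

# balanced, single-replicate dataset small enough for unit tests
small_config <- function(n_cells_per_type = 60, markers_per_type = 10,
                         n_background_genes = 200, dp_fraction = 0.1,
                         effect = 1.5, seed = 101L, ...) {
  mt <- small_marker_table(markers_per_type, effect)
  simulate_config(
    n_cells_per_type = n_cells_per_type,
    marker_table = mt,
    n_background_genes = n_background_genes,
    dp_fraction = dp_fraction,
    mixture = uniform_mixture(unique(mt$cell_type)),
    n_samples_per_group = 1,
    seed = seed, ...)
}

# brute-force percentile: linear interpolation between order statistics,
# written independently of stats::quantile
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# O(n^2) pairwise AUC with half credit for ties
oracle_auc <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}
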