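# Fixture builders and independent oracles, all generated in code.

# A tiny multispectral raster with constant bands.
const_raster <- function(h = 8, w = 8, green = 0.5, blue = 0.3, res = 0.027) {
  bands <- list(
    blue = matrix(blue, h, w), green = matrix(green, h, w),
    red = matrix(0.2, h, w), rededge = matrix(0.3, h, w),
    nir = matrix(0.4, h, w))
  multispectral_raster(bands, res)
}

# Single-band index raster from a value matrix.
idx_raster <- function(values, res = 1) {
  index_raster(values, res)
}

# Exhaustive-enumeration within-cluster sum of squares oracle: tries every
# assignment of n points to k clusters. Independent of the ISODATA path.
exhaustive_wss <- function(x, k) {
  n <- length(x)
  stopifnot(k^n <= 6e5)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    w <- 0
    for (kk in unique(lab)) {
      v <- x[lab == kk]
      w <- w + sum(v^2) - sum(v)^2 / length(v)
    }
    if (w < best) best <- w
  }
  best
}

# WSS of a fitted cluster_map, recomputed from scratch.
cluster_wss <- function(cm, values_matrix) {
  w <- 0
  for (kk in seq_along(cm$means)) {
    v <- values_matrix[!is.na(cm$labels) & cm$labels == kk]
    w <- w + sum((v - mean(v))^2)
  }
  w
}

# Packaged 1-D clustering instances for the enumeration oracle.
# `separated` marks instances whose cluster gaps exceed the within spread.
clustering_instances <- function() {
  list(
    list(x = c(0, 0, 0, 10, 10, 10), k = 2L, separated = TRUE),
    list(x = c(0, 0.1, 0.2, 5, 5.1, 9.9, 10, 10.1), k = 3L, separated = TRUE),
    list(x = c(-0.70, -0.72, -0.68, -0.30, -0.28, 0.30, 0.32, 0.29, 0.31),
         k = 3L, separated = TRUE),
    list(x = seq(1, 12), k = 2L, separated = FALSE),
    list(x = c(0, 1, 2, 3, 4, 10, 11, 20, 21, 22), k = 3L, separated = TRUE)
  )
}

tiny_iso <- function(k) {
  iso_params(k = k, max_iterations = 50, change_tolerance = 1e-12,
             min_cluster_size = 1)
}

# High-precision Student-t upper-tail probability by quadrature of the
# density written out from its formula; independent of stats::pt.
t_upper_tail_quadrature <- function(t, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, lower = abs(t), upper = Inf,
                   rel.tol = 1e-12)$value
}
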