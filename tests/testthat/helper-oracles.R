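# Independent brute-force oracles used across tests.

# all-pairs O(n^2) semivariogram, straight from the definition
brute_semivariogram <- function(x, y, z, lag_width, max_dist) {
  kmax <- floor(max_dist / lag_width + 1e-9)
  gamma_sum <- numeric(kmax)
  np <- integer(kmax)
  dsum <- numeric(kmax)
  n <- length(z)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      k <- ceiling(d / lag_width - 1e-9)
      if (k >= 1 && k <= kmax) {
        gamma_sum[k] <- gamma_sum[k] + 0.5 * (z[i] - z[j])^2
        np[k] <- np[k] + 1L
        dsum[k] <- dsum[k] + d
      }
    }
  }
  keep <- np > 0L
  data.frame(lag = (seq_len(kmax) * lag_width)[keep],
             avg_dist = (dsum / np)[keep],
             gamma = (gamma_sum / np)[keep],
             np = np[keep])
}

# dense grid search over (nugget, psill, range) for WLS variogram fitting
brute_variogram_rss <- function(sv, family, n_grid = 40) {
  h <- sv$avg_dist
  g <- sv$gamma
  w <- sv$np
  basis <- function(h, A) {
    switch(family,
           exponential = 1 - exp(-3 * h / A),
           gaussian = 1 - exp(-3 * (h / A)^2),
           spherical = { hr <- pmin(h / A, 1); 1.5 * hr - 0.5 * hr^3 })
  }
  best <- Inf
  sill_max <- 2 * max(g)
  for (A in exp(seq(log(50), log(2 * 4700), length.out = n_grid))) {
    f <- basis(h, A)
    for (c0 in seq(0, sill_max, length.out = n_grid)) {
      for (c1 in seq(0, sill_max, length.out = n_grid)) {
        rss <- sum(w * (g - c0 - c1 * f)^2)
        if (rss < best) best <- rss
      }
    }
  }
  best
}

# exact semivariogram data generated from a known model (no noise)
exact_sv <- function(model, lags = seq(250, 4250, by = 500), np = 100) {
  data.frame(lag = lags, avg_dist = lags,
             gamma = model_gamma(model, lags), np = np)
}

# a small survey layer for kriging tests: irregular-ish values on a grid
small_layer <- function(n_side = 5, spacing = 500, seed = 42) {
  g <- location_grid((n_side - 1) * spacing, (n_side - 1) * spacing, spacing)
  set.seed(seed)
  data.frame(x = g$nodes$x, y = g$nodes$y,
             soc = exp(rnorm(nrow(g$nodes), 0.4, 0.35)))
}
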