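# shared fixtures: everything generated in code, nothing on disk

# a small aligned world: 80 m Gaussian hill whose centre coincides with a
# cell centre so the crest depth is exact
aligned_hill_config <- function(height = 80, radius = 1000) {
  generator_config(hills = list(hill_spec(4950, 4950, height, radius)),
                   extent_m = c(10000, 10000))
}

# reduced render params for fast tests
fast_render <- function(...) {
  render_params(width = 160, height = 110, agg_area_px = 80,
                agg_min_area_px = 30, ...)
}

fast_seg <- function(...) segmentation_params(min_area_px = 15, ...)

# brute-force BPI oracle: explicit distance test per cell pair
bpi_oracle <- function(grid, inner, outer, min_valid_frac = 0.5) {
  z <- grid$depths; s <- grid$cell_size
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  rmax <- floor(outer / s)
  n_annulus <- 0L
  for (di in -rmax:rmax) for (dj in -rmax:rmax) {
    d <- s * sqrt(di^2 + dj^2)
    if (d >= inner && d <= outer) n_annulus <- n_annulus + 1L
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -rmax:rmax) for (dj in -rmax:rmax) {
      d <- s * sqrt(di^2 + dj^2)
      if (d < inner || d > outer) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && !is.na(z[ii, jj]))
        vals <- c(vals, z[ii, jj])
    }
    if (length(vals) >= min_valid_frac * n_annulus)
      out[i, j] <- z[i, j] - mean(vals)
  }
  out
}

# Welch ANOVA oracle: direct evaluation of the published formulas,
# independent of the package implementation
welch_oracle <- function(groups) {
  n <- sapply(groups, length); m <- sapply(groups, mean)
  v <- sapply(groups, var); k <- length(groups)
  w <- n / v
  mw <- sum(w * m) / sum(w)
  num <- sum(w * (m - mw)^2) / (k - 1)
  tmp <- sum((1 - w / sum(w))^2 / (n - 1))
  den <- 1 + 2 * (k - 2) * tmp / (k^2 - 1)
  f <- num / den
  df2 <- (k^2 - 1) / (3 * tmp)
  list(f = f, df2 = df2, p = pf(f, k - 1, df2, lower.tail = FALSE))
}
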