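dip_grid <- function(drop_per_cell = 1, n = 12, cell = 100) {
  # plane dipping east: depth increases by drop_per_cell per cell
  z <- outer(rep(0, n), seq_len(n) * drop_per_cell, "+") + 4000
  bathy_grid(z, cell_size = cell)
}

test_that("slope: constant, dipping plane, gradient oracle on a hill", {
  flat <- bathy_grid(matrix(4850, 10, 10))
  s <- compute_slope(flat)
  expect_true(all(s[2:9, 2:9] == 0))
  expect_true(all(is.na(s[1, ])))

  sd1 <- compute_slope(dip_grid(1))
  expect_equal(max(abs(sd1[2:11, 2:11] - atan(0.01) * 180 / pi)), 0,
               tolerance = 1e-10)

  g <- make_bathymetry(aligned_hill_config())
  s <- compute_slope(g)
  imax <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, ]
  # max slope on the flank, not at the crest (4950, 4950 = cell [50, 50])
  dist_from_crest <- 100 * sqrt(sum((imax - c(50, 50))^2))
  expect_gt(dist_from_crest, 300)
  # independent central-difference oracle at the max-slope cell
  z <- g$depths; i <- imax[1]; j <- imax[2]
  gx <- (z[i, j + 1] - z[i, j - 1]) / 200
  gy <- (z[i + 1, j] - z[i - 1, j]) / 200
  oracle <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  expect_lt(abs(s[i, j] - oracle) / oracle, 0.01)
  expect_error(compute_slope(bathy_grid(matrix(NA_real_, 3, 3))), "nodata")
})

test_that("rugosity and curvature: closed forms and convexity", {
  flat <- bathy_grid(matrix(4850, 8, 8))
  expect_true(all(compute_rugosity(flat)[2:7, 2:7] == 1))
  expect_true(all(compute_curvature(flat)[2:7, 2:7] == 0))

  gd <- dip_grid(5)   # slope atan(0.05)
  r <- compute_rugosity(gd)
  expect_equal(max(abs(r[2:11, 2:11] - 1 / cos(atan(0.05)))), 0,
               tolerance = 1e-12)
  expect_true(all(compute_rugosity(make_bathymetry(aligned_hill_config())) >= 1,
                  na.rm = TRUE))
  cv <- compute_curvature(gd)
  expect_equal(max(abs(cv[2:11, 2:11])), 0, tolerance = 1e-12)

  # hill crest region is convex-up: negative profile curvature near the crest
  g <- make_bathymetry(aligned_hill_config())
  cvh <- compute_curvature(g)
  expect_lt(cvh[50, 46], 0)   # upper flank (crest cell is [50, 50])

  # quadratic-surface oracle: on an exact quadratic the finite-difference
  # coefficients are exact, so curvature equals the analytic directional
  # second derivative of elevation along the gradient
  n <- 15; cell <- 100
  xs <- cell * (seq_len(n) - 0.5); ys <- xs
  gx0 <- 0.02; gy0 <- -0.01; zxx <- -4e-5; zyy <- -1e-5; zxy <- 2e-5
  efun <- function(x, y) gx0 * x + gy0 * y +
    0.5 * zxx * x^2 + 0.5 * zyy * y^2 + zxy * x * y
  e <- outer(ys, xs, function(y, x) efun(x, y))
  gq <- bathy_grid(5000 - e, cell_size = cell)
  cvq <- compute_curvature(gq)
  i <- 8; j <- 8
  gx <- gx0 + zxx * xs[j] + zxy * ys[i]
  gy <- gy0 + zyy * ys[i] + zxy * xs[j]
  oracle <- (zxx * gx^2 + 2 * zxy * gx * gy + zyy * gy^2) / (gx^2 + gy^2)
  expect_equal(cvq[i, j], oracle, tolerance = 1e-10)
})

test_that("BPI: constant grid, single-cell construction, hill crest, oracle", {
  flat <- bathy_grid(matrix(4850, 30, 30))
  b <- compute_bpi(flat, 400, 1200)
  expect_true(all(b[!is.na(b)] == 0))
  expect_false(is.na(b[15, 15]))

  z <- matrix(4850, 30, 30); z[15, 15] <- 4840
  b1 <- compute_bpi(bathy_grid(z), 400, 1200)
  expect_equal(b1[15, 15], -10)

  g <- make_bathymetry(aligned_hill_config())
  bh <- compute_bpi(g)
  expect_lt(bh[50, 50], -25)

  # exhaustive annulus enumeration oracle, including a nodata hole
  set.seed(11)
  zr <- matrix(4800 + rnorm(30 * 30, 0, 15), 30, 30)
  zr[10:12, 20:25] <- NA
  gr <- bathy_grid(zr)
  expect_equal(compute_bpi(gr, 250, 600),
               bpi_oracle(gr, 250, 600), tolerance = 1e-12)

  # invariance to a constant depth offset
  g2 <- bathy_grid(zr + 100)
  expect_equal(compute_bpi(g2, 250, 600), compute_bpi(gr, 250, 600),
               tolerance = 1e-9)
  expect_error(compute_bpi(gr, 1200, 400), "outer")
})

test_that("primary/secondary classification: published combinations and coverage", {
  expect_equal(classify_primary(-50, 3), "Hill")
  expect_equal(classify_primary(0, 1), "Plain")
  expect_equal(classify_primary(60, 1), "Slope")
  expect_equal(classify_secondary(-150, 3), "Hill B")
  expect_equal(classify_secondary(-50, 1), "Hill D")
  expect_equal(classify_secondary(-50, 3), "Hill E")
  expect_equal(classify_secondary(0, 3), "Slope A")
  expect_equal(classify_secondary(60, 1), "Slope C")
  expect_equal(classify_secondary(60, 3), "Slope D")
  expect_equal(classify_secondary(0, 1), "Plain")
  expect_true(is.na(classify_primary(NA, 1)))

  # exhaustive sweep over band midpoints: 12 reachable classes, each input
  # maps to exactly one class, and secondary nests in primary
  bpis <- c(-150, -60, 10, 75)
  slopes <- c(1, 3, 7)
  grid <- expand.grid(bpi = bpis, slope = slopes)
  sec <- classify_secondary(grid$bpi, grid$slope)
  pri <- classify_primary(grid$bpi, grid$slope)
  expect_length(unique(sec), 12L)
  expect_false(anyNA(sec))
  nested <- ifelse(grepl("^Hill", sec), "Hill",
                   ifelse(sec == "Plain", "Plain", "Slope"))
  expect_equal(nested, pri)

  # boundary policy: BPI -25 and 50 fall in the middle band; slope 2 in [2,5]
  expect_equal(classify_secondary(-25, 1), "Plain")
  expect_equal(classify_secondary(50, 1), "Plain")
  expect_equal(classify_secondary(0, 2), "Slope A")
  expect_equal(classify_secondary(0, 5), "Slope A")
})

test_that("depth bands: half-open 12.5 m bins with terminal amalgamation", {
  # population shaped like the survey: sparse terminal bins, deep plain mode
  set.seed(5)
  depths <- c(runif(120, 4770, 4787.5),      # sparse shallowest bins
              runif(200, 4787.5, 4800),
              runif(200, 4800, 4812.5),
              runif(200, 4812.5, 4825),
              runif(200, 4825, 4837.5),
              runif(2000, 4837.5, 4850),     # the plain
              rep(4850.5, 10),               # sparse deepest bin
              4850)
  b <- assign_depth_band(depths, min_n = 50)
  expect_equal(levels(b)[1], "<4788")
  expect_true("4788-4800" %in% levels(b))
  expect_equal(levels(b)[length(levels(b))], ">4838")
  expect_equal(as.character(b[length(depths)]), ">4838")  # 4850.0

  # 4787.5 starts the [4787.5, 4800) band; 4800 belongs to the next band
  b2 <- assign_depth_band(c(rep(4780, 60), rep(4787.5, 60), rep(4800, 60),
                            rep(4805, 60)), min_n = 50)
  expect_equal(as.character(b2[61]), "4788-4800")
  expect_equal(as.character(b2[121]), "4800-4813")
  expect_equal(as.character(b2[181]), "4800-4813")
})
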