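#' @keywords internal
#' @noRd
.shift <- function(m, di, dj) {
  # shift matrix by (di, dj) filling with NA; result[i,j] = m[i+di, j+dj]
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
  ok_i <- ri >= 1 & ri <= nr; ok_j <- cj >= 1 & cj <= nc
  out[ok_i, ok_j] <- m[ri[ok_i], cj[ok_j]]
  out
}

.horn_gradient <- function(grid) {
  z <- grid$depths; s <- grid$cell_size
  n <- function(di, dj) .shift(z, di, dj)
  # Horn 3x3 weights; di = +1 is the row to the north (higher y)
  gx <- ((n(1, 1) + 2 * n(0, 1) + n(-1, 1)) -
           (n(1, -1) + 2 * n(0, -1) + n(-1, -1))) / (8 * s)
  gy <- ((n(1, 1) + 2 * n(1, 0) + n(1, -1)) -
           (n(-1, 1) + 2 * n(-1, 0) + n(-1, -1))) / (8 * s)
  list(gx = gx, gy = gy)
}

#' Seabed slope angle
#'
#' Horn 3x3 finite-difference gradient of the depth surface; slope is
#' atan(|grad z|) in degrees. Border cells (incomplete 3x3 neighbourhood)
#' are NA.
#'
#' @param grid a \code{\link{bathy_grid}}.
#' @return numeric matrix of slope angles (degrees).
#' @export
compute_slope <- function(grid) {
  if (all(is.na(grid$depths))) stop("all-nodata grid")
  g <- .horn_gradient(grid)
  atan(sqrt(g$gx^2 + g$gy^2)) * 180 / pi
}

#' Surface rugosity
#'
#' Ratio of triangulated 3x3 surface area to its planar projection. Eight
#' triangles fan from the cell centre to its eight neighbour centres; their
#' summed 3D area divided by the planar fan area (4 * cell^2) is >= 1, and
#' equals 1/cos(slope) on a uniform dipping plane.
#'
#' @param grid a \code{\link{bathy_grid}}.
#' @return numeric matrix of rugosity ratios (>= 1 where defined).
#' @export
compute_rugosity <- function(grid) {
  if (all(is.na(grid$depths))) stop("all-nodata grid")
  z <- grid$depths; s <- grid$cell_size
  # neighbour ring in CCW order: E, NE, N, NW, W, SW, S, SE
  ring <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
               c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  area3d <- 0
  for (k in seq_along(ring)) {
    a <- ring[[k]]; b <- ring[[(k %% 8L) + 1L]]
    # triangle (centre, neighbour a, neighbour b); elevation = -depth,
    # sign immaterial for area
    ax <- a[2] * s; ay <- a[1] * s; az <- .shift(z, a[1], a[2]) - z
    bx <- b[2] * s; by <- b[1] * s; bz <- .shift(z, b[1], b[2]) - z
    cx <- ay * bz - az * by
    cy <- az * bx - ax * bz
    cz <- ax * by - ay * bx
    area3d <- area3d + 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  area3d / (4 * s^2)
}

#' Profile curvature
#'
#' Zevenbergen-Thorne quadratic-surface profile curvature (curvature in the
#' direction of maximum slope), computed on the elevation surface
#' (-depth). Sign convention: convex-up (crests, hill flanks shedding
#' flow) is negative; flat or zero-gradient cells are 0.
#'
#' @param grid a \code{\link{bathy_grid}}.
#' @return numeric matrix of profile curvature (1/m).
#' @export
compute_curvature <- function(grid) {
  if (all(is.na(grid$depths))) stop("all-nodata grid")
  e <- -grid$depths; L <- grid$cell_size
  sh <- function(di, dj) .shift(e, di, dj)
  zD <- (sh(0, -1) + sh(0, 1)) / 2 - e     # d2/dx2 term * L^2
  zE <- (sh(1, 0) + sh(-1, 0)) / 2 - e
  D <- zD / L^2; E <- zE / L^2
  FF <- (-sh(1, -1) + sh(1, 1) + sh(-1, -1) - sh(-1, 1)) / (4 * L^2)
  G <- (sh(0, 1) - sh(0, -1)) / (2 * L)
  H <- (sh(1, 0) - sh(-1, 0)) / (2 * L)
  g2 <- G^2 + H^2
  out <- 2 * (D * G^2 + E * H^2 + FF * G * H) / g2
  out[!is.na(g2) & g2 == 0] <- 0
  out
}

#' Bathymetric position index (BPI)
#'
#' Difference between a cell's depth and the mean depth over an annulus of
#' cell centres at planar distance in [inner_radius_m, outer_radius_m]
#' (inclusive). Computed on positive-down depth, so crests (locally
#' shallow) yield negative BPI. Cells whose annulus has fewer than
#' \code{min_valid_frac} of its members valid are NA.
#'
#' @param grid a \code{\link{bathy_grid}}.
#' @param inner_radius_m,outer_radius_m annulus radii (m); defaults 400 and
#'   1200 m (4 and 12 cells at 100 m resolution).
#' @param min_valid_frac minimum valid fraction of annulus cells.
#' @return numeric matrix of BPI values (m, signed).
#' @export
compute_bpi <- function(grid, inner_radius_m = 400, outer_radius_m = 1200,
                        min_valid_frac = 0.5) {
  if (!(outer_radius_m > inner_radius_m && inner_radius_m > 0))
    stop("need outer_radius_m > inner_radius_m > 0")
  z <- grid$depths; s <- grid$cell_size
  rmax <- floor(outer_radius_m / s)
  offs <- expand.grid(di = -rmax:rmax, dj = -rmax:rmax)
  dist <- s * sqrt(offs$di^2 + offs$dj^2)
  offs <- offs[dist >= inner_radius_m & dist <= outer_radius_m, ]
  if (!nrow(offs)) stop("annulus contains no cells at this resolution")
  sum_m <- matrix(0, nrow(z), ncol(z))
  cnt_m <- matrix(0L, nrow(z), ncol(z))
  for (k in seq_len(nrow(offs))) {
    sm <- .shift(z, offs$di[k], offs$dj[k])
    ok <- !is.na(sm)
    sum_m[ok] <- sum_m[ok] + sm[ok]
    cnt_m <- cnt_m + ok
  }
  bpi <- z - sum_m / cnt_m
  bpi[cnt_m < min_valid_frac * nrow(offs)] <- NA_real_
  bpi
}

#' Primary terrain classification
#'
#' Hill/Slope/Plain from BPI (m) and slope angle (degrees): Hill where
#' BPI < -25; Plain where -25 <= BPI <= 50 and slope < 2 degrees; Slope
#' otherwise. NA in either input propagates.
#'
#' @param bpi,slope numeric vectors or matrices of equal shape.
#' @return character vector/matrix with values "Hill", "Slope", "Plain".
#' @export
classify_primary <- function(bpi, slope) {
  stopifnot(length(bpi) == length(slope))
  out <- rep(NA_character_, length(bpi))
  ok <- !is.na(bpi) & !is.na(slope)
  out[ok & bpi < -25] <- "Hill"
  out[ok & bpi >= -25 & bpi <= 50 & slope < 2] <- "Plain"
  out[ok & is.na(out)] <- "Slope"
  if (is.matrix(bpi)) out <- matrix(out, nrow(bpi), ncol(bpi))
  out
}

#' Secondary terrain classification
#'
#' Cross-classification of four BPI bands (< -100, [-100, -25), [-25, 50],
#' > 50) by three slope bands (< 2, [2, 5], > 5 degrees) into twelve
#' classes. The seven published combinations keep their published names
#' (Hill B, Hill D, Hill E, Slope A, Slope C, Slope D, Plain); the five
#' unobserved combinations are named by the same row-major scheme (Hill A,
#' Hill C, Hill F, Slope B, Slope E). Every secondary class nests in its
#' primary class.
#'
#' @param bpi,slope numeric vectors or matrices of equal shape.
#' @return character vector/matrix of class names.
#' @export
classify_secondary <- function(bpi, slope) {
  stopifnot(length(bpi) == length(slope))
  bband <- ifelse(bpi < -100, 1L,
           ifelse(bpi < -25, 2L,
           ifelse(bpi <= 50, 3L, 4L)))
  sband <- ifelse(slope < 2, 1L, ifelse(slope <= 5, 2L, 3L))
  key <- paste(bband, sband)
  map <- c("1 1" = "Hill A", "1 2" = "Hill B", "1 3" = "Hill C",
           "2 1" = "Hill D", "2 2" = "Hill E", "2 3" = "Hill F",
           "3 1" = "Plain",  "3 2" = "Slope A", "3 3" = "Slope B",
           "4 1" = "Slope C", "4 2" = "Slope D", "4 3" = "Slope E")
  out <- unname(map[key])
  out[is.na(bpi) | is.na(slope)] <- NA_character_
  if (is.matrix(bpi)) out <- matrix(out, nrow(bpi), ncol(bpi))
  out
}

#' Natural 12.5 m depth bands with terminal amalgamation
#'
#' Bins depths into half-open natural 12.5 m intervals
#' [12.5 k, 12.5 (k+1)), then merges terminal (shallowest/deepest) bins
#' inward until each terminal band holds at least \code{min_n}
#' observations, producing open-ended first and last bands. Labels display
#' bounds rounded to the nearest integer (half away from zero), e.g. the
#' bound 4787.5 prints as 4788.
#'
#' @param depth_m numeric vector of depths (m, > 0).
#' @param min_n minimum terminal-band count before amalgamation stops.
#' @param interval band width (m).
#' @return factor of band labels ordered shallow to deep, e.g.
#'   \code{"<4788"}, \code{"4788-4800"}, \code{">4838"}. Attribute
#'   \code{"breaks"} holds the exact interior bounds.
#' @export
assign_depth_band <- function(depth_m, min_n = 50, interval = 12.5) {
  stopifnot(all(depth_m > 0, na.rm = TRUE))
  k <- floor(depth_m / interval)
  ks <- sort(unique(k[!is.na(k)]))
  if (!length(ks)) return(factor(rep(NA_character_, length(depth_m))))
  counts <- sapply(ks, function(kk) sum(k == kk, na.rm = TRUE))
  lo <- 1L; hi <- length(ks)
  while (lo < hi && counts[lo] < min_n) {
    counts[lo + 1L] <- counts[lo + 1L] + counts[lo]; lo <- lo + 1L
  }
  while (hi > lo && counts[hi] < min_n) {
    counts[hi - 1L] <- counts[hi - 1L] + counts[hi]; hi <- hi - 1L
  }
  # band edges after amalgamation: ks[lo] .. ks[hi] interior bins remain
  kept <- ks[lo:hi]
  fmt <- function(x) sprintf("%d", floor(x + 0.5))
  labs <- character(length(kept))
  for (i in seq_along(kept)) {
    lo_b <- kept[i] * interval; hi_b <- (kept[i] + 1) * interval
    labs[i] <- if (i == 1L && lo > 1L) paste0("<", fmt(hi_b))
      else if (i == length(kept) && hi < length(ks)) paste0(">", fmt(lo_b))
      else paste0(fmt(lo_b), "-", fmt(hi_b))
  }
  band_of <- findInterval(k, c(-Inf, kept[-1], Inf))
  out <- factor(labs[band_of], levels = labs)
  attr(out, "breaks") <- kept * interval
  out
}
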