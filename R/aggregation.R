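#' Locate points in grid cells
#'
#' Half-open cell membership: a point belongs to cell \code{[i, j]} when
#' \code{x} lies in \code{[x0 + s (j-1), x0 + s j)} (likewise for y), so a
#' point exactly on a shared edge belongs to the higher-index cell.
#'
#' @param grid a \code{\link{bathy_grid}}.
#' @param x,y planar coordinates (m).
#' @return data.frame with integer columns \code{row, col}.
#' @export
locate_cell <- function(grid, x, y) {
  d <- dim(grid$depths); s <- grid$cell_size
  col <- floor((x - grid$origin[1]) / s) + 1L
  row <- floor((y - grid$origin[2]) / s) + 1L
  if (any(col < 1L | col > d[2] | row < 1L | row > d[1], na.rm = TRUE))
    stop("point(s) outside grid extent")
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Distance from the hill crest
#'
#' Euclidean planar distance to the crest point. Unless supplied, the
#' crest is the minimum-depth cell within the largest 8-connected
#' component of Hill-classified cells.
#'
#' @param grid a \code{\link{bathy_grid}}.
#' @param x,y planar coordinates (m) to measure from.
#' @param crest_xy optional length-2 crest coordinates; when \code{NULL} a
#'   primary-class matrix must be supplied via \code{primary_class}.
#' @param primary_class character matrix of primary classes (as from
#'   \code{\link{classify_primary}} on the same grid).
#' @return numeric vector of distances (m).
#' @export
distance_from_crest <- function(grid, x, y, crest_xy = NULL,
                                primary_class = NULL) {
  if (is.null(crest_xy)) {
    if (is.null(primary_class))
      stop("no crest configured and no primary classification supplied")
    hill <- !is.na(primary_class) & primary_class == "Hill"
    if (!any(hill)) stop("no Hill cells and no configured crest")
    lab <- label_components(hill)
    biggest <- which.max(tabulate(lab[lab > 0L]))
    z <- grid$depths
    z[lab != biggest] <- NA_real_
    idx <- which(z == min(z, na.rm = TRUE), arr.ind = TRUE)[1, ]
    cc <- cell_centers(grid)
    crest_xy <- c(cc$x[idx[2]], cc$y[idx[1]])
  }
  sqrt((x - crest_xy[1])^2 + (y - crest_xy[2])^2)
}

#' Average observations into bathymetric grid cells
#'
#' Computes arithmetic per-cell means of image total POM cover and of tile
#' biomass, applying the minimum-count inclusion filters per variable
#' independently: a cell contributes a POM mean only with at least
#' \code{min_images} images and a biomass mean only with at least
#' \code{min_tiles} tiles. Optional terrain attribute matrices are sampled
#' at each cell.
#'
#' @param grid a \code{\link{bathy_grid}}.
#' @param pom data.frame with columns \code{x, y, total} (per-image cover).
#' @param tiles data.frame with columns \code{x, y, biomass_total}.
#' @param terrain optional named list of matrices (e.g. \code{bpi, slope,
#'   rugosity, curvature}) and/or character matrices (classes), each
#'   matching the grid dimensions.
#' @param min_images,min_tiles inclusion thresholds (defaults 50 and 5).
#' @param crest_xy optional crest location for the distance covariate.
#' @return data.frame of occupied cells: \code{row, col, x, y, depth_m,
#'   n_images, mean_pom, n_tiles, mean_biomass}, one column per terrain
#'   attribute, and \code{dist_crest_m} when a crest is given. Means
#'   failing their inclusion filter are NA.
#' @export
summarise_cells <- function(grid, pom = NULL, tiles = NULL, terrain = NULL,
                            min_images = 50, min_tiles = 5,
                            crest_xy = NULL) {
  d <- dim(grid$depths)
  key <- function(loc) (loc$col - 1L) * d[1] + loc$row
  cells <- integer(0)
  pk <- tk <- NULL
  if (!is.null(pom) && nrow(pom)) {
    pk <- key(locate_cell(grid, pom$x, pom$y))
    cells <- union(cells, pk)
  }
  if (!is.null(tiles) && nrow(tiles)) {
    tk <- key(locate_cell(grid, tiles$x, tiles$y))
    cells <- union(cells, tk)
  }
  cells <- sort(cells)
  row <- (cells - 1L) %% d[1] + 1L
  col <- (cells - 1L) %/% d[1] + 1L
  cc <- cell_centers(grid)
  out <- data.frame(row = row, col = col, x = cc$x[col], y = cc$y[row],
                    depth_m = grid$depths[cbind(row, col)])
  out$n_images <- if (is.null(pk)) 0L else
    as.integer(tabulate(match(pk, cells), nbins = length(cells)))
  out$mean_pom <- NA_real_
  if (!is.null(pk)) {
    mp <- tapply(pom$total, match(pk, cells), mean)
    out$mean_pom[as.integer(names(mp))] <- as.numeric(mp)
  }
  out$mean_pom[out$n_images < min_images] <- NA_real_
  out$n_tiles <- if (is.null(tk)) 0L else
    as.integer(tabulate(match(tk, cells), nbins = length(cells)))
  out$mean_biomass <- NA_real_
  if (!is.null(tk)) {
    mb <- tapply(tiles$biomass_total, match(tk, cells), mean)
    out$mean_biomass[as.integer(names(mb))] <- as.numeric(mb)
  }
  out$mean_biomass[out$n_tiles < min_tiles] <- NA_real_
  for (nm in names(terrain))
    out[[nm]] <- terrain[[nm]][cbind(row, col)]
  if (!is.null(crest_xy))
    out$dist_crest_m <- distance_from_crest(grid, out$x, out$y,
                                            crest_xy = crest_xy)
  out
}

#' Assign turbidity records to water-column / BBL layers and depth bands
#'
#' Records with vehicle altitude <= 10 m above the seafloor are benthic
#' boundary layer (BBL); records above 10 m are water column. Depth bands
#' are natural 12.5 m intervals via \code{\link{assign_depth_band}}.
#'
#' @param records data.frame with columns \code{ftu, depth_m, altitude_m}.
#' @param min_n terminal depth-band amalgamation threshold.
#' @return the records with added \code{layer} ("BBL"/"water_column") and
#'   \code{depth_band} columns.
#' @export
layer_turbidity <- function(records, min_n = 50) {
  if (any(records$altitude_m < 0, na.rm = TRUE))
    stop("negative altitude")
  records$layer <- ifelse(records$altitude_m <= 10, "BBL", "water_column")
  records$depth_band <- assign_depth_band(records$depth_m, min_n = min_n)
  records
}
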