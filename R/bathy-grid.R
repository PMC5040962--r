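#' Bathymetric grid container
#'
#' A minimal raster container for gridded water depth: a numeric matrix of
#' depths (metres, positive down), a square cell size (metres) and a planar
#' origin (the outer corner of cell \[1, 1\]). Rows index northing (row 1 is
#' the southernmost row), columns index easting, so the centre of cell
#' \[i, j\] lies at \code{origin + cell_size * (c(j, i) - 0.5)}. Invalid
#' cells are stored as \code{NA}.
#'
#' @param depths numeric matrix of depths in metres, positive down.
#' @param cell_size cell edge length in metres; must be > 0.
#' @param origin numeric length-2, planar x/y of the grid corner in metres.
#' @param nodata value to convert to \code{NA} on construction (and written
#'   to file on export).
#' @return An object of class \code{bathy_grid}.
#' @export
bathy_grid <- function(depths, cell_size = 100, origin = c(0, 0),
                       nodata = -9999) {
  depths <- as.matrix(depths)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L) stop("`origin` must have length 2")
  storage.mode(depths) <- "double"
  depths[!is.na(depths) & depths == nodata] <- NA_real_
  if (any(depths[!is.na(depths)] <= 0))
    stop("depths must be positive (metres, positive down)")
  structure(
    list(depths = depths, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  d <- dim(x$depths)
  cat(sprintf("<bathy_grid> %d rows x %d cols, cell %g m\n", d[1], d[2],
              x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$origin[1], x$origin[1] + d[2] * x$cell_size,
              x$origin[2], x$origin[2] + d[1] * x$cell_size))
  rng <- range(x$depths, na.rm = TRUE)
  cat(sprintf("  depth: %.1f - %.1f m (%d NA cells)\n", rng[1], rng[2],
              sum(is.na(x$depths))))
  invisible(x)
}

#' @export
dim.bathy_grid <- function(x) dim(x$depths)

#' Planar coordinates of cell centres
#'
#' @param grid a \code{bathy_grid}.
#' @return list with vectors \code{x} (column centres) and \code{y} (row
#'   centres) in metres.
#' @export
cell_centers <- function(grid) {
  d <- dim(grid$depths)
  list(x = grid$origin[1] + grid$cell_size * (seq_len(d[2]) - 0.5),
       y = grid$origin[2] + grid$cell_size * (seq_len(d[1]) - 0.5))
}

#' Bilinear depth interpolation
#'
#' Samples the grid, treated as point values at cell centres, at arbitrary
#' planar positions. Positions between the outermost cell centres and the
#' grid edge are clamped to the border value.
#'
#' @param grid a \code{bathy_grid}.
#' @param x,y numeric vectors of planar coordinates (metres).
#' @return numeric vector of interpolated depths (m).
#' @export
interp_depth <- function(grid, x, y) {
  d <- dim(grid$depths); s <- grid$cell_size
  fx <- (x - grid$origin[1]) / s - 0.5   # 0-based column position
  fy <- (y - grid$origin[2]) / s - 0.5
  if (any(fx < -0.5 | fx > d[2] - 0.5 | fy < -0.5 | fy > d[1] - 0.5, na.rm = TRUE))
    stop("point(s) outside grid extent")
  fx <- pmin(pmax(fx, 0), d[2] - 1)
  fy <- pmin(pmax(fy, 0), d[1] - 1)
  j0 <- pmin(floor(fx), d[2] - 2); i0 <- pmin(floor(fy), d[1] - 2)
  tx <- fx - j0; ty <- fy - i0
  z00 <- grid$depths[cbind(i0 + 1, j0 + 1)]
  z01 <- grid$depths[cbind(i0 + 1, j0 + 2)]
  z10 <- grid$depths[cbind(i0 + 2, j0 + 1)]
  z11 <- grid$depths[cbind(i0 + 2, j0 + 2)]
  (1 - ty) * ((1 - tx) * z00 + tx * z01) + ty * ((1 - tx) * z10 + tx * z11)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/nodata_value` header followed by rows north to south). Values
#' are interpreted as depths in metres, positive down.
#'
#' @param grid a \code{bathy_grid}.
#' @param path file path.
#' @return \code{read_ascii_grid} returns a \code{bathy_grid};
#'   \code{write_ascii_grid} returns \code{path} invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  d <- dim(grid$depths)
  hdr <- c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.6f", grid$origin[1]),
           sprintf("yllcorner %.6f", grid$origin[2]),
           sprintf("cellsize %.6f", grid$cell_size),
           sprintf("NODATA_value %g", grid$nodata))
  m <- grid$depths
  m[is.na(m)] <- grid$nodata
  # ESRI ASCII rows run north -> south; our row 1 is southernmost
  rows <- apply(m[rev(seq_len(d[1])), , drop = FALSE], 1L,
                function(r) paste(format(r, trim = TRUE, digits = 10),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header")
  vals <- scan(text = paste(lines[(i + 1L):length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("grid body size does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]   # back to south-first rows
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  bathy_grid(m, cell_size = hdr$cellsize,
             origin = c(hdr$xllcorner, hdr$yllcorner), nodata = nodata)
}
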