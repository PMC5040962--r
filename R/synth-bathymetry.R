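#' Gaussian abyssal-hill specification
#'
#' Hills are modelled as isotropic Gaussian bumps rising from the plain:
#' elevation(d) = height * exp(-(d / radius)^2), where d is planar distance
#' from the hill centre and `radius` is the e-folding scale.
#'
#' @param center_x,center_y planar hill-centre coordinates (m).
#' @param height crest elevation above the plain (m, > 0). Hills of interest
#'   here are modest (tens of metres, < 80 m).
#' @param radius Gaussian e-folding scale (m, > 0).
#' @return a \code{hill_spec} list.
#' @export
hill_spec <- function(center_x, center_y, height, radius) {
  if (height <= 0) stop("hill height must be > 0")
  if (radius <= 0) stop("hill radius must be > 0")
  structure(list(center_x = center_x, center_y = center_y,
                 height = height, radius = radius), class = "hill_spec")
}

#' Synthetic survey generator configuration
#'
#' Bundles every tunable of the synthetic world. Defaults describe a 4850 m
#' abyssal plain with one 80 m Gaussian hill, surveyed photographically from
#' 3.2 m altitude with a 1.6 m2 image footprint, Hill/Slope/Plain true total
#' POM covers of 45.4 / 44.7 / 43.4 % and expected megafauna biomass of
#' 5.2 / 3.4 / 2.1 g fwwt m-2.
#'
#' @param plain_depth abyssal plain depth (m).
#' @param hills list of \code{\link{hill_spec}} objects.
#' @param cell_size bathymetric cell size (m).
#' @param extent_m numeric length-2, grid extent in x and y (m).
#' @param noise_sd small-amplitude depth noise (m; 0 disables).
#' @param line_spacing survey line spacing (m); the field campaign used
#'   1000 m (broad grid) and 100 m (high-resolution grids).
#' @param image_spacing_m along-track distance between images (m); at
#'   ~1.2 m/s and one frame every 0.9 s the field spacing is ~1 m.
#' @param altitude_m camera altitude (m).
#' @param footprint_m2 seafloor area imaged per (cropped) frame (m2).
#' @param cover_by_class named numeric, true total POM cover (%) per primary
#'   terrain class.
#' @param light_fraction fraction of total cover in the 'light' class.
#' @param biomass_by_class named numeric, expected tile biomass
#'   (g fwwt m-2) per primary class.
#' @param seed integer random seed; fixed seed implies byte-identical output.
#' @return a \code{generator_config} list.
#' @export
generator_config <- function(plain_depth = 4850,
                             hills = list(hill_spec(5000, 5000, 80, 1000)),
                             cell_size = 100,
                             extent_m = c(10000, 10000),
                             noise_sd = 0,
                             line_spacing = 1000,
                             image_spacing_m = 1,
                             altitude_m = 3.2,
                             footprint_m2 = 1.6,
                             cover_by_class = c(Hill = 45.4, Slope = 44.7,
                                                Plain = 43.4),
                             light_fraction = 0.5,
                             biomass_by_class = c(Hill = 5.2, Slope = 3.4,
                                                  Plain = 2.1),
                             seed = 1L) {
  if (plain_depth <= 0) stop("plain_depth must be > 0")
  if (cell_size <= 0) stop("cell_size must be > 0")
  stopifnot(all(cover_by_class >= 0), all(cover_by_class <= 100),
            all(biomass_by_class >= 0))
  structure(as.list(environment()), class = "generator_config")
}

#' Generate synthetic bathymetry
#'
#' Builds a \code{\link{bathy_grid}} as plain depth minus the sum of
#' Gaussian hill elevations, plus optional seeded Gaussian noise.
#'
#' @param config a \code{\link{generator_config}}.
#' @return a \code{bathy_grid}.
#' @export
make_bathymetry <- function(config) {
  s <- config$cell_size
  if (s <= 0) stop("cell_size must be > 0")
  for (h in config$hills)
    if (h$radius < s)
      stop("hill radius smaller than cell size: feature unresolvable")
  nx <- floor(config$extent_m[1] / s)
  ny <- floor(config$extent_m[2] / s)
  xc <- s * (seq_len(nx) - 0.5)
  yc <- s * (seq_len(ny) - 0.5)
  z <- matrix(config$plain_depth, nrow = ny, ncol = nx)
  for (h in config$hills) {
    dx2 <- outer(rep(1, ny), (xc - h$center_x)^2)
    dy2 <- outer((yc - h$center_y)^2, rep(1, nx))
    z <- z - h$height * exp(-(dx2 + dy2) / h$radius^2)
  }
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    z <- z + matrix(rnorm(ny * nx, 0, config$noise_sd), ny, nx)
  }
  bathy_grid(z, cell_size = s, origin = c(0, 0))
}

#' Generate a photographic survey track
#'
#' Lays boustrophedon survey lines (east-west, stepping north by
#' \code{line_spacing}) across the grid and drops an image every
#' \code{image_spacing_m} metres. Each image records position, bilinearly
#' interpolated seabed depth, altitude and footprint area.
#'
#' @param grid a \code{\link{bathy_grid}}.
#' @param config a \code{\link{generator_config}}.
#' @param margin_m standoff between track ends and the grid edge (m).
#' @return data.frame with columns \code{image_id, line, x, y, depth_m,
#'   altitude_m, footprint_m2}, in track order.
#' @export
make_survey <- function(grid, config, margin_m = grid$cell_size) {
  d <- dim(grid$depths); s <- grid$cell_size
  xmax <- grid$origin[1] + d[2] * s
  ymax <- grid$origin[2] + d[1] * s
  x0 <- grid$origin[1] + margin_m; x1 <- xmax - margin_m
  y0 <- grid$origin[2] + margin_m; y1 <- ymax - margin_m
  if (x1 <= x0 || y1 < y0) stop("track does not fit inside grid extent")
  ys <- seq(y0, y1, by = config$line_spacing)
  xs <- seq(x0, x1, by = config$image_spacing_m)
  out <- vector("list", length(ys))
  for (k in seq_along(ys)) {
    xk <- if (k %% 2L == 1L) xs else rev(xs)
    out[[k]] <- data.frame(line = k, x = xk, y = ys[k])
  }
  df <- do.call(rbind, out)
  df$image_id <- sprintf("img%06d", seq_len(nrow(df)))
  df$depth_m <- interp_depth(grid, df$x, df$y)
  df$altitude_m <- config$altitude_m
  df$footprint_m2 <- config$footprint_m2
  df[, c("image_id", "line", "x", "y", "depth_m", "altitude_m",
         "footprint_m2")]
}
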