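#' Group survey images into mosaic tiles
#'
#' Consecutive, non-overlapping groups of \code{group_size} images in track
#' order form one tile; a trailing incomplete group is dropped. Tile area
#' is the sum of member footprints, tile depth the mean member depth, and
#' the centroid the mean member position.
#'
#' @param images data.frame in track order with columns \code{image_id,
#'   footprint_m2} and optionally \code{x, y, depth_m}.
#' @param group_size images per tile (default 10).
#' @return data.frame with columns \code{tile_id, n_images, area_m2, x, y,
#'   depth_m, first_image, last_image}; zero rows (with a warning) if fewer
#'   than \code{group_size} images are supplied.
#' @export
mosaic_tiles <- function(images, group_size = 10) {
  n <- nrow(images)
  n_tiles <- n %/% group_size
  if (n_tiles == 0L) {
    warning("fewer than `group_size` images: no tiles produced")
    return(data.frame(tile_id = character(), n_images = integer(),
                      area_m2 = numeric(), x = numeric(), y = numeric(),
                      depth_m = numeric(), first_image = character(),
                      last_image = character(), stringsAsFactors = FALSE))
  }
  idx <- seq_len(n_tiles * group_size)
  grp <- rep(seq_len(n_tiles), each = group_size)
  getcol <- function(col, fun) {
    if (col %in% names(images))
      as.numeric(tapply(images[[col]][idx], grp, fun))
    else rep(NA_real_, n_tiles)
  }
  data.frame(
    tile_id = sprintf("tile%05d", seq_len(n_tiles)),
    n_images = group_size,
    area_m2 = as.numeric(tapply(images$footprint_m2[idx], grp, sum)),
    x = getcol("x", mean), y = getcol("y", mean),
    depth_m = getcol("depth_m", mean),
    first_image = images$image_id[idx[seq(1, by = group_size,
                                          length.out = n_tiles)]],
    last_image = images$image_id[idx[seq(group_size, by = group_size,
                                         length.out = n_tiles)]],
    stringsAsFactors = FALSE)
}

#' Allometric individual mass
#'
#' mass_g = a * L^b with morphotype-specific coefficients from the LUT and
#' L the image-measured body dimension in mm.
#'
#' @param morphotype character vector of morphotype labels.
#' @param L_mm numeric vector of body dimensions (mm, > 0).
#' @param lut morphotype LUT with columns \code{morphotype, a, b,
#'   feeding_type} (see \code{\link{demo_morphotypes}}).
#' @return numeric vector of individual masses (g fresh wet weight).
#' @export
estimate_mass <- function(morphotype, L_mm, lut) {
  if (any(L_mm <= 0)) stop("body dimension must be > 0")
  i <- match(morphotype, lut$morphotype)
  if (anyNA(i))
    stop("morphotype(s) missing from LUT: ",
         paste(unique(morphotype[is.na(i)]), collapse = ", "))
  lut$a[i] * L_mm^lut$b[i]
}

#' Tile-level biomass and density
#'
#' Converts annotations to individual masses via the LUT and accumulates
#' per-tile biomass (g fwwt m-2), partitioned by nominal feeding type, and
#' numerical density (individuals m-2). Tiles without annotations score
#' zero. Feeding-type components sum exactly to the total.
#'
#' @param annotations data.frame with columns \code{tile_id, morphotype,
#'   dimension_mm, count}.
#' @param tiles data.frame with columns \code{tile_id, area_m2}.
#' @param lut morphotype LUT (must also carry \code{feeding_type}).
#' @return data.frame keyed by \code{tile_id} with \code{biomass_total},
#'   one \code{biomass_<feeding_type>} column per nominal type,
#'   and \code{density}.
#' @export
tile_biomass <- function(annotations, tiles, lut) {
  if (any(tiles$area_m2 <= 0)) stop("tile area must be > 0")
  ftypes <- c("suspension", "deposit", "predator_scavenger", "other")
  out <- data.frame(tile_id = tiles$tile_id, biomass_total = 0,
                    stringsAsFactors = FALSE)
  for (ft in ftypes) out[[paste0("biomass_", ft)]] <- 0
  out$density <- 0
  if (nrow(annotations)) {
    bad <- setdiff(annotations$tile_id, tiles$tile_id)
    if (length(bad))
      stop("annotations reference unknown tile(s): ",
           paste(head(bad, 5), collapse = ", "))
    mass <- estimate_mass(annotations$morphotype, annotations$dimension_mm,
                          lut) * annotations$count
    ft <- lut$feeding_type[match(annotations$morphotype, lut$morphotype)]
    ti <- match(annotations$tile_id, tiles$tile_id)
    area <- tiles$area_m2[ti]
    for (f in ftypes) {
      sel <- ft == f
      if (!any(sel)) next
      acc <- tapply(mass[sel] / area[sel], annotations$tile_id[sel], sum)
      j <- match(names(acc), out$tile_id)
      out[[paste0("biomass_", f)]][j] <- as.numeric(acc)
    }
    dens <- tapply(annotations$count / area, annotations$tile_id, sum)
    out$density[match(names(dens), out$tile_id)] <- as.numeric(dens)
  }
  out$biomass_total <- rowSums(out[, paste0("biomass_", ftypes)])
  out
}

#' Log10 transform for biomass
#'
#' log10(x + c) with a small documented offset c so zero-biomass tiles stay
#' finite; by default c is half the smallest nonzero observation.
#'
#' @param biomass numeric vector (>= 0).
#' @param offset the constant c; \code{NULL} selects the default rule.
#' @return numeric vector; attribute \code{"offset"} records c.
#' @export
log_biomass <- function(biomass, offset = NULL) {
  if (any(biomass < 0, na.rm = TRUE)) stop("biomass must be >= 0")
  if (is.null(offset)) {
    nz <- biomass[!is.na(biomass) & biomass > 0]
    offset <- if (length(nz)) min(nz) / 2 else 1e-6
  }
  out <- log10(biomass + offset)
  attr(out, "offset") <- offset
  out
}
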