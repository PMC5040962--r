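#' Synthetic demonstration morphotype look-up table
#'
#' The real survey's allometric coefficients are unpublished, so the
#' package ships a clearly synthetic demonstration LUT: four morphotypes
#' spanning the nominal feeding types, each with allometric coefficients
#' (mass_g = a * L_mm^b), a body-dimension definition, and a lognormal
#' body-size distribution used by the generator.
#'
#' @return data.frame with columns \code{morphotype, feeding_type,
#'   dimension, a, b, size_meanlog, size_sdlog, expected_mass_g}; the last
#'   column is the analytic per-individual expected mass
#'   \code{a * exp(b * meanlog + b^2 sdlog^2 / 2)}.
#' @export
demo_morphotypes <- function() {
  lut <- data.frame(
    morphotype  = c("holothurian_A", "anemone_A", "ophiuroid_A",
                    "xenophyophore_A"),
    feeding_type = c("deposit", "suspension", "predator_scavenger", "other"),
    dimension   = c("body length", "oral disc diameter", "disc diameter",
                    "test diameter"),
    a = c(1e-4, 3e-4, 8e-4, 2e-4),
    b = c(2.5, 2.4, 2.2, 2.0),
    size_meanlog = log(c(60, 30, 15, 35)),
    size_sdlog   = c(0.40, 0.35, 0.30, 0.30),
    stringsAsFactors = FALSE)
  lut$expected_mass_g <-
    lut$a * exp(lut$b * lut$size_meanlog + lut$b^2 * lut$size_sdlog^2 / 2)
  lut
}

#' Per-class morphotype densities matching target biomass means
#'
#' Solves analytically for Poisson densities (individuals m-2) such that
#' the expected tile biomass per terrain class equals the configured class
#' mean. The biomass composition mirrors the field pattern: suspension
#' feeders contribute about five times more biomass on the Hill than on the
#' Plain.
#'
#' @param biomass_by_class named numeric, target expected biomass
#'   (g fwwt m-2) per class (names are terrain classes).
#' @param lut a morphotype LUT as from \code{\link{demo_morphotypes}}.
#' @return data.frame with columns \code{morphotype, class, density}.
#' @export
demo_densities <- function(biomass_by_class = c(Hill = 5.2, Slope = 3.4,
                                                Plain = 2.1),
                           lut = demo_morphotypes()) {
  if (any(biomass_by_class < 0)) stop("biomass targets must be >= 0")
  frac <- list(  # biomass fraction by feeding type, per class
    Hill  = c(deposit = 0.40, suspension = 0.35, predator_scavenger = 0.15,
              other = 0.10),
    Slope = c(deposit = 0.50, suspension = 0.25, predator_scavenger = 0.15,
              other = 0.10),
    Plain = c(deposit = 0.55, suspension = 0.17, predator_scavenger = 0.18,
              other = 0.10))
  out <- list()
  for (cls in names(biomass_by_class)) {
    fr <- if (cls %in% names(frac)) frac[[cls]] else frac$Plain
    dens <- fr[lut$feeding_type] * biomass_by_class[[cls]] /
      lut$expected_mass_g
    out[[cls]] <- data.frame(morphotype = lut$morphotype, class = cls,
                             density = as.numeric(dens),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Generate megafauna annotations for image tiles
#'
#' For each tile and morphotype, draws a Poisson number of individuals at
#' the class-specific density and lognormal body sizes, and records the
#' resulting true tile biomass (total and by feeding type) computed from
#' the same allometry the analysis uses.
#'
#' @param tiles data.frame with columns \code{tile_id, area_m2} (as from
#'   \code{\link{mosaic_tiles}}).
#' @param class_of_tile character vector, primary terrain class per tile.
#' @param lut morphotype LUT (see \code{\link{demo_morphotypes}}).
#' @param densities density table (see \code{\link{demo_densities}}).
#' @param seed integer seed.
#' @return list with \code{annotations} (data.frame \code{tile_id,
#'   morphotype, dimension_mm, count}) and \code{truth} (data.frame of true
#'   per-tile biomass, per feeding type, and individual counts).
#' @export
make_annotations <- function(tiles, class_of_tile, lut = demo_morphotypes(),
                             densities = demo_densities(), seed = 1L) {
  stopifnot(nrow(tiles) == length(class_of_tile))
  if (any(densities$density < 0)) stop("negative density")
  set.seed(seed)
  ftypes <- c("suspension", "deposit", "predator_scavenger", "other")
  ann <- vector("list", nrow(tiles))
  truth <- data.frame(tile_id = tiles$tile_id, biomass_total = 0,
                      biomass_suspension = 0, biomass_deposit = 0,
                      biomass_predator_scavenger = 0, biomass_other = 0,
                      density = 0, stringsAsFactors = FALSE)
  for (t in seq_len(nrow(tiles))) {
    area <- tiles$area_m2[t]
    dt <- densities[densities$class == class_of_tile[t], , drop = FALSE]
    rows <- list()
    for (m in seq_len(nrow(dt))) {
      n <- rpois(1, dt$density[m] * area)
      if (n == 0) next
      lrow <- lut[lut$morphotype == dt$morphotype[m], ]
      sizes <- rlnorm(n, lrow$size_meanlog, lrow$size_sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        tile_id = tiles$tile_id[t], morphotype = dt$morphotype[m],
        dimension_mm = sizes, count = 1L, stringsAsFactors = FALSE)
      # record truth with the generator's own arithmetic (per-mass / area)
      bm <- sum(lrow$a * sizes^lrow$b / area)
      col <- paste0("biomass_", lrow$feeding_type)
      truth[t, col] <- truth[t, col] + bm
      truth$density[t] <- truth$density[t] + n / area
    }
    if (length(rows)) ann[[t]] <- do.call(rbind, rows)
  }
  truth$biomass_total <- rowSums(truth[, paste0("biomass_", ftypes)])
  annotations <- do.call(rbind, ann)
  if (is.null(annotations))
    annotations <- data.frame(tile_id = character(), morphotype = character(),
                              dimension_mm = numeric(), count = integer())
  rownames(annotations) <- NULL
  list(annotations = annotations, truth = truth)
}
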