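#' Environment generator parameters
#'
#' Defaults describe the stated world: 21 coring sites split 12 elevated
#' (< 4840 m) / 9 plain (> 4840 m); sediment mud, total nitrogen (TN) and
#' total organic carbon (TOC) increasing with water depth (winnowing of
#' fines over elevated terrain), C/N with no depth trend; turbidity with a
#' common baseline in the water column and a benthic-boundary-layer (BBL)
#' enhancement over elevated terrain of about 6 % at full hill elevation
#' (within the observed 1.04-1.09 envelope).
#'
#' Reference values are set at the 4850 m plain: mud 85 %, TOC 0.36 %,
#' C/N 5.73 (mass ratio, TN follows as TOC / C/N). Slopes are per metre of
#' water depth.
#'
#' @param n_sites number of coring sites.
#' @param n_plain number of sites deeper than the 4840 m elevation split.
#' @param mud_ref,mud_slope,mud_sd mud % at 4850 m, trend (% per m), noise sd.
#' @param toc_ref,toc_slope,toc_sd TOC % at 4850 m, trend, noise sd.
#' @param tn_ref,tn_slope,tn_sd TN % at 4850 m, trend, noise sd; the
#'   default trend is proportional to the TOC trend so the C/N ratio
#'   carries no depth signal.
#' @param ftu_base water-column turbidity baseline (FTU).
#' @param ftu_sd turbidity sensor noise sd (FTU).
#' @param bbl_gain fractional BBL turbidity enhancement at full hill
#'   elevation (0.06 = six percent).
#' @param n_turbidity number of turbidity records.
#' @return an \code{env_params} list.
#' @export
env_params <- function(n_sites = 21, n_plain = 9,
                       mud_ref = 85, mud_slope = 0.29, mud_sd = 4,
                       toc_ref = 0.36, toc_slope = 0.00126, toc_sd = 0.015,
                       tn_ref = 0.063, tn_slope = 0.063 / 0.36 * 0.00126,
                       tn_sd = 0.0026,
                       ftu_base = 0.10, ftu_sd = 0.004,
                       bbl_gain = 0.06, n_turbidity = 10000) {
  structure(as.list(environment()), class = "env_params")
}

#' Generate sediment cores and turbidity records
#'
#' Sediment sites are placed on grid cells (plain sites deeper than 4840 m,
#' elevated sites shallower); mud, TN and TOC are linear in depth plus
#' independent noise, with the TN trend proportional to the TOC trend so
#' the C/N ratio (TOC/TN) carries no depth signal in expectation.
#' Turbidity records alternate between
#' water-column transit (altitude > 10 m) and near-bottom photo runs
#' (altitude <= 10 m); BBL records gain
#' \code{ftu_base * bbl_gain * elevation / max elevation} over the plain
#' baseline.
#'
#' @param grid a \code{\link{bathy_grid}}.
#' @param params an \code{\link{env_params}}.
#' @param seed integer seed.
#' @return list with \code{sediments} (data.frame \code{site_id, x, y,
#'   depth_m, mud, tn, toc, cn}) and \code{turbidity} (data.frame
#'   \code{ftu, depth_m, altitude_m}).
#' @export
make_environment <- function(grid, params = env_params(), seed = 1L) {
  set.seed(seed)
  cc <- cell_centers(grid)
  z <- grid$depths
  idx <- which(!is.na(z))
  deep <- idx[z[idx] > 4840]
  shal <- idx[z[idx] < 4840]
  n_elev <- params$n_sites - params$n_plain
  if (length(deep) < params$n_plain || length(shal) < n_elev)
    stop("grid does not contain enough plain/elevated cells for the sites")
  pick <- c(sample(deep, params$n_plain), sample(shal, n_elev))
  rc <- arrayInd(pick, dim(z))
  depth <- z[pick]
  dz <- depth - 4850
  toc <- pmax(params$toc_ref + params$toc_slope * dz +
                rnorm(params$n_sites, 0, params$toc_sd), 0.01)
  tn <- pmax(params$tn_ref + params$tn_slope * dz +
               rnorm(params$n_sites, 0, params$tn_sd), 0.001)
  sed <- data.frame(
    site_id = sprintf("site%02d", seq_len(params$n_sites)),
    x = cc$x[rc[, 2]], y = cc$y[rc[, 1]], depth_m = depth,
    mud = pmin(pmax(params$mud_ref + params$mud_slope * dz +
                      rnorm(params$n_sites, 0, params$mud_sd), 0), 100),
    tn = tn, toc = toc)
  sed$cn <- sed$toc / sed$tn

  # turbidity: AUV alternates transit legs (~100 m altitude) and photo runs
  n <- params$n_turbidity
  cell <- sample(idx, n, replace = TRUE)
  seabed <- z[cell]
  altitude <- ifelse(runif(n) < 0.5, 3.2, runif(n, 20, 120))
  elev <- pmax(max(seabed, na.rm = TRUE) - seabed, 0)
  elev_frac <- if (max(elev) > 0) elev / max(elev) else elev
  ftu <- params$ftu_base +
    ifelse(altitude <= 10, params$ftu_base * params$bbl_gain * elev_frac, 0) +
    rnorm(n, 0, params$ftu_sd)
  turb <- data.frame(ftu = ftu, depth_m = seabed, altitude_m = altitude)
  list(sediments = sed, turbidity = turb)
}
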