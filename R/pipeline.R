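#' Default pipeline configuration
#'
#' A small, fully-runnable demonstration configuration: a 5 x 5 km world
#' with one 60 m Gaussian hill, a 9-line photographic survey, reduced-
#' resolution image rendering, and the synthetic demonstration morphotype
#' table. All entries can be overridden via a YAML file
#' (\code{\link{read_pipeline_config}}) or by editing the returned list.
#'
#' @param seed integer master seed (mandatory for simulation).
#' @return nested list of class \code{pipeline_config}.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    generator = list(plain_depth = 4850,
                     hills = list(list(center_x = 2500, center_y = 2500,
                                       height = 60, radius = 800)),
                     cell_size = 100, extent_m = c(5000, 5000),
                     noise_sd = 0, line_spacing = 500, image_spacing_m = 25,
                     altitude_m = 3.2, footprint_m2 = 1.6,
                     cover_by_class = c(Hill = 45.4, Slope = 44.7,
                                        Plain = 43.4),
                     light_fraction = 0.5,
                     biomass_by_class = c(Hill = 5.2, Slope = 3.4,
                                          Plain = 2.1)),
    render = list(width = 120, height = 80, agg_area_px = 60,
                  agg_min_area_px = 20, tol_pp = 0.25),
    segmentation = list(k_light = 2, k_dark = 2, chroma_max = 0.25,
                        min_area_px = 12),
    bpi = list(inner_radius_m = 400, outer_radius_m = 1200),
    thresholds = list(min_images = 5, min_tiles = 2, band_min_n = 20,
                      elevation_threshold_m = 4840),
    tile_group_size = 10,
    lut = "demo",
    null_model = list(z_ref_m = 4850, z_m = 4780),
    environment = list(n_sites = 21, n_plain = 9)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a \code{pipeline_config} list.
#' @return \code{read_pipeline_config} returns a \code{pipeline_config};
#'   the writer returns \code{path} invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config(seed = cfg$seed %||% 1L)
  modifyList(base, cfg)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full survey analysis pipeline on synthetic data
#'
#' Executes simulate, terrain, pom, biomass, aggregate/stats and report
#' stages in order, writing versioned CSV outputs, the bathymetry as an
#' ESRI ASCII grid, and a run manifest (config hash, seed, per-file MD5
#' checksums). A rerun with the same configuration is byte-identical.
#'
#' @param config a \code{pipeline_config}
#'   (see \code{\link{default_pipeline_config}}).
#' @param outdir output directory (created if absent).
#' @return invisibly, a list with the principal in-memory results
#'   (\code{grid, survey, pom, tiles, tile_biomass, cells, class_table,
#'   sediment_table, observed_vs_predicted, manifest}).
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gc0 <- config$generator
  gcfg <- generator_config(
    plain_depth = gc0$plain_depth,
    hills = lapply(gc0$hills, function(h)
      hill_spec(h$center_x, h$center_y, h$height, h$radius)),
    cell_size = gc0$cell_size, extent_m = gc0$extent_m,
    noise_sd = gc0$noise_sd, line_spacing = gc0$line_spacing,
    image_spacing_m = gc0$image_spacing_m, altitude_m = gc0$altitude_m,
    footprint_m2 = gc0$footprint_m2,
    cover_by_class = unlist(gc0$cover_by_class),
    light_fraction = gc0$light_fraction,
    biomass_by_class = unlist(gc0$biomass_by_class),
    seed = config$seed)

  grid <- .stage("simulate/bathymetry", make_bathymetry(gcfg))
  write_ascii_grid(grid, file.path(outdir, "bathymetry.asc"))
  survey <- .stage("simulate/survey", make_survey(grid, gcfg))

  terr <- .stage("terrain", {
    slope <- compute_slope(grid)
    bpi <- compute_bpi(grid, config$bpi$inner_radius_m,
                       config$bpi$outer_radius_m)
    list(slope = slope, rugosity = compute_rugosity(grid),
         curvature = compute_curvature(grid), bpi = bpi,
         class1 = classify_primary(bpi, slope),
         class2 = classify_secondary(bpi, slope))
  })
  jsonlite::write_json(
    list(primary = c("Hill", "Slope", "Plain"),
         secondary = sort(unique(as.vector(
           terr$class2[!is.na(terr$class2)])))),
    file.path(outdir, "terrain_legend.json"), auto_unbox = FALSE)

  loc <- locate_cell(grid, survey$x, survey$y)
  survey$class1 <- terr$class1[cbind(loc$row, loc$col)]
  survey <- survey[!is.na(survey$class1), , drop = FALSE]

  rp <- do.call(render_params, config$render)
  sp <- do.call(segmentation_params,
                c(config$segmentation,
                  list(crop_dims = c(rp$width, rp$height))))
  pom <- .stage("pom", {
    covers <- gcfg$cover_by_class[survey$class1]
    res <- vector("list", nrow(survey))
    for (i in seq_len(nrow(survey))) {
      ri <- render_image(covers[i] * gcfg$light_fraction,
                         covers[i] * (1 - gcfg$light_fraction),
                         params = rp, seed = config$seed + i)
      r <- pom_cover(segment_pom(ri$image, sp), survey$image_id[i])
      r$true_total <- ri$truth$total
      res[[i]] <- r
    }
    cbind(do.call(rbind, res),
          survey[, c("x", "y", "depth_m", "class1")])
  })
  write.csv(pom, file.path(outdir, "pom_cover.csv"), row.names = FALSE)

  lut <- .stage("biomass/lut", {
    if (identical(config$lut, "demo")) demo_morphotypes()
    else {
      if (!file.exists(config$lut))
        stop("morphotype LUT file not found: ", config$lut)
      read.csv(config$lut, stringsAsFactors = FALSE)
    }
  })
  bio <- .stage("biomass", {
    tiles <- mosaic_tiles(survey, config$tile_group_size)
    tloc <- locate_cell(grid, tiles$x, tiles$y)
    tiles$class1 <- terr$class1[cbind(tloc$row, tloc$col)]
    dens <- demo_densities(gcfg$biomass_by_class, lut)
    ann <- make_annotations(tiles, tiles$class1, lut, dens,
                            seed = config$seed + 1L)
    tb <- tile_biomass(ann$annotations, tiles, lut)
    tb <- cbind(tb, tiles[, c("x", "y", "depth_m", "class1")])
    list(tiles = tiles, annotations = ann$annotations, truth = ann$truth,
         tile_biomass = tb)
  })
  write.csv(bio$annotations, file.path(outdir, "annotations.csv"),
            row.names = FALSE)
  write.csv(bio$tile_biomass, file.path(outdir, "tile_biomass.csv"),
            row.names = FALSE)

  agg <- .stage("aggregate", {
    cells <- summarise_cells(grid, pom = pom, tiles = bio$tile_biomass,
                             terrain = terr,
                             min_images = config$thresholds$min_images,
                             min_tiles = config$thresholds$min_tiles)
    cells$dist_crest_m <- tryCatch(
      distance_from_crest(grid, cells$x, cells$y,
                          primary_class = terr$class1),
      error = function(e) NA_real_)
    cells
  })
  write.csv(agg, file.path(outdir, "grid_cells.csv"), row.names = FALSE)

  stats_out <- .stage("stats", {
    keep2 <- function(g) g[vapply(g, length, 1L) >= 2L]
    pg <- keep2(split(logit_transform(pom$total, n = rp$width * rp$height),
                      pom$class1))
    bg <- keep2(split(log_biomass(bio$tile_biomass$biomass_total),
                      bio$tile_biomass$class1))
    list(pom_welch = welch_anova(pg), pom_gh = games_howell(pg),
         pom_levene = levene_test(pg),
         bio_welch = welch_anova(bg), bio_gh = games_howell(bg),
         bio_levene = levene_test(bg))
  })
  st <- data.frame(
    response = c("pom", "pom", "biomass", "biomass"),
    test = c("welch_anova", "levene", "welch_anova", "levene"),
    statistic = c(stats_out$pom_welch$statistic,
                  stats_out$pom_levene$statistic,
                  stats_out$bio_welch$statistic,
                  stats_out$bio_levene$statistic),
    p = c(stats_out$pom_welch$p, stats_out$pom_levene$p,
          stats_out$bio_welch$p, stats_out$bio_levene$p))
  write.csv(st, file.path(outdir, "stats_tests.csv"), row.names = FALSE)
  write.csv(rbind(cbind(response = "pom", stats_out$pom_gh),
                  cbind(response = "biomass", stats_out$bio_gh)),
            file.path(outdir, "games_howell.csv"), row.names = FALSE)

  env <- .stage("environment", {
    ep <- env_params(n_sites = config$environment$n_sites,
                     n_plain = config$environment$n_plain)
    e <- make_environment(grid, ep, seed = config$seed + 2L)
    list(sediments = e$sediments,
         sediment_table = sediment_report(
           e$sediments, config$thresholds$elevation_threshold_m),
         turbidity = turbidity_summary(
           layer_turbidity(e$turbidity,
                           min_n = config$thresholds$band_min_n)))
  })
  write.csv(env$sediment_table, file.path(outdir, "sediment_table.csv"),
            row.names = FALSE)
  write.csv(env$turbidity, file.path(outdir, "turbidity_summary.csv"),
            row.names = FALSE)

  report <- .stage("report", {
    cls_pom <- tapply(pom$total, pom$class1, mean)
    cls_bio <- tapply(bio$tile_biomass$biomass_total,
                      bio$tile_biomass$class1, mean)
    class_table <- data.frame(
      class = names(cls_pom),
      n_images = as.integer(table(pom$class1)[names(cls_pom)]),
      mean_pom = as.numeric(cls_pom),
      n_tiles = as.integer(table(bio$tile_biomass$class1)[names(cls_pom)]),
      mean_biomass = as.numeric(cls_bio[names(cls_pom)]))
    obs <- c(pom = unname(normalise_to_plain(cls_pom)["Hill"]),
             biomass = unname(normalise_to_plain(cls_bio)["Hill"]))
    pred <- c(pom = flux_factor(config$null_model$z_ref_m,
                                config$null_model$z_m),
              biomass = biomass_factor(config$null_model$z_ref_m,
                                       config$null_model$z_m))
    list(class_table = class_table,
         ovp = observed_vs_predicted(obs, pred))
  })
  write.csv(report$class_table, file.path(outdir, "class_table.csv"),
            row.names = FALSE)
  write.csv(report$ovp, file.path(outdir, "observed_vs_predicted.csv"),
            row.names = FALSE)

  cfg_path <- file.path(outdir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  outputs <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("abysshill")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    checksums = as.list(tools::md5sum(file.path(outdir, outputs))))
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(grid = grid, survey = survey, pom = pom,
                 tiles = bio$tiles, tile_biomass = bio$tile_biomass,
                 cells = agg, stats = stats_out,
                 sediment_table = env$sediment_table,
                 turbidity = env$turbidity,
                 class_table = report$class_table,
                 observed_vs_predicted = report$ovp, manifest = manifest))
}
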