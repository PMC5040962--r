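#' Rendering parameters for synthetic seabed photographs
#'
#' The renderer emulates what matters to the segmentation stage, not
#' photo-realism: a speckled sediment background, elliptical phytodetritus
#' aggregates of a brighter ('light') and a darker ('dark') colour class,
#' and optional radial illumination falloff.
#'
#' @param width,height image size in pixels. The default is a reduced-scale
#'   frame (240 x 160); cover is a pixel fraction so estimates are
#'   resolution-consistent provided aggregates remain much larger than the
#'   segmentation minimum object area.
#' @param bg_mean background sediment RGB mean (0-1).
#' @param bg_sd luminance speckle standard deviation.
#' @param light_delta,dark_delta luminance offsets of the two POM classes
#'   relative to the background.
#' @param agg_area_px mean aggregate area (pixels); areas are lognormal.
#' @param agg_area_sdlog lognormal sigma of aggregate area.
#' @param agg_min_area_px smallest aggregate the placer will draw; keep
#'   comfortably above the segmentation minimum object area.
#' @param axis_ratio_range range of ellipse minor/major axis ratios.
#' @param tol_pp placement tolerance: per-class mask fraction is brought
#'   within this many percentage points of target.
#' @param illum_falloff fractional radial illumination loss at the frame
#'   corner (0 disables).
#' @return a \code{render_params} list.
#' @export
render_params <- function(width = 240, height = 160,
                          bg_mean = c(0.42, 0.40, 0.36), bg_sd = 0.025,
                          light_delta = 0.28, dark_delta = -0.22,
                          agg_area_px = 120, agg_area_sdlog = 0.5,
                          agg_min_area_px = 40,
                          axis_ratio_range = c(0.4, 1),
                          tol_pp = 0.25, illum_falloff = 0) {
  stopifnot(width >= 8, height >= 8, tol_pp > 0)
  structure(as.list(environment()), class = "render_params")
}

# paint one ellipse onto an integer mask, converting only background (0)
# pixels to `value`; returns the updated mask plus the pixel count painted
.paint_ellipse <- function(mask, cx, cy, area, ratio, theta, value) {
  h <- nrow(mask); w <- ncol(mask)
  a <- sqrt(area / (pi * ratio))       # semi-major axis (px)
  b <- a * ratio
  r <- ceiling(a)
  ii <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  jj <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(ii) || !length(jj)) return(list(mask = mask, painted = 0L))
  dx <- outer(rep(1, length(ii)), jj - cx)
  dy <- outer(ii - cy, rep(1, length(jj)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- mask[ii, jj, drop = FALSE]
  hit <- inside & sub == 0L
  sub[hit] <- value
  mask[ii, jj] <- sub
  list(mask = mask, painted = sum(hit))
}

#' Render a synthetic seabed photograph with ground truth
#'
#' Places elliptical aggregates of the two POM colour classes onto a
#' speckled sediment background until the per-class mask fraction is within
#' \code{params$tol_pp} percentage points of target (never overshooting:
#' the last aggregate of each class is sized to the remaining deficit).
#' The returned mask is the truth definition: reported true covers are the
#' exact mask fractions.
#'
#' @param true_cover_light,true_cover_dark target covers (%); each >= 0 and
#'   their sum must not exceed 100.
#' @param params a \code{\link{render_params}}.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with \code{image} (height x width x 3 array in 0-1),
#'   \code{mask} (integer matrix, 0 background / 1 light / 2 dark) and
#'   \code{truth} (list \code{light, dark, total} in %, exact mask
#'   fractions).
#' @export
render_image <- function(true_cover_light, true_cover_dark,
                         params = render_params(), seed = 1L) {
  if (true_cover_light < 0 || true_cover_dark < 0)
    stop("target covers must be >= 0")
  if (true_cover_light + true_cover_dark > 100)
    stop("target covers must sum to <= 100")
  h <- params$height; w <- params$width; npix <- h * w
  if (params$agg_min_area_px > npix)
    stop("aggregate size exceeds image: target unreachable")
  set.seed(seed)
  mask <- matrix(0L, h, w)
  tol_px <- params$tol_pp / 100 * npix
  mulog <- log(params$agg_area_px) - params$agg_area_sdlog^2 / 2
  for (cls in 1:2) {
    target_px <- c(true_cover_light, true_cover_dark)[cls] / 100 * npix
    placed <- 0
    iter <- 0L
    while (target_px - placed > tol_px) {
      iter <- iter + 1L
      if (iter > 50000L) stop("aggregate placement failed to converge")
      deficit <- target_px - placed
      area <- rlnorm(1, mulog, params$agg_area_sdlog)
      area <- min(max(area, params$agg_min_area_px), deficit)
      ratio <- runif(1, params$axis_ratio_range[1], params$axis_ratio_range[2])
      res <- .paint_ellipse(mask, cx = runif(1, 1, w), cy = runif(1, 1, h),
                            area = area, ratio = ratio,
                            theta = runif(1, 0, pi), value = cls)
      mask <- res$mask
      placed <- placed + res$painted
    }
  }
  lum_noise <- matrix(rnorm(npix, 0, params$bg_sd), h, w)
  delta <- matrix(0, h, w)
  delta[mask == 1L] <- params$light_delta
  delta[mask == 2L] <- params$dark_delta
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- params$bg_mean[ch] + delta + lum_noise
  if (params$illum_falloff > 0) {
    cx <- (w + 1) / 2; cy <- (h + 1) / 2
    r2 <- outer(((seq_len(h) - cy) / (h / 2))^2,
                ((seq_len(w) - cx) / (w / 2))^2, "+")
    gain <- 1 - params$illum_falloff * r2 / max(r2)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * gain
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  truth <- list(light = 100 * sum(mask == 1L) / npix,
                dark = 100 * sum(mask == 2L) / npix)
  truth$total <- truth$light + truth$dark
  list(image = img, mask = mask, truth = truth)
}

#' Write / read an RGB image as PNG
#'
#' Thin optional wrappers around the \pkg{png} package for the on-disk
#' interface; the analysis itself operates on in-memory arrays.
#'
#' @param image height x width x 3 array in 0-1.
#' @param path file path.
#' @return \code{read_image_png} returns the array; writer returns
#'   \code{path} invisibly.
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG output")
  png::writePNG(image, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG input")
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
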