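#' Split sediment sites by terrain elevation
#'
#' Abyssal plain sites are deeper than the threshold (default 4840 m, the
#' primary hill-bounding contour); elevated-terrain sites are shallower. A
#' sample exactly at the threshold goes to the side named by
#' \code{boundary}, with a warning.
#'
#' @param samples data.frame with a \code{depth_m} column.
#' @param threshold_m split depth (m).
#' @param boundary side receiving samples exactly at the threshold.
#' @return list with data.frames \code{plain} and \code{elevated}.
#' @export
elevation_split <- function(samples, threshold_m = 4840,
                            boundary = c("plain", "elevated")) {
  boundary <- match.arg(boundary)
  at <- samples$depth_m == threshold_m
  if (any(at, na.rm = TRUE))
    warning(sum(at), " sample(s) exactly at the ", threshold_m,
            " m threshold assigned to ", boundary)
  plain <- samples$depth_m > threshold_m | (at & boundary == "plain")
  list(plain = samples[plain, , drop = FALSE],
       elevated = samples[!plain, , drop = FALSE])
}

#' Sediment parameter report
#'
#' For each of mud, TN, TOC and C/N: the median with a Wilcoxon
#' signed-rank confidence interval for all sites, plain sites and elevated
#' sites; the Spearman rank correlation with water depth; Mood's median
#' test comparing plain with elevated; and a least-squares linear trend
#' versus depth for plotting.
#'
#' @param samples data.frame with columns \code{depth_m, mud, tn, toc, cn}.
#' @param threshold_m elevation split depth (m).
#' @param conf_level nominal CI level.
#' @param ci_method achieved-level rule for
#'   \code{\link{wilcoxon_median_ci}}.
#' @return data.frame with one row per variable: medians and CIs (with
#'   achieved levels) for all/plain/elevated, \code{rs, rs_p} (Spearman
#'   vs depth), \code{chi2, chi2_p} (Mood's test), \code{slope,
#'   intercept} (trend vs depth).
#' @export
sediment_report <- function(samples, threshold_m = 4840, conf_level = 0.95,
                            ci_method = "normal") {
  if (nrow(samples) < 6) stop("need n >= 6 sediment samples")
  split <- elevation_split(samples, threshold_m)
  vars <- c("mud", "tn", "toc", "cn")
  rows <- lapply(vars, function(v) {
    ci_all <- wilcoxon_median_ci(samples[[v]], conf_level, ci_method)
    ci_pl <- wilcoxon_median_ci(split$plain[[v]], conf_level, ci_method)
    ci_el <- wilcoxon_median_ci(split$elevated[[v]], conf_level, ci_method)
    # degenerate (constant) variables yield NA statistics, not errors
    na_stat <- list(statistic = NA_real_, p = NA_real_)
    sp <- tryCatch(spearman_cor(samples$depth_m, samples[[v]]),
                   error = function(e) na_stat)
    md <- tryCatch(moods_median(split$plain[[v]], split$elevated[[v]]),
                   error = function(e) na_stat)
    tr <- linear_trend(samples$depth_m, samples[[v]])
    data.frame(variable = v, n = nrow(samples),
               median_all = ci_all$median, lo_all = ci_all$lo,
               hi_all = ci_all$hi, level_all = ci_all$level,
               n_plain = nrow(split$plain), median_plain = ci_pl$median,
               lo_plain = ci_pl$lo, hi_plain = ci_pl$hi,
               level_plain = ci_pl$level,
               n_elevated = nrow(split$elevated),
               median_elevated = ci_el$median, lo_elevated = ci_el$lo,
               hi_elevated = ci_el$hi, level_elevated = ci_el$level,
               rs = sp$statistic, rs_p = sp$p,
               chi2 = md$statistic, chi2_p = md$p,
               slope = tr$slope, intercept = tr$intercept,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Turbidity summary by depth band and layer
#'
#' Mean FTU with a t-based 95 percent confidence interval per (depth band
#' x layer) cell, then normalised within each layer by that layer's
#' reference (plain) band mean so the plain scores exactly 1. Optional
#' block averaging decimates the 2-second sensor series to temper serial
#' autocorrelation before CIs are computed.
#'
#' @param records layered turbidity records from
#'   \code{\link{layer_turbidity}} (columns \code{ftu, layer, depth_band}).
#' @param plain_band reference band label; default the deepest band
#'   present.
#' @param conf_level confidence level.
#' @param block optional block size (records) for block-mean decimation
#'   before summarising; \code{NULL} (default) uses raw records.
#' @return data.frame with \code{depth_band, layer, n, mean_ftu, lo, hi,
#'   norm, norm_lo, norm_hi}; empty band-layer cells are omitted.
#' @export
turbidity_summary <- function(records, plain_band = NULL,
                              conf_level = 0.95, block = NULL) {
  stopifnot(all(c("ftu", "layer", "depth_band") %in% names(records)))
  if (!is.null(block) && block > 1) {
    key <- paste(records$layer, records$depth_band)
    records <- do.call(rbind, lapply(split(records, key), function(d) {
      g <- (seq_len(nrow(d)) - 1L) %/% block
      data.frame(ftu = as.numeric(tapply(d$ftu, g, mean)),
                 layer = d$layer[1], depth_band = d$depth_band[1])
    }))
  }
  bands <- levels(factor(records$depth_band))
  if (is.null(plain_band)) plain_band <- bands[length(bands)]
  out <- list()
  for (ly in unique(records$layer)) {
    for (b in bands) {
      v <- records$ftu[records$layer == ly & records$depth_band == b]
      if (length(v) < 2) {
        if (length(v)) warning("band-layer cell with n < 2 omitted: ",
                               b, " / ", ly)
        next
      }
      se <- sd(v) / sqrt(length(v))
      tq <- qt((1 + conf_level) / 2, length(v) - 1)
      out[[paste(ly, b)]] <- data.frame(
        depth_band = b, layer = ly, n = length(v), mean_ftu = mean(v),
        lo = mean(v) - tq * se, hi = mean(v) + tq * se,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$norm <- NA_real_; out$norm_lo <- NA_real_; out$norm_hi <- NA_real_
  for (ly in unique(out$layer)) {
    ref <- out$mean_ftu[out$layer == ly & out$depth_band == plain_band]
    if (!length(ref)) {
      warning("no reference band for layer ", ly)
      next
    }
    sel <- out$layer == ly
    out$norm[sel] <- out$mean_ftu[sel] / ref
    out$norm_lo[sel] <- out$lo[sel] / ref
    out$norm_hi[sel] <- out$hi[sel] / ref
  }
  out
}
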