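#' Depth-only POC flux enhancement factor
#'
#' Martin-curve attenuation, flux proportional to Z^-0.7 with Z the water
#' depth in metres: the predicted flux at depth z relative to the
#' reference (plain) depth z_ref is (z_ref / z)^exponent. Factors exceed 1
#' for terrain shallower than the reference and compose multiplicatively
#' across depths.
#'
#' @param z_ref_m reference (plain) depth (m, > 0).
#' @param z_m comparison depth(s) (m, > 0).
#' @param exponent Martin-curve attenuation exponent (default 0.7).
#' @return numeric enhancement factor(s).
#' @export
flux_factor <- function(z_ref_m, z_m, exponent = 0.7) {
  if (any(z_ref_m <= 0) || any(z_m <= 0)) stop("depths must be > 0")
  (z_ref_m / z_m)^exponent
}

#' Depth-only megafauna biomass enhancement factor
#'
#' Standing-stock biomass proportional to 10^(-0.4 Z) with Z the water
#' depth in kilometres: the predicted biomass at depth z relative to z_ref
#' is 10^(slope (z_ref - z) / 1000).
#'
#' @param z_ref_m reference (plain) depth (m, > 0).
#' @param z_m comparison depth(s) (m, > 0).
#' @param slope attenuation slope per km of depth (default 0.4).
#' @return numeric enhancement factor(s).
#' @export
biomass_factor <- function(z_ref_m, z_m, slope = 0.4) {
  if (any(z_ref_m <= 0) || any(z_m <= 0)) stop("depths must be > 0")
  10^(slope * (z_ref_m - z_m) / 1000)
}

#' Normalise a series to its abyssal-plain value
#'
#' Divides every value by the plain entry so the plain maps to exactly 1.
#'
#' @param series named numeric vector (band or class means).
#' @param plain_key name of the plain entry.
#' @return named numeric vector of the same length and order.
#' @export
normalise_to_plain <- function(series, plain_key = "Plain") {
  if (!plain_key %in% names(series)) stop("missing plain key: ", plain_key)
  ref <- series[[plain_key]]
  if (is.na(ref) || ref <= 0) stop("plain value must be > 0")
  series / ref
}

#' Observed versus depth-only predicted enhancement
#'
#' Joins plain-normalised observed factors with the null-model predictions
#' per band or class and reports their ratio; ratios above 1 mean the
#' observation exceeds what depth alone predicts.
#'
#' @param observed named numeric vector of observed factors
#'   (plain-normalised).
#' @param predicted named numeric vector of predicted factors over the
#'   same keys.
#' @return data.frame with columns \code{key, observed, predicted, ratio}.
#' @export
observed_vs_predicted <- function(observed, predicted) {
  if (!setequal(names(observed), names(predicted)))
    stop("observed and predicted keys do not match")
  predicted <- predicted[names(observed)]
  data.frame(key = names(observed), observed = as.numeric(observed),
             predicted = as.numeric(predicted),
             ratio = as.numeric(observed) / as.numeric(predicted),
             stringsAsFactors = FALSE)
}
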