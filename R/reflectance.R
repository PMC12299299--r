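# Kubelka-Munk / Beer-Lambert theory layer.
#
# For an optically thick reagent pad the diffuse reflectance R relates to the
# ratio of absorption to scattering through the Kubelka-Munk function
#   K/S = (1 - R)^2 / (2 R),
# and Beer-Lambert makes the absorption coefficient proportional to analyte
# concentration, K = eps * C. This module encodes those relations exactly; the
# empirical bridge from camera color to concentration lives in the calibration
# and pipeline modules.

#' Kubelka-Munk function
#'
#' `ks_ratio(R)` returns K/S = (1-R)^2 / (2R) for reflectivity R in (0, 1].
#'
#' @param R reflectivity, in (0, 1]; vectorized.
#' @return the non-negative absorption/scattering ratio.
#' @export
ks_ratio <- function(R) {
  R <- as.numeric(R)
  if (any(!is.finite(R)) || any(R <= 0) || any(R > 1))
    stop("reflectivity must lie in (0, 1]", call. = FALSE)
  (1 - R)^2 / (2 * R)
}

#' Invert the Kubelka-Munk function
#'
#' Returns the unique root in (0, 1] of (1-R)^2/(2R) = ks, i.e.
#' `R = 1 + ks - sqrt(ks^2 + 2 ks)`.
#'
#' @param ks non-negative K/S ratio; vectorized.
#' @return reflectivity in (0, 1].
#' @export
reflectance_from_ks <- function(ks) {
  ks <- as.numeric(ks)
  if (any(!is.finite(ks)) || any(ks < 0))
    stop("K/S ratio must be non-negative", call. = FALSE)
  1 + ks - sqrt(ks^2 + 2 * ks)
}

#' Reflectance parameters
#'
#' @param S scattering coefficient of the pad matrix (> 0, arbitrary units).
#' @param epsilon molar absorptivity (> 0, per concentration unit).
#' @return an object of class `reflectance_params`.
#' @export
reflectance_params <- function(S, epsilon) {
  if (!is.finite(S) || S <= 0) stop("S must be > 0", call. = FALSE)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("epsilon must be > 0", call. = FALSE)
  structure(list(S = S, epsilon = epsilon), class = "reflectance_params")
}

#' Concentration from diffuse reflectance
#'
#' Combines Kubelka-Munk with Beer-Lambert: since K = eps * C and
#' K/S = (1-R)^2/(2R), the concentration is
#' `C = S * (1-R)^2 / (2 R eps)`. Strictly decreasing in R: a darker pad
#' means more analyte.
#'
#' @param R reflectivity in (0, 1]; vectorized.
#' @param params a [reflectance_params()].
#' @return concentration in the units implied by `epsilon`.
#' @export
concentration_from_reflectance <- function(R, params) {
  stopifnot(inherits(params, "reflectance_params"))
  params$S * ks_ratio(R) / params$epsilon
}
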