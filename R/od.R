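#' Convert an 8-bit RGB image to optical density
#'
#' Brightfield stains absorb light, so stain amounts mix (approximately)
#' linearly in optical density, not in raw intensity. Each channel is mapped
#' by the Beer-Lambert relation `OD = -log10((I + 1) / 256)`. The `+1` offset
#' keeps the result finite at `I = 0`, capping per-channel OD at
#' `log10(256) ~ 2.408`.
#'
#' @param rgb An `H x W x 3` array of intensities in `[0, 255]`, or any
#'   numeric array/vector of such intensities.
#' @return An array of the same shape holding non-negative optical densities.
#' @seealso [od_to_rgb()] for the inverse, [deconvolve()] for unmixing.
#' @export
#' @examples
#' rgb_to_od(c(255, 127, 0))
rgb_to_od <- function(rgb) {
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255)
    stop_tq("invalid_image", "intensities must lie in [0, 255]")
  -log10((rgb + 1) / 256)
}

#' Convert optical density back to 8-bit RGB
#'
#' Exact inverse of [rgb_to_od()] up to rounding:
#' `I = clamp(round(256 * 10^(-OD) - 1), 0, 255)` with half-up rounding.
#'
#' @param od A non-negative optical-density array.
#' @return An integer-valued array of intensities in `[0, 255]`.
#' @export
od_to_rgb <- function(od) {
  if (anyNA(od) || min(od) < 0)
    stop_tq("invalid_image", "optical densities must be finite and non-negative")
  clamp(round_half_up(256 * 10^(-od) - 1), 0, 255)
}
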