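#' @importFrom rlang abort warn %||%
#' @importFrom stats median sd quantile rnorm runif pnorm pt dnorm
#' @importFrom utils write.csv read.csv combn
NULL

# Round-half-up (ImageJ-style); base round() rounds half to even.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_tq <- function(class, message) {
  abort(message, class = c(paste0("tq_error_", class), "tq_error"))
}

#' @noRd
assert_rgb_image <- function(rgb, arg = "rgb") {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop_tq("invalid_image", sprintf("`%s` must be an H x W x 3 array.", arg))
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255)
    stop_tq("invalid_image", sprintf("`%s` must hold intensities in [0, 255].", arg))
  invisible(rgb)
}

assert_mask <- function(mask, dims = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_tq("invalid_mask", sprintf("`%s` must be a logical matrix.", arg))
  if (!is.null(dims) && !identical(dim(mask), as.integer(dims)))
    stop_tq("dimension_mismatch", sprintf("`%s` dimensions do not match the image.", arg))
  invisible(mask)
}
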