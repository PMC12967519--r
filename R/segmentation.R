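#' Gaussian blur of an 8-bit channel
#'
#' Separable Gaussian filter with reflective boundary handling, re-quantised
#' to `[0, 255]`. Used to homogenise the collagen channel before building the
#' connective-tissue mask, so that thin unstained cracks between collagen
#' bundles do not fragment it.
#'
#' @param channel `H x W` matrix of values in `[0, 255]`.
#' @param sigma Gaussian standard deviation in pixels (protocol default 2.0).
#' @return Blurred integer-valued matrix of the same size.
#' @export
gaussian_blur <- function(channel, sigma = 2.0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop_tq("invalid_sigma", "`sigma` must be a single positive number")
  out <- gaussian_blur_matrix(channel, sigma)
  out <- clamp(round_half_up(out), 0, 255)
  attr(out, "stain") <- attr(channel, "stain")
  out
}

# Float-valued separable Gaussian with symmetric (reflect) padding; shared by
# gaussian_blur() and the synthetic texture generator.
gaussian_blur_matrix <- function(x, sigma) {
  stopifnot(is.matrix(x))
  r <- max(1L, min(ceiling(4 * sigma), nrow(x) - 1L, ncol(x) - 1L))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    if (along_rows) m <- t(m)
    n <- nrow(m)
    idx <- c(seq_len(r)[r:1], seq_len(n), n + 1L - seq_len(r))  # reflect incl. edge
    mp <- m[idx, , drop = FALSE]
    acc <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) acc <- acc + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    if (along_rows) t(acc) else acc
  }
  conv1(conv1(x, FALSE), TRUE)
}

#' Build a 256-bin histogram of an 8-bit channel
#'
#' @param channel `H x W` matrix of values in `[0, 255]`.
#' @param region Optional logical matrix restricting the counted pixels.
#' @param ignore_black If `TRUE`, bin 0 is zeroed before return — the
#'   protocol's "ignore black" option, which discards unstained pixels so the
#'   bright background does not drag the auto-threshold down.
#' @return An object of class `histogram256`: list of `counts` (length 256)
#'   and `total`.
#' @export
build_histogram <- function(channel, region = NULL, ignore_black = FALSE) {
  stopifnot(is.matrix(channel))
  vals <- if (is.null(region)) as.vector(channel) else {
    assert_mask(region, dim(channel), "region")
    channel[region]
  }
  if (length(vals) == 0L) stop_tq("empty_region", "region selects no pixels")
  counts <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  if (ignore_black) counts[1L] <- 0L
  structure(list(counts = counts, total = sum(counts)), class = "histogram256")
}

#' Iterative-intermeans ("Default") auto-threshold
#'
#' The classic isodata-style fixed point: starting from the midpoint of the
#' occupied gray range, iterate `t <- round((mean of values <= t + mean of
#' values > t) / 2)` (half-up rounding) until stable. Foreground is defined
#' as values strictly greater than `t`.
#'
#' @param hist A `histogram256` from [build_histogram()].
#' @return Integer threshold in `[0, 255]`.
#' @export
default_threshold <- function(hist) {
  stopifnot(inherits(hist, "histogram256"))
  counts <- as.numeric(hist$counts)
  occ <- which(counts > 0) - 1L
  if (length(occ) < 2L)
    stop_tq("degenerate_histogram", "histogram needs at least two occupied bins")
  lv <- 0:255
  t <- round_half_up((min(occ) + max(occ)) / 2)
  for (i in 1:256) {
    lo <- lv <= t
    n_lo <- sum(counts[lo]); n_hi <- sum(counts[!lo])
    if (n_lo == 0 || n_hi == 0) break
    mu_lo <- sum(counts[lo] * lv[lo]) / n_lo
    mu_hi <- sum(counts[!lo] * lv[!lo]) / n_hi
    t_new <- round_half_up((mu_lo + mu_hi) / 2)
    if (t_new == t) break
    t <- t_new
  }
  as.integer(t)
}

#' Threshold an 8-bit channel into a binary mask
#'
#' @param channel `H x W` matrix in `[0, 255]`.
#' @param t Threshold in `[0, 255]`; pixels with value `> t` are foreground.
#' @param region Optional logical matrix; foreground is intersected with it.
#' @return Logical `H x W` matrix.
#' @export
apply_threshold <- function(channel, t, region = NULL) {
  stopifnot(is.matrix(channel), length(t) == 1L, t >= 0, t <= 255)
  m <- channel > t
  if (!is.null(region)) {
    assert_mask(region, dim(channel), "region")
    m <- m & region
  }
  m
}

# 3x3 dilation/erosion via padded shifts. `pad` is the value assumed outside
# the image: FALSE (background) for dilation; erosion inside closing() pads
# with TRUE so that closing never removes border pixels (extensivity).
morph3 <- function(mask, op = c("dilate", "erode"), pad) {
  op <- match.arg(op)
  H <- nrow(mask); W <- ncol(mask)
  mp <- matrix(pad, H + 2L, W + 2L)
  mp[2:(H + 1L), 2:(W + 1L)] <- mask
  acc <- NULL
  for (dr in 0:2) for (dc in 0:2) {
    s <- mp[(1L + dr):(H + dr), (1L + dc):(W + dc)]
    acc <- if (is.null(acc)) s else if (op == "dilate") acc | s else acc & s
  }
  acc
}

#' Binary closing (dilation then erosion)
#'
#' 3x3 square structuring element, repeated `iterations` times. Fills the
#' natural cracks between collagen bundles so the tissue mask is a
#' consolidated region. Outside-image pixels count as background for the
#' dilation and as foreground for the erosion, so the result always contains
#' the input (`closing(X) >= X`), including at image borders.
#'
#' @param mask Logical `H x W` matrix.
#' @param iterations Number of dilate/erode rounds (default 1).
#' @return Logical matrix containing `mask`.
#' @export
binary_closing <- function(mask, iterations = 1L) {
  assert_mask(mask)
  stopifnot(iterations >= 1L)
  for (i in seq_len(iterations)) {
    mask <- morph3(mask, "dilate", pad = FALSE)
    mask <- morph3(mask, "erode", pad = TRUE)
  }
  mask
}

#' Build the connective-tissue mask from the collagen channel
#'
#' The protocol's mask pipeline: Gaussian blur (sigma 2.0), histogram with
#' black ignored, iterative-intermeans threshold, then binary closing. The
#' chosen threshold is attached as attribute `threshold`.
#'
#' @param blue_channel 8-bit collagen (blue-green) stain channel.
#' @param sigma Blur sigma in pixels.
#' @param iterations Closing iterations.
#' @return Logical mask with attribute `threshold`.
#' @export
build_tissue_mask <- function(blue_channel, sigma = 2.0, iterations = 1L) {
  blurred <- gaussian_blur(blue_channel, sigma)
  t <- default_threshold(build_histogram(blurred, ignore_black = TRUE))
  mask <- binary_closing(apply_threshold(blurred, t), iterations)
  attr(mask, "threshold") <- t
  mask
}

#' Pixelwise AND of two masks
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return Logical matrix `a & b`.
#' @export
combine_and <- function(a, b) {
  assert_mask(a, arg = "a"); assert_mask(b, arg = "b")
  if (!identical(dim(a), dim(b)))
    stop_tq("dimension_mismatch", "masks have different dimensions")
  a & b
}
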