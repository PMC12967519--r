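#' Convert a pixel count to a calibrated area
#'
#' @param pixel_count Number of pixels (>= 0).
#' @param px_per_mm Pixels per millimetre; default 473, the calibration of a
#'   4x objective setup where 1 mm spans 473 pixels.
#' @return Area in mm^2: `pixel_count / px_per_mm^2`.
#' @export
#' @examples
#' area_mm2(473^2)  # exactly 1 mm^2
area_mm2 <- function(pixel_count, px_per_mm = 473) {
  stopifnot(pixel_count >= 0, px_per_mm > 0)
  pixel_count / px_per_mm^2
}

#' Intensity-distribution statistics of a channel over a region
#'
#' Reports the gray-value statistics the protocol measures inside each
#' thresholded stain region. Conventions follow the original measurement
#' tool: `sd` uses the `n - 1` denominator while skewness and excess
#' kurtosis use population moments about the mean
#' (`skew = m3 / m2^(3/2)`, `kurt = m4 / m2^2 - 3`). Shape statistics are
#' `NaN` for constant regions.
#'
#' @param channel `H x W` 8-bit matrix.
#' @param region Non-empty logical matrix.
#' @return One-row tibble: `n, mean, median, sd, min, max, skewness, kurtosis`.
#' @export
region_stats <- function(channel, region) {
  stopifnot(is.matrix(channel))
  assert_mask(region, dim(channel), "region")
  x <- as.numeric(channel[region])
  if (length(x) == 0L) stop_tq("empty_region", "region selects no pixels")
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  tibble::tibble(
    n = n, mean = mu, median = median(x),
    sd = if (n > 1) sd(x) else 0,
    min = min(x), max = max(x),
    skewness = if (m2 > 0) m3 / m2^1.5 else NaN,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else NaN
  )
}

empty_stats <- function() {
  tibble::tibble(n = 0L, mean = NA_real_, median = NA_real_, sd = NA_real_,
                 min = NA_real_, max = NA_real_, skewness = NA_real_,
                 kurtosis = NA_real_)
}

#' Run the full histomorphometry pipeline on one image
#'
#' Deconvolves the image into the two stain channels, builds the
#' connective-tissue mask from the blurred collagen channel, auto-thresholds
#' each stain channel (black ignored), restricts each thresholded stain to
#' the mask with a pixelwise AND, and measures calibrated areas, ratios and
#' intensity statistics inside the AND regions.
#'
#' @param rgb `H x W x 3` intensity array in `[0, 255]`.
#' @param basis A [stain_basis()]; default [trichrome_basis()].
#' @param px_per_mm Spatial calibration (pixels per millimetre).
#' @param sigma Blur sigma for the tissue mask.
#' @param closing_iterations Binary-closing iterations for the tissue mask.
#' @param image_id Identifier recorded in the output rows.
#' @param threshold_within_mask If `TRUE`, per-stain thresholds are computed
#'   on the mask-restricted histogram instead of the whole image (the
#'   protocol's ordering — threshold first, AND second — is the default).
#' @return An object of class `trichrome_features`: list with
#'   * `features`: tibble, one row per stain, columns `image_id, stain,
#'     mask_area_mm2, thresh_area_mm2, thresh_to_mask_pct, mask_to_image_pct,
#'     mean, median, sd, min, max, skewness, kurtosis`;
#'   * `paired`: one-row tibble `image_id, red_to_blue_area_pct,
#'     sum_to_mask_pct`;
#'   * `masks`: list of logical matrices (`tissue`, per-stain AND regions);
#'   * `thresholds`: the auto-thresholds chosen (mask and per stain).
#' @export
extract_features <- function(rgb, basis = trichrome_basis(), px_per_mm = 473,
                             sigma = 2.0, closing_iterations = 1L,
                             image_id = "image", threshold_within_mask = FALSE) {
  assert_rgb_image(rgb)
  conc <- deconvolve(rgb, basis)
  labels <- c(basis$stain1$label, basis$stain2$label)
  ch <- list(concentration_to_channel(conc[, , 1], labels[1]),
             concentration_to_channel(conc[, , 2], labels[2]))
  names(ch) <- labels

  tissue <- build_tissue_mask(ch[[1]], sigma = sigma, iterations = closing_iterations)
  mask_px <- sum(tissue)
  n_px <- length(tissue)

  thresholds <- c(mask = attr(tissue, "threshold"))
  and_masks <- list()
  rows <- vector("list", 2L)
  for (i in 1:2) {
    hist_region <- if (threshold_within_mask) tissue else NULL
    # a channel with (near) no signal has a degenerate histogram: that stain
    # is simply absent, so its thresholded region is empty
    t_i <- tryCatch(
      default_threshold(build_histogram(ch[[i]], region = hist_region,
                                        ignore_black = TRUE)),
      tq_error_degenerate_histogram = function(e) NA_integer_)
    thresholds[labels[i]] <- t_i
    m_i <- if (is.na(t_i)) matrix(FALSE, nrow(tissue), ncol(tissue)) else
      combine_and(apply_threshold(ch[[i]], t_i), tissue)
    and_masks[[labels[i]]] <- m_i
    st <- if (any(m_i)) region_stats(ch[[i]], m_i) else empty_stats()
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(
        image_id = image_id, stain = labels[i],
        mask_area_mm2 = area_mm2(mask_px, px_per_mm),
        thresh_area_mm2 = area_mm2(sum(m_i), px_per_mm),
        thresh_to_mask_pct = if (mask_px > 0) 100 * sum(m_i) / mask_px else NA_real_,
        mask_to_image_pct = 100 * mask_px / n_px
      ),
      st[, c("mean", "median", "sd", "min", "max", "skewness", "kurtosis")]
    )
  }
  features <- dplyr::bind_rows(rows)

  blue_px <- sum(and_masks[[1]]); red_px <- sum(and_masks[[2]])
  paired <- tibble::tibble(
    image_id = image_id,
    red_to_blue_area_pct = if (blue_px > 0) 100 * red_px / blue_px else NA_real_,
    sum_to_mask_pct = if (mask_px > 0) 100 * (blue_px + red_px) / mask_px else NA_real_
  )

  structure(list(features = features, paired = paired,
                 masks = c(list(tissue = tissue), and_masks),
                 thresholds = thresholds, image_id = image_id),
            class = "trichrome_features")
}

#' @export
print.trichrome_features <- function(x, ...) {
  cat(sprintf("<trichrome_features> %s  (thresholds: %s)\n", x$image_id,
              paste(names(x$thresholds), x$thresholds, sep = "=", collapse = ", ")))
  print(x$features)
  invisible(x)
}

#' @export
tidy.trichrome_features <- function(x, ...) x$features

#' Plot the masks produced by the pipeline
#'
#' Panelled raster view of the tissue mask and the two mask-restricted
#' thresholded stain regions.
#'
#' @param object A `trichrome_features` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trichrome_features <- function(object, ...) {
  df <- purrr::imap_dfr(object$masks, function(m, nm) {
    idx <- which(m, arr.ind = TRUE)
    tibble::tibble(panel = nm, y = idx[, 1], x = idx[, 2])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(fill = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(title = object$image_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
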