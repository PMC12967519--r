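#' Read an 8-bit RGB image
#'
#' PNG and TIFF are read natively; JPEG requires the `EBImage` package.
#' Grayscale images are expanded to three channels and any alpha channel is
#' dropped.
#'
#' @param path Image file (`.png`, `.tif(f)`, `.jpg`/`.jpeg`).
#' @return `H x W x 3` array of integers in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_tq("io_failure", sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop_tq("io_failure", "JPEG input requires the EBImage package")
      img <- EBImage::readImage(path)
      aperm(array(EBImage::imageData(img),
                  dim = c(dim(img)[1], dim(img)[2],
                          if (length(dim(img)) == 3) dim(img)[3] else 1)),
            c(2, 1, 3))
    },
    stop_tq("io_failure", sprintf("unsupported image format: .%s", ext))
  )
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1L) x <- array(rep(x, 3), dim = c(dim(x)[1:2], 3))
  clamp(round_half_up(x * 255), 0, 255)
}

#' Write an 8-bit RGB image
#'
#' @param rgb `H x W x 3` array in `[0, 255]`.
#' @param path Output path (`.png` or `.tif(f)`).
#' @return `path`, invisibly.
#' @export
write_image <- function(rgb, path) {
  assert_rgb_image(rgb)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(rgb / 255, path),
    tif = , tiff = tiff::writeTIFF(rgb / 255, path, bits.per.sample = 8L),
    stop_tq("io_failure", sprintf("unsupported output format: .%s", ext))
  )
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read named ROIs from a plain-text file
#'
#' Each non-comment line defines one ROI, 0-based with top-left origin:
#' * rectangle (half-open intervals): `label x y width height`
#' * polygon: `label polygon x1 y1 x2 y2 ...` (>= 3 vertices)
#'
#' @param path ROI file.
#' @return Named list of ROI descriptors (`type`, plus geometry fields).
#' @seealso [roi_mask()] to rasterise one ROI.
#' @export
read_roi_file <- function(path) {
  if (!file.exists(path)) stop_tq("io_failure", sprintf("no such file: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rois <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) >= 2 && tok[2] == "polygon") {
      xy <- as.numeric(tok[-(1:2)])
      if (length(xy) < 6 || length(xy) %% 2 != 0 || anyNA(xy))
        stop_tq("io_failure", sprintf("bad polygon ROI line: %s", ln))
      rois[[tok[1]]] <- list(type = "polygon",
                             x = xy[seq(1, length(xy), 2)],
                             y = xy[seq(2, length(xy), 2)])
    } else if (length(tok) == 5) {
      v <- as.numeric(tok[2:5])
      if (anyNA(v) || v[3] <= 0 || v[4] <= 0)
        stop_tq("io_failure", sprintf("bad rectangle ROI line: %s", ln))
      rois[[tok[1]]] <- list(type = "rect", x = v[1], y = v[2],
                             width = v[3], height = v[4])
    } else stop_tq("io_failure", sprintf("unparseable ROI line: %s", ln))
  }
  rois
}

#' Rasterise one ROI descriptor to a logical mask
#'
#' @param roi One element of [read_roi_file()]'s result.
#' @param height,width Image dimensions in pixels.
#' @return Logical `height x width` matrix.
#' @export
roi_mask <- function(roi, height, width) {
  m <- matrix(FALSE, height, width)
  if (roi$type == "rect") {
    # 0-based, half-open: pixel columns x .. x+width-1 (0-based)
    cols <- (roi$x + 1):(roi$x + roi$width)
    rows <- (roi$y + 1):(roi$y + roi$height)
    cols <- cols[cols >= 1 & cols <= width]
    rows <- rows[rows >= 1 & rows <= height]
    m[rows, cols] <- TRUE
  } else {
    # even-odd ray casting at pixel centers (0-based centers = index - 1)
    px <- rep(seq_len(width) - 1, each = height)
    py <- rep(seq_len(height) - 1, width)
    vx <- roi$x; vy <- roi$y; nv <- length(vx)
    inside <- rep(FALSE, length(px))
    j <- nv
    for (i in seq_len(nv)) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- xor(inside, crosses)
      j <- i
    }
    m <- matrix(inside, height, width)
  }
  m
}

#' Read a run configuration from YAML
#'
#' Recognised keys (all optional; missing keys fall back to the built-in
#' defaults): `stain1`, `stain2` (length-3 numeric), `stain_labels`,
#' `roi_file`, `sigma`, `closing_iterations`, `px_per_mm`, `alpha`, `seed`,
#' `threshold_within_mask`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(stain1 = c(0.8001, 0.4070, 0.4407),
                   stain2 = c(0.4311, 0.7154, 0.5498),
                   stain_labels = c("blue-green", "red-pink"),
                   roi_file = NULL, sigma = 2.0, closing_iterations = 1L,
                   px_per_mm = 473, alpha = 0.05, seed = 1L,
                   threshold_within_mask = FALSE)
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg))
  defaults[names(cfg)] <- cfg
  if (defaults$px_per_mm <= 0) stop_tq("invalid_params", "px_per_mm must be > 0")
  if (defaults$alpha <= 0 || defaults$alpha >= 1)
    stop_tq("invalid_params", "alpha must be in (0, 1)")
  defaults
}

config_basis <- function(config) {
  stain_basis(stain_vector(config$stain1, config$stain_labels[1]),
              stain_vector(config$stain2, config$stain_labels[2]))
}
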