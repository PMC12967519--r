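#' Construct a stain vector
#'
#' A stain vector is the unit direction, in per-channel optical density,
#' along which one dye absorbs. Note the counter-intuitive convention: a
#' blue-green dye absorbs mostly red light, so its *R* component is largest.
#'
#' @param v Numeric length-3 (R, G, B optical-density components). Normalised
#'   to unit Euclidean length.
#' @param label Character name for the stain.
#' @return An object of class `stain_vector` with fields `label` and `v`.
#' @export
#' @examples
#' stain_vector(c(0.8001, 0.4070, 0.4407), "blue-green")
stain_vector <- function(v, label = "stain") {
  if (!is.numeric(v) || length(v) != 3L || anyNA(v))
    stop_tq("invalid_vector", "`v` must be a numeric length-3 vector.")
  n <- sqrt(sum(v^2))
  if (n < 1e-6)
    stop_tq("degenerate_roi", "stain vector has (near-)zero norm")
  v <- v / n
  if (max(v) <= 0)
    stop_tq("invalid_vector", "a stain vector needs at least one positive component")
  structure(list(label = label, v = as.numeric(v)), class = "stain_vector")
}

#' @export
print.stain_vector <- function(x, ...) {
  cat(sprintf("<stain_vector> %s: [%.4f, %.4f, %.4f]\n", x$label, x$v[1], x$v[2], x$v[3]))
  invisible(x)
}

#' Estimate a stain vector from a region of interest
#'
#' Mirrors the protocol of deriving custom deconvolution vectors from the
#' tissue itself: the user outlines a region dominated by one dye (dermal
#' collagen for the blue-green vector, panniculus carnosus muscle for the
#' red-pink vector) and the mean optical density over that region, normalised
#' to unit length, becomes the dye's vector.
#'
#' @param od An `H x W x 3` optical-density array (see [rgb_to_od()]).
#' @param roi Logical `H x W` matrix selecting the region, or `NULL` for the
#'   whole image.
#' @param label Stain name for the result.
#' @return A [stain_vector()].
#' @export
estimate_stain_vector <- function(od, roi = NULL, label = "stain") {
  stopifnot(is.array(od), length(dim(od)) == 3L, dim(od)[3] == 3L)
  if (is.null(roi)) roi <- matrix(TRUE, dim(od)[1], dim(od)[2])
  assert_mask(roi, dim(od)[1:2], "roi")
  if (!any(roi)) stop_tq("empty_roi", "ROI selects no pixels")
  m <- vapply(1:3, function(ch) mean(od[, , ch][roi]), numeric(1))
  if (sqrt(sum(m^2)) <= 1e-6)
    stop_tq("degenerate_roi", "ROI is blank/white: mean optical density is ~0")
  stain_vector(m, label)
}

#' Orthogonal complement of two stain vectors
#'
#' The two-dye system needs a third, mathematically orthogonal axis to make
#' the unmixing matrix invertible. The unit cross product is used; negative
#' components are allowed (this residual axis is never rendered).
#'
#' @param v1,v2 [stain_vector()]s (or numeric length-3 vectors).
#' @return A `stain_vector` perpendicular to both inputs.
#' @export
complement_vector <- function(v1, v2) {
  a <- if (inherits(v1, "stain_vector")) v1$v else v1
  b <- if (inherits(v2, "stain_vector")) v2$v else v2
  cp <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  n <- sqrt(sum(cp^2))
  if (n < 1e-6)
    stop_tq("collinear_vectors", "stain vectors are collinear; no unique complement")
  structure(list(label = "complement", v = cp / n), class = "stain_vector")
}

#' Build an invertible two-stain basis
#'
#' Assembles the 3x3 unmixing system from two stain vectors plus their
#' computed orthogonal complement (rows of `matrix`).
#'
#' @param stain1,stain2 [stain_vector()]s or numeric length-3 vectors.
#' @param labels Labels used when raw numeric vectors are given.
#' @return An object of class `stain_basis` with fields `stain1`, `stain2`,
#'   `complement` and `matrix`.
#' @export
stain_basis <- function(stain1, stain2, labels = c("stain1", "stain2")) {
  s1 <- if (inherits(stain1, "stain_vector")) stain1 else stain_vector(stain1, labels[1])
  s2 <- if (inherits(stain2, "stain_vector")) stain2 else stain_vector(stain2, labels[2])
  comp <- complement_vector(s1, s2)
  M <- rbind(s1$v, s2$v, comp$v)
  dimnames(M) <- list(c(s1$label, s2$label, "complement"), c("R", "G", "B"))
  if (!is.finite(kappa(M)) || rcond(M) < 1e-12)
    stop_tq("singular_basis", "stain basis matrix is singular")
  structure(list(stain1 = s1, stain2 = s2, complement = comp, matrix = M),
            class = "stain_basis")
}

#' Default stain basis for Masson's trichrome
#'
#' Unit optical-density vectors for the blue-green (aniline blue, collagen)
#' and red-pink (Biebrich scarlet-acid fuchsin, muscle/cytoplasm/keratin)
#' dyes, estimated by ROI selection on trichrome-stained rodent skin
#' (collagenous dermis and panniculus carnosus muscle respectively).
#'
#' @return A [stain_basis()].
#' @export
#' @examples
#' trichrome_basis()
trichrome_basis <- function() {
  stain_basis(stain_vector(c(0.8001, 0.4070, 0.4407), "blue-green"),
              stain_vector(c(0.4311, 0.7154, 0.5498), "red-pink"))
}

#' @export
print.stain_basis <- function(x, ...) {
  cat("<stain_basis>\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a stain basis into a label/R/G/B tibble
#'
#' @param x A [stain_basis()].
#' @param ... Unused.
#' @export
tidy.stain_basis <- function(x, ...) {
  tibble::tibble(
    label = rownames(x$matrix),
    R = unname(x$matrix[, "R"]), G = unname(x$matrix[, "G"]),
    B = unname(x$matrix[, "B"])
  )
}

#' Write / read stain vectors as CSV (label,R,G,B)
#'
#' @param basis A [stain_basis()].
#' @param path CSV file path.
#' @return `write_stain_vectors()` returns `path` invisibly;
#'   `read_stain_vectors()` returns a [stain_basis()] built from the first
#'   two rows.
#' @export
write_stain_vectors <- function(basis, path) {
  df <- tidy(basis)
  df <- df[df$label != "complement", ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stain_vectors
#' @export
read_stain_vectors <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) >= 2, all(c("label", "R", "G", "B") %in% names(df)))
  stain_basis(stain_vector(as.numeric(df[1, c("R", "G", "B")]), df$label[1]),
              stain_vector(as.numeric(df[2, c("R", "G", "B")]), df$label[2]))
}
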