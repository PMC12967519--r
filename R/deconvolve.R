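#' Unmix an RGB image into per-stain concentrations
#'
#' Per pixel, solves the Beer-Lambert linear system `od = t(M) %*% conc`,
#' where the rows of `M` are the two stain vectors and their orthogonal
#' complement. Small negative concentrations (cross-talk noise) are kept
#' as-is; clipping happens only when rendering 8-bit channels, so the linear
#' algebra stays exactly invertible.
#'
#' @param rgb `H x W x 3` intensity array in `[0, 255]`.
#' @param basis A [stain_basis()].
#' @return `H x W x 3` array of concentrations (stain1, stain2, complement).
#' @seealso [concentration_to_channel()], [recompose()].
#' @export
deconvolve <- function(rgb, basis = trichrome_basis()) {
  assert_rgb_image(rgb)
  stopifnot(inherits(basis, "stain_basis"))
  M <- basis$matrix
  if (rcond(M) < 1e-12) stop_tq("singular_basis", "stain basis matrix is singular")
  od <- rgb_to_od(rgb)
  odm <- matrix(od, ncol = 3L)            # N x 3, columns = channels
  conc <- t(solve(t(M), t(odm)))          # od = t(M) %*% c  =>  c = solve(t(M), od)
  array(conc, dim = dim(rgb))
}

#' Render one concentration plane as an 8-bit stain-amount channel
#'
#' Converts concentration `c` to transmittance `T = round(255 * 10^(-c))`
#' and reports `255 - T`, so that larger values mean more stain. Saturates at
#' 255 for `c >= ~2.71`; non-positive concentrations map to 0.
#'
#' @param conc_plane `H x W` numeric matrix of concentrations for one stain.
#' @param label Stain name, attached as attribute `stain`.
#' @return Integer-valued `H x W` matrix in `[0, 255]` (attribute `stain`).
#' @export
concentration_to_channel <- function(conc_plane, label = "stain") {
  stopifnot(is.numeric(conc_plane), all(is.finite(conc_plane)))
  tr <- clamp(round_half_up(255 * 10^(-conc_plane)), 0, 255)
  out <- 255 - tr
  attr(out, "stain") <- label
  out
}

#' Recompose an RGB image from unmixed concentrations
#'
#' Inverse of [deconvolve()]: rebuilds optical density as the
#' stain-vector-weighted sum of the concentration planes, then renders RGB.
#' Used for round-trip validation of a stain basis.
#'
#' @param conc `H x W x 3` concentration array.
#' @param basis The [stain_basis()] used for unmixing.
#' @return `H x W x 3` RGB intensity array.
#' @export
recompose <- function(conc, basis = trichrome_basis()) {
  stopifnot(is.array(conc), length(dim(conc)) == 3L, dim(conc)[3] == 3L)
  M <- basis$matrix
  odm <- matrix(conc, ncol = 3L) %*% M     # od = t(M) %*% c, row-wise
  odm[odm < 0] <- 0                        # negative OD is unphysical; clip at render
  array(od_to_rgb(odm), dim = dim(conc))
}
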