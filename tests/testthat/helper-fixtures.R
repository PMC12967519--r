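# Published custom deconvolution vectors for Masson's trichrome on rodent
# skin (blue-green = aniline blue / collagen, red-pink = Biebrich
# scarlet-acid fuchsin / muscle & cytoplasm).
vec_blue <- c(0.8001, 0.4070, 0.4407)
vec_red <- c(0.4311, 0.7154, 0.5498)

# uniform optical-density image: every pixel equals `v * scale`
uniform_od_image <- function(v, h = 8, w = 8, scale = 1) {
  array(rep(v * scale, each = h * w), dim = c(h, w, 3))
}

# RGB image synthesised from two concentration matrices via Beer-Lambert
compose_rgb <- function(conc1, conc2, basis = trichrome_basis()) {
  stopifnot(identical(dim(conc1), dim(conc2)))
  rgb <- array(0, dim = c(dim(conc1), 3))
  for (ch in 1:3) {
    od <- conc1 * basis$stain1$v[ch] + conc2 * basis$stain2$v[ch]
    rgb[, , ch] <- od_to_rgb(od)
  }
  rgb
}

hist_from_counts <- function(counts) {
  structure(list(counts = as.integer(counts), total = sum(counts)),
            class = "histogram256")
}

small_scene <- function(fill = 0.6, seed = 1, w = 600, h = 440, ...) {
  generate_scene(scene_params(width_px = w, height_px = h,
                              collagen_fill = fill, seed = seed, ...))
}
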