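test_that("gaussian blur preserves constants, mass, and the delta limit", {
  const <- matrix(80, 16, 16)
  expect_equal(gaussian_blur(const, 2), const)
  # single bright pixel: internal float filter conserves total mass
  x <- matrix(0, 31, 31); x[16, 16] <- 1000
  blurred <- trichromequant:::gaussian_blur_matrix(x, 2)
  expect_equal(sum(blurred), 1000, tolerance = 1e-9)
  expect_equal(blurred[16, 14], blurred[16, 18])  # symmetry
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_lte(max(abs(gaussian_blur(img, 0.01) - img)), 1)
  expect_error(gaussian_blur(img, 0), class = "tq_error_invalid_sigma")
  expect_error(gaussian_blur(img, -2), class = "tq_error_invalid_sigma")
})

test_that("histogram counts respect region and the ignore-black option", {
  ch <- matrix(5L, 10, 10)
  h <- build_histogram(ch)
  expect_equal(h$counts[6], 100)
  expect_equal(h$total, 100)
  ch2 <- matrix(c(rep(0L, 50), rep(200L, 50)), 10, 10)
  h2 <- build_histogram(ch2, ignore_black = TRUE)
  expect_equal(h2$counts[1], 0)
  expect_equal(h2$counts[201], 50)
  h3 <- build_histogram(ch2, ignore_black = FALSE)
  expect_equal(h3$counts[1], 50)
  expect_error(build_histogram(ch, region = matrix(FALSE, 10, 10)),
               class = "tq_error_empty_region")
})

test_that("intermeans threshold hits known two-mass fixed points", {
  h <- hist_from_counts(replace(rep(0, 256), c(51, 151), 10))
  expect_equal(default_threshold(h), 100L)
  h2 <- hist_from_counts(replace(rep(0, 256), c(11, 21), c(7, 7)))
  expect_equal(default_threshold(h2), 15L)
  h3 <- hist_from_counts(replace(rep(0, 256), 42, 9))
  expect_error(default_threshold(h3), class = "tq_error_degenerate_histogram")
})

test_that("intermeans threshold satisfies its fixed-point condition on random histograms", {
  set.seed(123)
  lv <- 0:255
  for (i in 1:200) {
    counts <- rep(0, 256)
    occ <- sample(0:255, sample(2:40, 1))
    counts[occ + 1] <- sample(1:50, length(occ), replace = TRUE)
    t <- default_threshold(hist_from_counts(counts))
    lo <- lv <= t
    mu_lo <- sum(counts[lo] * lv[lo]) / sum(counts[lo])
    mu_hi <- sum(counts[!lo] * lv[!lo]) / sum(counts[!lo])
    expect_equal(t, as.integer(floor((mu_lo + mu_hi) / 2 + 0.5)))
  }
})

test_that("thresholding selects strictly-greater values within the region", {
  ch <- matrix(c(rep(50L, 32), rep(150L, 32)), 8, 8)
  m <- apply_threshold(ch, 100)
  expect_equal(sum(m), 32)
  expect_true(all(ch[m] == 150))
  expect_equal(sum(apply_threshold(ch, 255)), 0)
  expect_equal(sum(apply_threshold(ch, 0)), 64)   # t = 0 keeps all values >= 1
  reg <- matrix(FALSE, 8, 8); reg[, 5:8] <- TRUE
  expect_equal(sum(apply_threshold(ch, 100, reg)), sum(ch[reg] > 100))
})

test_that("binary closing fills holes, is extensive and idempotent", {
  ring <- matrix(FALSE, 5, 5); ring[2:4, 2:4] <- TRUE; ring[3, 3] <- FALSE
  closed <- binary_closing(ring)
  expect_true(closed[3, 3])
  expect_true(all(closed[ring]))
  empty <- matrix(FALSE, 6, 6)
  expect_equal(binary_closing(empty), empty)
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(runif(400) < 0.35, 20, 20)
    cl <- binary_closing(m)
    expect_true(all(cl[m]))                        # extensivity incl. borders
    expect_equal(binary_closing(cl), cl)           # idempotence
  }
})

test_that("mask AND is monotone and idempotent", {
  set.seed(9)
  a <- matrix(runif(100) < 0.5, 10, 10)
  b <- matrix(runif(100) < 0.5, 10, 10)
  expect_equal(combine_and(a, a), a)
  expect_equal(sum(combine_and(a, matrix(FALSE, 10, 10))), 0)
  expect_lte(sum(combine_and(a, b)), min(sum(a), sum(b)))
  expect_error(combine_and(a, matrix(TRUE, 5, 5)),
               class = "tq_error_dimension_mismatch")
})

test_that("tissue mask recovers the dermis band of a synthetic scene", {
  sc <- small_scene(fill = 0.5, seed = 2, w = 400, h = 300)
  conc <- deconvolve(sc$image)
  blue <- concentration_to_channel(conc[, , 1], "blue-green")
  mask <- build_tissue_mask(blue)
  dermis <- sc$truth$dermis_mask
  frac_measured <- sum(mask) / length(mask)
  frac_true <- sum(dermis) / length(dermis)
  expect_lt(abs(frac_measured - frac_true), 0.05)
  # noise-free block fixture: a strongly stained band with thin cracks;
  # blur + closing must consolidate it, covering >= 99% of the true band
  conc <- matrix(0, 400, 600)
  band <- matrix(FALSE, 400, 600); band[60:340, 30:570] <- TRUE
  conc[band] <- 2.5
  conc[seq(60, 340, by = 7), 30:570] <- 0.15   # horizontal cracks
  blue0 <- concentration_to_channel(conc)
  mask0 <- build_tissue_mask(blue0)
  cover <- sum(mask0 & band) / sum(band)
  expect_gte(cover, 0.99)
})

test_that("an all-white image yields a degenerate histogram, not a mask", {
  white <- matrix(0L, 32, 32)  # stain channel of a blank image
  expect_error(build_tissue_mask(white), class = "tq_error_degenerate_histogram")
})

test_that("tissue-mask area is stable under 1% salt-and-pepper noise", {
  sc <- small_scene(fill = 0.5, seed = 3, w = 400, h = 300)
  rgb <- sc$image
  area0 <- sum(extract_features(rgb)$masks$tissue)
  set.seed(42)
  n <- prod(dim(rgb)[1:2])
  idx <- sample(n, round(0.01 * n))
  noisy <- rgb
  for (ch in 1:3) {
    plane <- noisy[, , ch]
    plane[idx] <- ifelse(runif(length(idx)) < 0.5, 0, 255)
    noisy[, , ch] <- plane
  }
  area1 <- sum(extract_features(noisy)$masks$tissue)
  expect_lt(abs(area1 - area0) / area0, 0.03)
})
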