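test_that("Shapiro-Wilk wrapper holds its level and detects skew", {
  set.seed(21)
  p_norm <- replicate(100, shapiro_wilk(rnorm(200))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(100, shapiro_wilk(rexp(200))$p_value)
  expect_gte(mean(p_exp < 0.05), 0.99)
  expect_error(shapiro_wilk(c(1, 2)), class = "tq_error_sample_too_small")
  expect_error(shapiro_wilk(rep(3, 10)), class = "tq_error_degenerate_sample")
})

test_that("pooled t-test matches the textbook formula on a hand case", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  res <- students_t(a, b)
  # manual pooled-variance computation
  sp2 <- ((3 - 1) * var(a) + (3 - 1) * var(b)) / (3 + 3 - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_manual), df = 4), tolerance = 1e-12)
  ident <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_lt(students_t(a, a + 1000)$p_value, 0.001)
  expect_error(students_t(rep(1, 3), rep(1, 3)), class = "tq_error_degenerate_variance")
})

test_that("Mann-Whitney exact path matches hand enumeration and wilcox.test", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  expect_equal(mann_whitney_u(c(5, 9, 2), c(5, 9, 2))$p_value, 1)
  # independent enumeration oracle: R's exact wilcox.test on tie-free samples
  set.seed(77)
  for (na in 2:6) for (nb in 2:(12 - na)) {
    if (nb < 2) next
    a <- rnorm(na); b <- rnorm(nb)
    mine <- mann_whitney_u(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney normal approximation tracks the exact test", {
  set.seed(78)
  for (i in 1:25) {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    pe <- mann_whitney_u(a, b, exact = TRUE)$p_value
    pa <- mann_whitney_u(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
  # tie correction against wilcox.test's corrected normal approximation
  a <- c(1, 2, 2, 3, 5, 5, 6, 7); b <- c(2, 3, 3, 4, 5, 6, 8, 8)
  mine <- mann_whitney_u(a, b, exact = FALSE)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("the normality gate selects the test the distributions call for", {
  set.seed(41)
  res_nn <- compare_feature(rnorm(50), rnorm(50, 1), feature_name = "x")
  expect_equal(res_nn$test_used, "t_test")
  expect_true(grepl("±", res_nn$summary1))
  res_sk <- compare_feature(rexp(50)^2, rnorm(50, 1), feature_name = "x")
  expect_equal(res_sk$test_used, "mann_whitney")
  expect_true(grepl("\\[", res_sk$summary1))
  # constant group: Shapiro undefined, treated as non-normal
  res_c <- compare_feature(rep(2, 10), rnorm(10), feature_name = "x")
  expect_equal(res_c$test_used, "mann_whitney")
})

test_that("linear regression matches the closed-form slope and is affine-invariant", {
  x <- c(1, 2, 3, 4); y <- c(2.1, 3.9, 6.2, 7.8)
  fit <- linear_regression(x, y)
  slope_manual <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, slope_manual, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope_manual * mean(x), tolerance = 1e-12)
  perfect <- suppressWarnings(linear_regression(1:10, 2 * (1:10)))  # exact fit
  expect_equal(perfect$r_squared, 1)
  expect_lt(perfect$p_value, 1e-6)
  set.seed(13)
  xr <- rnorm(100); yr <- sample(xr)
  expect_lt(linear_regression(xr, yr)$r_squared, 0.1)
  g <- glance(linear_regression(xr, 3 * xr + rnorm(100)))
  expect_true(all(c("r.squared", "p.value", "slope") %in% names(g)))
  expect_error(linear_regression(rep(1, 5), rnorm(5)), class = "tq_error_degenerate_x")
})

test_that("affine rescaling of x and y leaves R^2 unchanged", {
  set.seed(14)
  x <- rnorm(60); y <- 1.5 * x + rnorm(60)
  r1 <- linear_regression(x, y)$r_squared
  r2 <- linear_regression(4 * x - 2, -0.5 * y + 3)$r_squared
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("cohort summary flags a designed blue > red area difference", {
  set.seed(61)
  n <- 12
  mk <- function(stain, area) tibble::tibble(
    image_id = sprintf("img%02d", 1:n), stain = stain,
    mask_area_mm2 = rnorm(n, 2.2, 0.2),
    thresh_area_mm2 = area, thresh_to_mask_pct = 50 + rnorm(n),
    mean = rnorm(n, 200, 5), median = rnorm(n, 205, 5), sd = rnorm(n, 30, 3),
    min = rep(1, n), max = rep(255, n),
    skewness = rnorm(n, 0, 0.1), kurtosis = rnorm(n, -1, 0.1))
  feats <- dplyr::bind_rows(mk("blue-green", rnorm(n, 1.3, 0.1)),
                            mk("red-pink", rnorm(n, 0.3, 0.05)))
  cmp <- summarize_table(feats)
  row <- tidy(cmp)[tidy(cmp)$feature == "thresh_area_mm2", ]
  expect_true(row$significant)
  expect_true(all(c("test_used", "p_value") %in% names(tidy(cmp))))
  md <- report_markdown(cmp)
  expect_true(any(grepl("^\\| Feature", md)))
})

test_that("identical cohorts rarely reach significance", {
  set.seed(62)
  hits <- replicate(40, {
    x <- rnorm(15)
    res <- compare_feature(x, x + rnorm(15, 0, 1), feature_name = "f")
    res$significant
  })
  expect_lte(mean(hits), 0.2)
})

test_that("paired regression pairs records by image id", {
  set.seed(63)
  n <- 10
  blue <- rnorm(n, 1.3, 0.2)
  feats <- dplyr::bind_rows(
    tibble::tibble(image_id = sprintf("i%02d", 1:n), stain = "blue-green",
                   thresh_area_mm2 = blue),
    tibble::tibble(image_id = sprintf("i%02d", 1:n), stain = "red-pink",
                   thresh_area_mm2 = 0.2 * blue + rnorm(n, 0, 0.02)))
  fit <- paired_regression(feats)
  expect_gt(fit$r_squared, 0.5)
  expect_equal(fit$n, n)
})
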