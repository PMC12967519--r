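#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] (Royston's AS R94
#' approximation), with the degenerate cases surfaced as classed errors. A
#' sample is treated as normally distributed when `p > 0.05`.
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @return List with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop_tq("sample_too_small", "Shapiro-Wilk needs at least 3 values")
  if (n > 5000L) stop_tq("sample_too_large", "Shapiro-Wilk supports at most 5000 values")
  if (diff(range(values)) == 0)
    stop_tq("degenerate_sample", "Shapiro-Wilk is undefined for a constant sample")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided independent-samples t-test by default
#' ([stats::t.test()] with `var.equal = TRUE`); Welch's unequal-variance
#' version via `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors (each `n >= 2`).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List with `statistic` (t), `p_value` and `df`.
#' @export
students_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop_tq("sample_too_small", "t-test needs n >= 2 in each group")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      stop_tq("degenerate_variance", "both groups constant and equal; t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined sample sizes `n_a + n_b <= 12` the
#' null distribution of U is obtained by full enumeration over all label
#' assignments (valid with ties, using midranks); otherwise a normal
#' approximation with continuity and tie correction is used.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param exact `NULL` (auto: exact when combined n <= 12), or logical.
#' @return List with `statistic` (U of the first sample), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (is.null(exact)) exact <- N <= 12L
  if (exact) {
    # Null distribution of U over all choose(N, na) assignments of the
    # observed (mid)ranks to group a.
    sets <- combn(N, na)
    base <- na * (na + 1) / 2
    u_all <- colSums(matrix(r[sets], nrow = na)) - base
    eps <- 1e-9
    p <- 2 * min(mean(u_all <= U + eps), mean(u_all >= U - eps))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- na * nb / 12 * ((N + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(v)
      z <- max(z, 0)
      p <- 2 * pnorm(-z)
    }
    method <- "normal_approx"
  }
  list(statistic = U, p_value = p, method = method)
}

summary_string <- function(x, normal) {
  if (normal) {
    sprintf("%.3g ± %.3g", mean(x), sd(x))
  } else {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)  # linear interpolation
    sprintf("%.3g [%.3g–%.3g]", q[2], q[1], q[3])
  }
}

#' Normality-gated two-group comparison
#'
#' The two-step scheme used to compare features between the two stains:
#' Shapiro-Wilk on each group (normal iff `p > 0.05`, so a p of exactly 0.05
#' counts as non-normal); if both groups are normal an independent-samples
#' t-test is used, otherwise the Mann-Whitney U test. Each group is
#' summarised as mean +/- SD when normal, median [IQR] otherwise. Constant
#' groups (Shapiro-Wilk undefined) are treated as non-normal.
#'
#' @param a,b Numeric vectors (each `n >= 3`).
#' @param alpha Significance level for the comparison (default 0.05).
#' @param feature_name Label recorded in the output.
#' @param labels Group labels (length 2).
#' @return One-row tibble: `feature, group1, group2, summary1, summary2,
#'   test_used, statistic, p_value, significant`.
#' @export
compare_feature <- function(a, b, alpha = 0.05, feature_name = "feature",
                            labels = c("group1", "group2")) {
  stopifnot(length(a) >= 3L, length(b) >= 3L, alpha > 0, alpha < 1)
  norm_p <- function(x) {
    tryCatch(shapiro_wilk(x)$p_value, tq_error = function(e) 0)
  }
  normal_a <- norm_p(a) > 0.05
  normal_b <- norm_p(b) > 0.05
  if (normal_a && normal_b) {
    res <- students_t(a, b)
    test_used <- "t_test"
  } else {
    res <- mann_whitney_u(a, b)
    test_used <- "mann_whitney"
  }
  tibble::tibble(
    feature = feature_name,
    group1 = labels[1], group2 = labels[2],
    summary1 = summary_string(a, normal_a),
    summary2 = summary_string(b, normal_b),
    test_used = test_used,
    statistic = res$statistic,
    p_value = res$p_value,
    significant = res$p_value < alpha
  )
}

#' Ordinary least-squares regression with R-squared
#'
#' Fits `y ~ x` by OLS ([stats::lm()]) and reports slope, intercept,
#' coefficient of determination and the two-sided p-value of the slope.
#' Used for paired blue-green vs red-pink feature regressions.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; `x` non-constant.
#' @return Object of class `trichrome_regression` wrapping the `lm` fit,
#'   with fields `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
linear_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_tq("sample_too_small", "regression needs n >= 3")
  if (var(x) == 0) stop_tq("degenerate_x", "x has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  structure(list(model = fit,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = p, n = length(x)),
            class = "trichrome_regression")
}

#' @export
print.trichrome_regression <- function(x, ...) {
  cat(sprintf("<trichrome_regression> y = %.4g + %.4g x  (R^2 = %.3f, p = %.3g, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.trichrome_regression <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
                 statistic = cf[, 3], p.value = cf[, 4])
}

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.trichrome_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value,
                 slope = x$slope, intercept = x$intercept, n = x$n)
}

#' Feature-by-feature comparison of the two stains
#'
#' Builds the summary report for a cohort of analysed images: for every
#' measured feature, the per-stain summary (mean +/- SD or median [IQR],
#' depending on normality), the gated test, its statistic and p-value. No
#' multiple-testing correction is applied across features.
#'
#' @param features Feature tibble as produced by [extract_features()] /
#'   [cmd_run()] (long format, one row per image x stain).
#' @param alpha Significance level.
#' @return Object of class `stain_comparison`: a tibble (one row per
#'   feature) with attribute `alpha`.
#' @export
summarize_table <- function(features, alpha = 0.05) {
  stopifnot(is.data.frame(features), all(c("image_id", "stain") %in% names(features)))
  stains <- unique(features$stain)
  if (length(stains) != 2L)
    stop_tq("invalid_input", "feature table must contain exactly two stains")
  n_img <- length(unique(features$image_id))
  if (n_img < 3L) stop_tq("too_few_images", "need at least 3 images to compare")
  feat_cols <- c("mask_area_mm2", "thresh_area_mm2", "thresh_to_mask_pct",
                 "mean", "median", "sd", "min", "max", "skewness", "kurtosis")
  feat_cols <- intersect(feat_cols, names(features))
  rows <- purrr::map_dfr(feat_cols, function(fc) {
    a <- features[[fc]][features$stain == stains[1]]
    b <- features[[fc]][features$stain == stains[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 3L || length(b) < 3L) {
      return(tibble::tibble(feature = fc, group1 = stains[1], group2 = stains[2],
                            summary1 = NA_character_, summary2 = NA_character_,
                            test_used = NA_character_, statistic = NA_real_,
                            p_value = NA_real_, significant = NA))
    }
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
      # identical constant feature in both groups (e.g. shared mask area)
      return(tibble::tibble(feature = fc, group1 = stains[1], group2 = stains[2],
                            summary1 = summary_string(a, FALSE),
                            summary2 = summary_string(b, FALSE),
                            test_used = "none", statistic = NA_real_,
                            p_value = 1, significant = FALSE))
    }
    compare_feature(a, b, alpha = alpha, feature_name = fc, labels = stains)
  })
  structure(rows, class = c("stain_comparison", class(rows)), alpha = alpha)
}

#' @export
tidy.stain_comparison <- function(x, ...) tibble::as_tibble(unclass(x))

#' Plot a stain comparison
#'
#' Dot plot of -log10 p-values per feature, coloured by the test the
#' normality gate selected; the dashed line marks the significance level.
#'
#' @param object A `stain_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stain_comparison <- function(object, ...) {
  df <- tidy(object)
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p_value), .data$feature,
                                   colour = .data$test_used)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, colour = "test") +
    ggplot2::theme_minimal()
}

#' Markdown report of a stain comparison
#'
#' @param comparison A `stain_comparison` from [summarize_table()].
#' @param path Optional file to write to.
#' @return The report lines, invisibly (character vector).
#' @export
report_markdown <- function(comparison, path = NULL) {
  df <- tidy(comparison)
  hdr <- sprintf("| Feature | %s | %s | Test | p |", df$group1[1], df$group2[1])
  sep <- "|---|---|---|---|---|"
  body <- sprintf("| %s | %s | %s | %s | %s |",
                  df$feature, df$summary1, df$summary2, df$test_used,
                  ifelse(df$p_value < 0.001, "<0.001", sprintf("%.3f", df$p_value)))
  foot <- c("",
            "Data are mean ± SD for normally distributed groups (Shapiro–Wilk p > 0.05),",
            "median [interquartile range] otherwise; p from independent t-test when both",
            "groups are normal, Mann–Whitney U otherwise. No multiple-testing correction.")
  lines <- c(hdr, sep, body, foot)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Paired regression of a feature between the two stains
#'
#' Pairs records by `image_id` and regresses the second stain's values on
#' the first stain's (e.g. red-pink thresholded area vs blue-green).
#'
#' @param features Long feature tibble (two stains per image).
#' @param feature Column to regress (default `"thresh_area_mm2"`).
#' @return A [linear_regression()] result.
#' @export
paired_regression <- function(features, feature = "thresh_area_mm2") {
  stains <- unique(features$stain)
  stopifnot(length(stains) == 2L, feature %in% names(features))
  wide <- tidyr::pivot_wider(features[, c("image_id", "stain", feature)],
                             names_from = "stain", values_from = dplyr::all_of(feature))
  linear_regression(wide[[stains[1]]], wide[[stains[2]]])
}
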