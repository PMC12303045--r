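# Reader-study statistics: pairwise agreement matrices over a panel of
# annotation sources, t and bootstrap confidence intervals, Wilcoxon tests
# comparing model-reader against inter-reader agreement, and Gaussian
# agreement heatmaps.

# Group a flat list of point_annotation_sets by source and image; every
# source must cover every image.
.panel_index <- function(sets) {
  src <- vapply(sets, `[[`, "", "source_id")
  img <- vapply(sets, `[[`, "", "image_id")
  sources <- unique(src); images <- unique(img)
  idx <- matrix(NA_integer_, length(sources), length(images),
                dimnames = list(sources, images))
  for (k in seq_along(sets)) idx[src[k], img[k]] <- k
  if (anyNA(idx)) {
    miss <- which(is.na(idx), arr.ind = TRUE)[1, ]
    stop("source '", sources[miss[1]], "' has no annotation set for image '",
         images[miss[2]], "'")
  }
  list(sources = sources, images = images, idx = idx)
}

.metric_column <- function(metric) {
  switch(metric, F1_OVERALL = "f1_overall",
         COUNT_AGREEMENT = "count_agreement",
         JS_SIMILARITY = "js_similarity")
}

# Per-lesion (or per-image) scores between two sets of the same image.
.pair_scores <- function(a, b, metric, lesions, hit_radius_um, buffer_um,
                         aggregation) {
  col <- .metric_column(metric)
  if (aggregation == "PER_IMAGE" || length(lesions) == 0L) {
    mb <- f1_scores(a, b, hit_radius_um, order = "DISTANCE")
    return(data.frame(lesion_id = "(image)", score = mb[[col]]))
  }
  lm <- lesion_metrics(a, b, lesions, buffer_um, hit_radius_um,
                       order = "DISTANCE")
  data.frame(lesion_id = lm$lesion_id, score = lm[[col]])
}

#' Pairwise agreement matrix over a panel of annotation sources
#'
#' Computes the chosen metric between every unordered pair of sources
#' (readers and/or models) on every image, either per lesion (default) or
#' per whole image. The matrix holds the mean score per pair; the long-form
#' score table feeds the statistical tests. Lesion polygons are taken from
#' the `lesions` argument (a list named by image id) or, by default, from
#' the first source's set for each image.
#'
#' @param sets flat list of [point_annotation_set()]s; every source must
#'   cover every image.
#' @param metric `"F1_OVERALL"`, `"COUNT_AGREEMENT"` or `"JS_SIMILARITY"`.
#' @param lesions optional named list (by image id) of lesion polygon lists.
#' @param hit_radius_um hit radius for F1 (micrometers).
#' @param buffer_um lesion dilation when restricting points.
#' @param aggregation `"PER_LESION"` (default) or `"PER_IMAGE"`.
#' @return List with `matrix` (square, NA diagonal), `scores` (long
#'   data.frame: `source_a`, `source_b`, `image_id`, `lesion_id`, `score`)
#'   and `metric`.
#' @export
pairwise_agreement <- function(sets,
                               metric = c("F1_OVERALL", "COUNT_AGREEMENT",
                                          "JS_SIMILARITY"),
                               lesions = NULL, hit_radius_um = 10,
                               buffer_um = 0,
                               aggregation = c("PER_LESION", "PER_IMAGE")) {
  metric <- match.arg(metric)
  aggregation <- match.arg(aggregation)
  panel <- .panel_index(sets)
  if (length(panel$sources) < 2L) stop("need at least two sources")
  ns <- length(panel$sources)
  rows <- list()
  for (img in panel$images) {
    les <- if (!is.null(lesions)) lesions[[img]] else
      sets[[panel$idx[1, img]]]$lesions
    for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
      sc <- .pair_scores(sets[[panel$idx[i, img]]], sets[[panel$idx[j, img]]],
                         metric, les, hit_radius_um, buffer_um, aggregation)
      rows[[length(rows) + 1L]] <- data.frame(
        source_a = panel$sources[i], source_b = panel$sources[j],
        image_id = img, lesion_id = sc$lesion_id, score = sc$score)
    }
  }
  scores <- do.call(rbind, rows)
  m <- matrix(NA_real_, ns, ns, dimnames = list(panel$sources, panel$sources))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    sel <- scores$source_a == panel$sources[i] &
      scores$source_b == panel$sources[j]
    m[i, j] <- m[j, i] <- mean(scores$score[sel])
  }
  list(matrix = m, scores = scores, metric = metric)
}

#' t-distribution confidence interval for a mean
#'
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)`.
#'
#' @param values numeric vector, length >= 2.
#' @param level nominal coverage (default 0.95).
#' @return Named numeric vector `c(mean, lo, hi)`.
#' @export
mean_ci_t <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least two values for a t interval")
  m <- mean(values)
  hw <- stats::qt((1 + level) / 2, n - 1L) * stats::sd(values) / sqrt(n)
  c(mean = m, lo = m - hw, hi = m + hw)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when `min(n) <= 8` and the pooled sample has no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param x,y non-empty numeric score vectors.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  exact <- min(length(x), length(y)) <= 8L && !any(duplicated(c(x, y)))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  if (is.nan(p)) p <- 1  # fully tied samples: no evidence of a shift
  min(1, p)
}

#' Two-sided Wilcoxon signed-rank test for paired scores
#'
#' Zero differences are dropped (Wilcoxon convention). Exact enumeration
#' when the effective n is at most 15 and the absolute differences are
#' untied; otherwise the normal approximation with continuity correction.
#' When every difference is zero the test is degenerate: p = 1 is returned
#' with attribute `degenerate = TRUE` and a warning.
#'
#' @param paired_a,paired_b equal-length numeric vectors.
#' @return Two-sided p-value (attribute `degenerate` when all differences
#'   are zero).
#' @export
signed_rank_test <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b), length(paired_a) >= 1L)
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; signed-rank test is degenerate")
    return(structure(1.0, degenerate = TRUE))
  }
  exact <- length(d) <= 15L && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  if (is.nan(p)) p <- 1
  min(1, p)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the per-unit scores (whole-slide images or lesions) with
#' replacement `n_iter` times, recomputes the mean each time, and takes the
#' `(1 - level)/2` and `(1 + level)/2` percentiles of the bootstrap means
#' (2.5% and 97.5% at the default level). Deterministic for a fixed seed.
#'
#' @param per_unit_scores numeric vector, length >= 2.
#' @param n_iter bootstrap iterations, >= 100 (default 1000).
#' @param level nominal coverage (default 0.95).
#' @param seed integer seed (RNG state is restored afterwards).
#' @return Named vector `c(mean, lo, hi)` with the bootstrap means in
#'   attribute `boot_means`.
#' @export
bootstrap_ci <- function(per_unit_scores, n_iter = 1000L, level = 0.95,
                         seed = NULL) {
  n <- length(per_unit_scores)
  if (n < 2L) stop("need at least two units")
  if (n_iter < 100L) stop("n_iter must be at least 100")
  means <- with_seed(seed, {
    draws <- matrix(sample.int(n, n * n_iter, replace = TRUE), nrow = n)
    colMeans(matrix(per_unit_scores[draws], nrow = n))
  })
  qs <- stats::quantile(means, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  structure(c(mean = mean(per_unit_scores), lo = qs[1], hi = qs[2]),
            boot_means = means)
}

#' Compare a model against a reader panel
#'
#' Builds, per lesion, the model-reader pairwise scores (the model against
#' each reader) and the inter-reader pairwise scores (every unordered
#' reader pair), compares the two pooled groups with the two-sided Wilcoxon
#' rank-sum test, and attaches t-distribution confidence intervals for both
#' group means. With R readers and L lesions this yields R*L model-reader
#' and choose(R,2)*L inter-reader scores.
#'
#' @param reader_sets flat list of reader [point_annotation_set()]s (>= 2
#'   readers, every reader covering every image).
#' @param model_sets a single model [point_annotation_set()] or a list, one
#'   per image.
#' @inheritParams pairwise_agreement
#' @return Object of class `comparison_report`: `group_inter`,
#'   `group_model` (per-lesion score vectors), `p_value`, `test_name`,
#'   `means_with_ci` (rows `inter_reader`, `model_reader`), `metric`.
#' @export
compare_model_to_readers <- function(reader_sets, model_sets,
                                     metric = c("F1_OVERALL",
                                                "COUNT_AGREEMENT",
                                                "JS_SIMILARITY"),
                                     lesions = NULL, hit_radius_um = 10,
                                     buffer_um = 0,
                                     aggregation = c("PER_LESION",
                                                     "PER_IMAGE")) {
  metric <- match.arg(metric)
  aggregation <- match.arg(aggregation)
  if (inherits(model_sets, "point_annotation_set"))
    model_sets <- list(model_sets)
  inter <- pairwise_agreement(reader_sets, metric, lesions, hit_radius_um,
                              buffer_um, aggregation)
  panel <- .panel_index(reader_sets)
  if (length(panel$sources) < 2L) stop("need at least two readers")
  model_img <- vapply(model_sets, `[[`, "", "image_id")
  if (!all(panel$images %in% model_img))
    stop("model predictions missing for image(s): ",
         paste(setdiff(panel$images, model_img), collapse = ", "))
  rows <- list()
  for (img in panel$images) {
    les <- if (!is.null(lesions)) lesions[[img]] else
      reader_sets[[panel$idx[1, img]]]$lesions
    mset <- model_sets[[match(img, model_img)]]
    for (s in panel$sources) {
      sc <- .pair_scores(mset, reader_sets[[panel$idx[s, img]]], metric, les,
                         hit_radius_um, buffer_um, aggregation)
      rows[[length(rows) + 1L]] <- sc$score
    }
  }
  group_model <- unlist(rows)
  group_inter <- inter$scores$score
  p <- rank_sum_test(group_model, group_inter)
  ci <- rbind(inter_reader = mean_ci_t(group_inter),
              model_reader = mean_ci_t(group_model))
  structure(list(group_inter = group_inter, group_model = group_model,
                 p_value = p, test_name = "two-sided Wilcoxon rank-sum",
                 means_with_ci = ci, metric = metric),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", x$metric, "\n")
  cat(sprintf("  inter-reader : %.4f (%.4f-%.4f), n=%d\n",
              x$means_with_ci["inter_reader", "mean"],
              x$means_with_ci["inter_reader", "lo"],
              x$means_with_ci["inter_reader", "hi"], length(x$group_inter)))
  cat(sprintf("  model-reader : %.4f (%.4f-%.4f), n=%d\n",
              x$means_with_ci["model_reader", "mean"],
              x$means_with_ci["model_reader", "lo"],
              x$means_with_ci["model_reader", "hi"], length(x$group_model)))
  cat(sprintf("  %s p = %.4g\n", x$test_name, x$p_value))
  invisible(x)
}

#' Gaussian agreement heatmap for one cell class
#'
#' Sums the point masses all readers placed for a class onto the pixel grid
#' and convolves with an isotropic Gaussian of standard deviation
#' `sigma_um` (default 10 um, the hit radius). The kernel is normalized to
#' unit mass, so a location where k readers placed coincident points peaks
#' at k times the single-reader value and the raster total approximates the
#' point count.
#'
#' @param sets list of reader [point_annotation_set()]s (same image).
#' @param cell_class class code to map.
#' @param sigma_um kernel standard deviation in micrometers.
#' @param extent raster size `c(width_px, height_px)` (default: bounds of
#'   the first set).
#' @return Numeric matrix (rows x cols) of agreement density with
#'   attributes `spacing_um_per_px` and `cell_class`.
#' @export
agreement_heatmap <- function(sets, cell_class, sigma_um = 10, extent = NULL) {
  stopifnot(sigma_um > 0, length(sets) >= 1L)
  cell_class <- match.arg(cell_class, cell_classes())
  sp <- sets[[1]]$spacing_um_per_px
  if (is.null(extent)) extent <- sets[[1]]$bounds
  if (is.null(extent)) stop("extent required when sets declare no bounds")
  width <- as.integer(extent[1]); height <- as.integer(extent[2])
  acc <- matrix(0, nrow = height, ncol = width)
  for (s in sets) {
    p <- s$points[s$points$class == cell_class, , drop = FALSE]
    if (!nrow(p)) next
    r <- pmin(pmax(round(p$y_px) + 1L, 1L), height)
    c_ <- pmin(pmax(round(p$x_px) + 1L, 1L), width)
    for (k in seq_along(r)) acc[r[k], c_[k]] <- acc[r[k], c_[k]] + 1
  }
  sigma_px <- sigma_um / sp
  half <- max(1L, ceiling(3 * sigma_px))
  g <- stats::dnorm(-half:half, sd = sigma_px)
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  out <- EBImage::filter2(acc, kern, boundary = "circular")
  out <- matrix(as.numeric(out), nrow = height)
  structure(out, spacing_um_per_px = sp, cell_class = cell_class,
            sigma_um = sigma_um)
}
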