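# Two-stage training data logistics: class-weighted patch sampling and
# hard-negative mining with confidence-proportional resampling.

.patch_sources <- function() {
  c("TYPICAL_SRC", "ATYPICAL_SRC", "NON_SRC",
    "HN_TYPICAL", "HN_ATYPICAL", "HN_NON_SRC", "HEALTHY")
}

.hn_source_of_class <- function(cls) {
  c(TYPICAL_SRC = "HN_TYPICAL", ATYPICAL_SRC = "HN_ATYPICAL",
    NON_SRC = "HN_NON_SRC")[as.character(cls)]
}

#' Patch sampling weights for the two training stages
#'
#' Stage 1: 10% of patches from healthy tissue, the remaining 90% evenly
#' from the three tumor cell types (0.30 each). Stage 2 (after hard-negative
#' mining): 20% to each tumor cell type, 10% to each hard-negative tumor
#' cell type, and 10% to healthy tissue from regions without prior errors.
#'
#' @param stage 1 or 2.
#' @return Object of class `sampling_weights`: named non-negative vector
#'   over the seven patch sources, summing to 1.
#' @export
stage_weights <- function(stage) {
  if (!stage %in% c(1L, 2L)) stop("stage must be 1 or 2")
  w <- if (stage == 1L)
    c(TYPICAL_SRC = 0.30, ATYPICAL_SRC = 0.30, NON_SRC = 0.30,
      HN_TYPICAL = 0, HN_ATYPICAL = 0, HN_NON_SRC = 0, HEALTHY = 0.10)
  else
    c(TYPICAL_SRC = 0.20, ATYPICAL_SRC = 0.20, NON_SRC = 0.20,
      HN_TYPICAL = 0.10, HN_ATYPICAL = 0.10, HN_NON_SRC = 0.10,
      HEALTHY = 0.10)
  sampling_weights(w)
}

#' Construct patch sampling weights
#'
#' @param w named non-negative vector over the sources of
#'   `c("TYPICAL_SRC", "ATYPICAL_SRC", "NON_SRC", "HN_TYPICAL",
#'   "HN_ATYPICAL", "HN_NON_SRC", "HEALTHY")`, summing to 1 within 1e-9.
#' @return Object of class `sampling_weights`.
#' @export
sampling_weights <- function(w) {
  src <- .patch_sources()
  stopifnot(all(names(w) %in% src))
  full <- stats::setNames(numeric(length(src)), src)
  full[names(w)] <- w
  if (any(full < 0)) stop("weights must be non-negative")
  if (abs(sum(full) - 1) > 1e-9) stop("weights must sum to 1")
  structure(full, class = "sampling_weights")
}

#' Mine hard negatives from detections outside lesions
#'
#' Returns the detections (with class and confidence preserved) whose
#' location falls outside every lesion polygon dilated by `buffer_um` —
#' tumor cell predictions in non-tumor regions. Detections inside lesions
#' are never returned.
#'
#' @param detections a [point_annotation_set()] whose points all carry
#'   confidences.
#' @param lesions list of lesion [region_polygon()]s.
#' @param buffer_um lesion dilation in micrometers.
#' @return data.frame of hard negatives: `image_id`, `x_px`, `y_px`,
#'   `class`, `confidence`.
#' @export
mine_hard_negatives <- function(detections, lesions, buffer_um = 10) {
  stopifnot(inherits(detections, "point_annotation_set"))
  p <- detections$points
  if (nrow(p) && anyNA(p$confidence))
    stop("hard-negative mining requires confidences on all detections")
  if (nrow(p) == 0L)
    return(data.frame(image_id = character(0), x_px = numeric(0),
                      y_px = numeric(0), class = character(0),
                      confidence = numeric(0)))
  inside <- point_in_dilated_polygons(p$x_px, p$y_px, lesions, buffer_um,
                                      detections$spacing_um_per_px)
  out <- p[!inside, , drop = FALSE]
  data.frame(image_id = rep(detections$image_id, nrow(out)),
             x_px = out$x_px, y_px = out$y_px,
             class = as.character(out$class), confidence = out$confidence,
             row.names = NULL)
}

#' Randomly select slides for hard-negative mining
#'
#' Per cross-validation fold, selects `ceiling(fraction * n_fold)` slides
#' uniformly without replacement (the default 0.1 selects 10% of the
#' slides of each fold). Deterministic under the seed.
#'
#' @param folds named list of slide id vectors, one per fold (non-empty).
#' @param fraction fraction of slides per fold, in (0, 1].
#' @param seed integer seed.
#' @return Named list of selected slide ids per fold.
#' @export
select_mining_slides <- function(folds, fraction = 0.1, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (any(lengths(folds) == 0L)) stop("every fold must contain slides")
  with_seed(seed, lapply(folds, function(ids) {
    k <- ceiling(fraction * length(ids))
    sort(sample(ids, k))
  }))
}

#' Group hard negatives by confidence score bins
#'
#' Partitions mined hard negatives into half-open score bins
#' `(edge_i, edge_{i+1}]`; each bin is a distinct sampling sub-source.
#'
#' @param samples data.frame of hard negatives (as from
#'   [mine_hard_negatives()]).
#' @param bin_edges strictly increasing numeric edges covering all scores
#'   (e.g. `c(0, 0.5, 1)`).
#' @return Named list of data.frames, one per non-empty-able bin (empty
#'   bins are kept as zero-row data.frames).
#' @export
score_bin_hard_negatives <- function(samples, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  s <- samples$confidence
  if (any(s <= bin_edges[1] | s > bin_edges[length(bin_edges)]))
    stop("sample score outside the bin range")
  lab <- cut(s, breaks = bin_edges, right = TRUE)
  split(samples, lab)
}

#' Draw training patch specifications by weighted source sampling
#'
#' For each of `n` draws a patch source is sampled according to `weights`,
#' then a seed location from that source: tumor classes sample uniformly
#' from the annotated cells of that class; hard-negative sources sample
#' with probability proportional to confidence, so a sample with score x is
#' drawn x/y times more often than one with score y; healthy patches sample
#' uniformly from tissue outside lesions, and — whenever hard-negative
#' sources carry weight (stage 2) — also outside a buffer of twice the hit
#' radius around every mined hard negative ("regions without prior
#' errors"). Patch centers are clamped so the window stays in bounds.
#'
#' @param annotations list of [point_annotation_set()]s (one per image,
#'   with bounds, tissue and lesions).
#' @param weights a [sampling_weights()] (e.g. [stage_weights()]).
#' @param n number of patches (>= 1).
#' @param hard_negs data.frame from [mine_hard_negatives()] (required when
#'   hard-negative sources have positive weight).
#' @param seed integer seed; equal seeds give identical output.
#' @param config a [toolkit_config()] (patch size, hit radius).
#' @return data.frame of patch specs: `image_id`, `center_x_px`,
#'   `center_y_px`, `size_px`, `source_label`.
#' @export
sample_patches <- function(annotations, weights, n, hard_negs = NULL,
                           seed = NULL, config = toolkit_config()) {
  stopifnot(inherits(weights, "sampling_weights"), n >= 1L)
  if (inherits(annotations, "point_annotation_set"))
    annotations <- list(annotations)
  size <- config$patch_size_px
  # candidate pools per source
  pools <- list()
  for (cls in cell_classes()) {
    rows <- lapply(annotations, function(s) {
      p <- s$points[s$points$class == cls, , drop = FALSE]
      if (nrow(p)) data.frame(image_id = s$image_id, x = p$x_px, y = p$y_px)
      else NULL
    })
    pools[[cls]] <- do.call(rbind, rows)
  }
  if (!is.null(hard_negs) && nrow(hard_negs)) {
    for (cls in cell_classes()) {
      hn <- hard_negs[hard_negs$class == cls, , drop = FALSE]
      if (nrow(hn))
        pools[[.hn_source_of_class(cls)]] <-
          data.frame(image_id = hn$image_id, x = hn$x_px, y = hn$y_px,
                     w = hn$confidence)
    }
  }
  for (srcname in .patch_sources()) {
    if (weights[srcname] > 0 && srcname != "HEALTHY" &&
        (is.null(pools[[srcname]]) || nrow(pools[[srcname]]) == 0L))
      stop("no candidate locations for positive-weight source ", srcname)
  }
  if (weights["HEALTHY"] > 0 &&
      all(vapply(annotations, function(s) length(s$tissue) == 0L, TRUE)))
    stop("no candidate locations for positive-weight source HEALTHY")
  hn_buffer_um <- if (any(weights[c("HN_TYPICAL", "HN_ATYPICAL",
                                    "HN_NON_SRC")] > 0))
    2 * config$hit_radius_um else 0
  img_ids <- vapply(annotations, `[[`, "", "image_id")
  bounds_of <- function(img) {
    b <- annotations[[match(img, img_ids)]]$bounds
    if (is.null(b)) stop("annotation set for image ", img, " declares no bounds")
    b
  }
  clamp_center <- function(x, b) {
    lo <- size / 2; hi <- b - size / 2
    ifelse(hi < lo, b / 2, pmin(pmax(x, lo), hi))
  }
  draw_healthy <- function(m) {
    imgs <- sample(img_ids, m, replace = TRUE)
    x <- numeric(m); y <- numeric(m)
    for (k in seq_len(m)) {
      s <- annotations[[match(imgs[k], img_ids)]]
      tis <- s$tissue[[sample.int(length(s$tissue), 1L)]]
      loc <- NULL
      for (try in 1:200) {
        cand <- .sample_points_in_polygon(
          1L, tis, exclude = s$lesions,
          spacing_um_per_px = s$spacing_um_per_px)
        ok <- TRUE
        if (hn_buffer_um > 0 && !is.null(hard_negs) && nrow(hard_negs)) {
          hh <- hard_negs[hard_negs$image_id == s$image_id, , drop = FALSE]
          if (nrow(hh)) {
            buf_px <- hn_buffer_um / s$spacing_um_per_px
            ok <- all((hh$x_px - cand[1, 1])^2 +
                        (hh$y_px - cand[1, 2])^2 > buf_px^2)
          }
        }
        if (ok) { loc <- cand; break }
      }
      if (is.null(loc))
        stop("could not place a HEALTHY patch outside prior-error regions")
      x[k] <- loc[1, 1]; y[k] <- loc[1, 2]
    }
    data.frame(image_id = imgs, x = x, y = y)
  }
  with_seed(seed, {
    src_draw <- sample(names(weights), n, replace = TRUE, prob = weights)
    img <- character(n); cx <- numeric(n); cy <- numeric(n)
    for (srcname in unique(src_draw)) {
      ii <- which(src_draw == srcname)
      loc <- if (srcname == "HEALTHY") draw_healthy(length(ii)) else {
        pool <- pools[[srcname]]
        pr <- if (!is.null(pool$w)) pool$w else NULL
        pick <- sample.int(nrow(pool), length(ii), replace = TRUE, prob = pr)
        pool[pick, c("image_id", "x", "y")]
      }
      b <- t(vapply(as.character(loc$image_id), bounds_of, numeric(2)))
      img[ii] <- loc$image_id
      cx[ii] <- clamp_center(loc$x, b[, 1])
      cy[ii] <- clamp_center(loc$y, b[, 2])
    }
    data.frame(image_id = img, center_x_px = cx, center_y_px = cy,
               size_px = size, source_label = src_draw)
  })
}
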