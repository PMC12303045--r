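# Body/membrane mask codec: point annotations -> segmentation label rasters
# for training, and segmentation outputs -> individual point detections.
#
# Each annotated cell is drawn as an inner disk (the "cell body", the
# segmentation target) surrounded by an annulus (the "cell membrane", a
# separator that keeps adjacent cells apart in the prediction). Decoding
# removes membranes, labels connected body components, filters small ones,
# and suppresses near-duplicate centroids.

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# the (few) label pairs that touch diagonally with a small union-find.
.label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- structure(as.integer(lab), dim = dim(mask))
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal adjacencies, scanned only over foreground pixels
  q <- which(lab > 0L)
  r <- (q - 1L) %% nr + 1L; cc <- (q - 1L) %/% nr + 1L
  diag_pairs <- function(off, ok) {
    qq <- q[ok]; nb <- qq + off
    lv <- lab[qq]; ln <- lab[nb]
    sel <- ln > 0L & ln != lv
    cbind(lv[sel], ln[sel])
  }
  pairs <- rbind(diag_pairs(nr + 1L, r < nr & cc < nc),   # down-right
                 diag_pairs(nr - 1L, r > 1L & cc < nc))   # up-right
  if (nrow(pairs)) {
    parent <- seq_len(nmax)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nmax), find, 0L)
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  # compact label ids
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# Scanline even-odd rasterization of one polygon onto a height x width grid.
# Pixel (r, c) has center (x, y) = (c - 1, r - 1). Each row is scanned at
# y +/- epsilon and the fills unioned, which keeps boundary pixel rows
# inside (matching the boundary-inclusive point-in-polygon test) and avoids
# vertex degeneracies.
.rasterize_polygon <- function(v, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  n <- nrow(v)
  xs <- v[, 1]; ys <- v[, 2]
  xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
  for (r in seq_len(height)) {
    for (y in (r - 1) + c(-1e-7, 1e-7)) {
      cross <- ((ys > y) != (ye > y))
      if (!any(cross)) next
      cx <- xs[cross] + (y - ys[cross]) * (xe[cross] - xs[cross]) / (ye[cross] - ys[cross])
      cx <- sort(cx)
      for (k in seq(1L, length(cx) - 1L, by = 2L)) {
        c1 <- ceiling(cx[k] - 1e-7) + 1L; c2 <- floor(cx[k + 1L] + 1e-7) + 1L
        if (c2 >= c1) mask[r, max(1L, c1):min(width, c2)] <- TRUE
      }
    }
  }
  mask
}

#' Encode point annotations as a body/membrane label raster
#'
#' Each point becomes a filled disk of its class's body label surrounded by
#' an annulus of its membrane label. Membranes are rendered first and bodies
#' second, so bodies overwrite overlapping membranes; where two bodies
#' overlap, each pixel takes the class of the nearest annotation center
#' (ties go to the lower class in [cell_classes()] order). Pixels inside
#' tissue polygons that belong to no cell get label 1 (healthy tissue);
#' pixels outside tissue get 0 (background).
#'
#' @param set a [point_annotation_set()]; all points must lie inside
#'   `extent`.
#' @param geometry a [class_geometry()].
#' @param tissue list of tissue [region_polygon()]s (default: the set's).
#' @param extent raster size `c(width_px, height_px)` (default: the set's
#'   declared bounds).
#' @return A [label_raster()] at the set's spacing.
#' @export
encode_points_to_mask <- function(set, geometry = class_geometry(),
                                  tissue = NULL, extent = NULL) {
  stopifnot(inherits(set, "point_annotation_set"),
            inherits(geometry, "class_geometry"))
  if (is.null(extent)) extent <- set$bounds
  if (is.null(extent)) stop("extent is required when the set declares no bounds")
  width <- as.integer(extent[1]); height <- as.integer(extent[2])
  if (width < 1L || height < 1L) stop("extent must have positive area")
  if (is.null(tissue)) tissue <- set$tissue
  p <- set$points
  if (nrow(p)) {
    bad <- p$x_px < 0 | p$x_px > width - 1 | p$y_px < 0 | p$y_px > height - 1
    if (any(bad))
      stop(sprintf("point (%.1f, %.1f) lies outside the raster extent",
                   p$x_px[which(bad)[1]], p$y_px[which(bad)[1]]))
  }
  lab <- matrix(0L, nrow = height, ncol = width)
  for (poly in tissue) lab[.rasterize_polygon(poly$vertices, width, height)] <- 1L

  cls_idx <- as.integer(p$class)
  rb <- geometry$body_radius_px[cls_idx]
  mw <- geometry$membrane_width_px[cls_idx]

  stamp_window <- function(i, radius) {
    # local pixel window and squared distances to the annotation center
    x0 <- p$x_px[i]; y0 <- p$y_px[i]
    cmin <- max(1L, floor(x0 - radius) + 1L); cmax <- min(width, ceiling(x0 + radius) + 1L)
    rmin <- max(1L, floor(y0 - radius) + 1L); rmax <- min(height, ceiling(y0 + radius) + 1L)
    cols <- cmin:cmax; rows <- rmin:rmax
    dx <- (cols - 1) - x0; dy <- (rows - 1) - y0
    d2 <- outer(dy^2, dx^2, `+`)
    list(rows = rows, cols = cols, d2 = d2)
  }

  # pass 1: membranes (later points overwrite earlier in their annulus)
  for (i in seq_len(nrow(p))) {
    w <- stamp_window(i, rb[i] + mw[i])
    sel <- w$d2 > rb[i]^2 & w$d2 <= (rb[i] + mw[i])^2
    if (any(sel)) {
      block <- lab[w$rows, w$cols, drop = FALSE]
      block[sel] <- membrane_label(p$class[i])
      lab[w$rows, w$cols] <- block
    }
  }
  # pass 2: bodies, nearest-center wins, ties to the lower class order
  if (nrow(p)) {
    bestd2 <- matrix(Inf, nrow = height, ncol = width)
    for (i in seq_len(nrow(p))) {
      w <- stamp_window(i, rb[i])
      sel <- w$d2 <= rb[i]^2
      if (!any(sel)) next
      bd <- bestd2[w$rows, w$cols, drop = FALSE]
      block <- lab[w$rows, w$cols, drop = FALSE]
      ex_cls <- block - 1L  # valid only where a body already sits (labels 2..4)
      win <- sel & (w$d2 < bd |
                      (w$d2 == bd & block >= 2L & block <= 4L & cls_idx[i] < ex_cls))
      if (any(win)) {
        block[win] <- body_label(p$class[i])
        bd[win] <- w$d2[win]
        lab[w$rows, w$cols] <- block
        bestd2[w$rows, w$cols] <- bd
      }
    }
  }
  label_raster(lab, set$spacing_um_per_px)
}

#' Combine an ensemble of probability rasters
#'
#' Averages the per-class probability channels across the ensemble, then
#' assigns each pixel the label with maximal mean probability (ties broken
#' toward the lower label code). For a single raster this reduces to a
#' per-pixel argmax.
#'
#' @param prob_rasters list of [probability_raster()]s with identical shape
#'   and spacing.
#' @return List with `labels` (a [label_raster()]) and `mean_probs` (the
#'   averaged [probability_raster()], for confidence extraction).
#' @export
combine_ensemble <- function(prob_rasters) {
  stopifnot(length(prob_rasters) >= 1L,
            all(vapply(prob_rasters, inherits, TRUE, "probability_raster")))
  d <- dim(prob_rasters[[1]]$probs)
  sp <- prob_rasters[[1]]$spacing_um_per_px
  for (r in prob_rasters)
    if (!identical(dim(r$probs), d) || r$spacing_um_per_px != sp)
      stop("ensemble members must share shape and spacing")
  mean_probs <- prob_rasters[[1]]$probs
  if (length(prob_rasters) > 1L) {
    for (r in prob_rasters[-1]) mean_probs <- mean_probs + r$probs
    mean_probs <- mean_probs / length(prob_rasters)
  }
  flat <- matrix(mean_probs, nrow = d[1] * d[2], ncol = d[3])
  lab <- matrix(max.col(flat, ties.method = "first") - 1L, nrow = d[1])
  list(labels = label_raster(lab, sp),
       mean_probs = probability_raster(mean_probs, sp))
}

#' Decode a label raster into point detections
#'
#' Postprocessing of a (combined) segmentation output: membrane labels are
#' relabelled as healthy tissue, 8-connected components of each class's body
#' label are extracted, components with equivalent radius `sqrt(area/pi)`
#' below `min_component_radius_px` are removed, and surviving area centroids
#' are greedily deduplicated: components are visited by decreasing area
#' (ties: class order, then row-major centroid) and a centroid strictly
#' closer than `min_centroid_distance_px` (Euclidean, across classes) to an
#' already-kept centroid is suppressed.
#'
#' @param labels a [label_raster()].
#' @param mean_probs optional [probability_raster()]; when given, each
#'   detection's confidence is the mean of its class-body channel over the
#'   component pixels, otherwise 1.0.
#' @param config a [toolkit_config()] supplying the two thresholds.
#' @param image_id,source_id identifiers for the returned set.
#' @return A [point_annotation_set()] of detections with confidences.
#' @export
decode_mask_to_points <- function(labels, mean_probs = NULL,
                                  config = toolkit_config(),
                                  image_id = "image", source_id = "decoder") {
  stopifnot(inherits(labels, "label_raster"))
  lab <- labels$labels
  lab[lab >= 5L] <- 1L  # membranes become healthy tissue
  comps <- list()
  for (k in 1:3) {
    cc <- .label_components8(lab == (1L + k))
    ncomp <- max(cc)
    if (ncomp == 0L) next
    idx <- which(cc > 0L)
    id <- cc[idx]
    rows <- (idx - 1L) %% nrow(cc) + 1L
    cols <- (idx - 1L) %/% nrow(cc) + 1L
    area <- tabulate(id, ncomp)
    cx <- rowsum(as.numeric(cols - 1L), id)[, 1] / area
    cy <- rowsum(as.numeric(rows - 1L), id)[, 1] / area
    conf <- rep(1.0, ncomp)
    if (!is.null(mean_probs)) {
      ch <- mean_probs$probs[, , 2L + k]
      conf <- rowsum(as.numeric(ch[idx]), id)[, 1] / area
    }
    comps[[k]] <- data.frame(class_idx = k, area = area,
                             x_px = cx, y_px = cy, confidence = conf)
  }
  det <- if (length(comps)) do.call(rbind, comps) else
    data.frame(class_idx = integer(0), area = numeric(0), x_px = numeric(0),
               y_px = numeric(0), confidence = numeric(0))
  # equivalent-radius filter: sqrt(area/pi) < r_min  <=>  area < pi r_min^2
  det <- det[det$area >= pi * config$min_component_radius_px^2, , drop = FALSE]
  if (nrow(det)) {
    ord <- order(-det$area, det$class_idx, det$y_px, det$x_px)
    det <- det[ord, , drop = FALSE]
    keep <- logical(nrow(det))
    kx <- numeric(0); ky <- numeric(0)
    dmin <- config$min_centroid_distance_px
    for (i in seq_len(nrow(det))) {
      if (length(kx) == 0L ||
          all((kx - det$x_px[i])^2 + (ky - det$y_px[i])^2 >= dmin^2)) {
        keep[i] <- TRUE
        kx <- c(kx, det$x_px[i]); ky <- c(ky, det$y_px[i])
      }
    }
    det <- det[keep, , drop = FALSE]
  }
  point_annotation_set(
    if (nrow(det)) data.frame(x_px = det$x_px, y_px = det$y_px,
                              class = cell_classes()[det$class_idx],
                              confidence = det$confidence) else NULL,
    image_id = image_id, source_id = source_id,
    spacing_um_per_px = labels$spacing_um_per_px,
    bounds = c(ncol(labels$labels), nrow(labels$labels)))
}

#' Convert detection boxes to center points
#'
#' One point per box at the box center, carrying the box's class and score
#' as confidence. Intended for fused bounding-box detector output.
#'
#' @param boxes data.frame with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `class`, `score`.
#' @param spacing_um_per_px pixel size for the returned set.
#' @param image_id,source_id identifiers.
#' @return A [point_annotation_set()].
#' @export
boxes_to_points <- function(boxes, spacing_um_per_px = 0.5,
                            image_id = "image", source_id = "boxes") {
  boxes <- as.data.frame(boxes)
  if (nrow(boxes)) {
    stopifnot(all(c("x_min", "y_min", "x_max", "y_max", "class", "score")
                  %in% names(boxes)))
    if (any(boxes$x_min >= boxes$x_max | boxes$y_min >= boxes$y_max))
      stop("degenerate box: x_min < x_max and y_min < y_max required")
  }
  pts <- if (nrow(boxes)) data.frame(
    x_px = (boxes$x_min + boxes$x_max) / 2,
    y_px = (boxes$y_min + boxes$y_max) / 2,
    class = boxes$class, confidence = boxes$score) else NULL
  point_annotation_set(pts, image_id = image_id, source_id = source_id,
                       spacing_um_per_px = spacing_um_per_px)
}
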