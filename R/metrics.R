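# Hit-radius detection scoring: one-to-one point matching under a physical
# distance criterion, per-class and overall F1, and the two lesion-level
# agreement measures (1 - NAE on counts, Jensen-Shannon similarity on class
# distributions).

#' Match predicted against reference points under a hit radius
#'
#' A prediction can match a reference annotation if their distance is at
#' most `hit_radius_um` micrometers (and, when `class_aware`, the classes
#' agree). Matching is greedy one-to-one:
#'
#' * `order = "DISTANCE"`: all admissible pairs are accepted in order of
#'   ascending distance (ties: lower prediction index, then lower reference
#'   index). Symmetric in its arguments, used for reader--reader pairs.
#' * `order = "CONFIDENCE"`: predictions are visited by descending
#'   confidence (ties: lower index) and each takes its nearest free
#'   admissible reference (ties: lower reference index). Used for
#'   model-versus-reference scoring; requires confidences.
#'
#' @param pred,ref [point_annotation_set()]s at the same spacing.
#' @param hit_radius_um hit radius in micrometers (default 10).
#' @param class_aware require equal classes for a match (default TRUE).
#' @param order `"DISTANCE"` or `"CONFIDENCE"`.
#' @return Object of class `match_result`: `matched_pairs` (data.frame of
#'   `pred_idx`, `ref_idx`, `distance_um`), `unmatched_pred`,
#'   `unmatched_ref` (integer indices), plus the matching parameters.
#' @export
match_points <- function(pred, ref, hit_radius_um = 10, class_aware = TRUE,
                         order = c("DISTANCE", "CONFIDENCE")) {
  order <- match.arg(order)
  stopifnot(inherits(pred, "point_annotation_set"),
            inherits(ref, "point_annotation_set"))
  if (pred$spacing_um_per_px != ref$spacing_um_per_px)
    stop("pred and ref sets must share spacing_um_per_px")
  sp <- pred$spacing_um_per_px
  P <- pred$points; R <- ref$points
  np <- nrow(P); nr <- nrow(R)
  if (order == "CONFIDENCE" && np > 0L && anyNA(P$confidence))
    stop("order = CONFIDENCE requires confidences on all predictions")
  cand <- NULL
  if (np > 0L && nr > 0L) {
    dum <- sqrt(outer(P$x_px, R$x_px, `-`)^2 +
                  outer(P$y_px, R$y_px, `-`)^2) * sp
    adm <- dum <= hit_radius_um
    if (class_aware)
      adm <- adm & outer(as.integer(P$class), as.integer(R$class), `==`)
    idx <- which(adm, arr.ind = TRUE)
    if (nrow(idx))
      cand <- data.frame(pred_idx = idx[, 1], ref_idx = idx[, 2],
                         distance_um = dum[idx])
  }
  pred_used <- logical(np); ref_used <- logical(nr)
  pairs <- list()
  if (!is.null(cand)) {
    if (order == "DISTANCE") {
      cand <- cand[order(cand$distance_um, cand$pred_idx, cand$ref_idx), ]
      for (k in seq_len(nrow(cand))) {
        i <- cand$pred_idx[k]; j <- cand$ref_idx[k]
        if (!pred_used[i] && !ref_used[j]) {
          pred_used[i] <- TRUE; ref_used[j] <- TRUE
          pairs[[length(pairs) + 1L]] <- cand[k, ]
        }
      }
    } else {
      by_pred <- split(cand, cand$pred_idx)
      pred_order <- base::order(-P$confidence, seq_len(np))
      for (i in pred_order) {
        ci <- by_pred[[as.character(i)]]
        if (is.null(ci)) next
        ci <- ci[!ref_used[ci$ref_idx], , drop = FALSE]
        if (!nrow(ci)) next
        ci <- ci[order(ci$distance_um, ci$ref_idx), , drop = FALSE]
        pred_used[i] <- TRUE; ref_used[ci$ref_idx[1]] <- TRUE
        pairs[[length(pairs) + 1L]] <- ci[1, ]
      }
    }
  }
  matched <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pred_idx = integer(0), ref_idx = integer(0),
               distance_um = numeric(0))
  rownames(matched) <- NULL
  structure(list(matched_pairs = matched,
                 unmatched_pred = which(!pred_used),
                 unmatched_ref = which(!ref_used),
                 class_aware = class_aware, hit_radius_um = hit_radius_um,
                 order = order),
            class = "match_result")
}

#' Maximum-cardinality matching oracle
#'
#' Exact maximum one-to-one matching on the admissible-pair graph
#' (augmenting-path search). A test oracle for the greedy matcher; refuses
#' instances with `|pred| * |ref| > 1e4`.
#'
#' @inheritParams match_points
#' @return A `match_result` (pair distances included; ordering arbitrary).
#' @export
oracle_max_matching <- function(pred, ref, hit_radius_um = 10,
                                class_aware = TRUE) {
  P <- pred$points; R <- ref$points
  np <- nrow(P); nr <- nrow(R)
  if (np * nr > 1e4) stop("instance too large for the matching oracle")
  if (pred$spacing_um_per_px != ref$spacing_um_per_px)
    stop("pred and ref sets must share spacing_um_per_px")
  sp <- pred$spacing_um_per_px
  adj <- vector("list", np)
  dum <- NULL
  if (np > 0L && nr > 0L) {
    dum <- sqrt(outer(P$x_px, R$x_px, `-`)^2 +
                  outer(P$y_px, R$y_px, `-`)^2) * sp
    adm <- dum <= hit_radius_um
    if (class_aware)
      adm <- adm & outer(as.integer(P$class), as.integer(R$class), `==`)
    for (i in seq_len(np)) adj[[i]] <- which(adm[i, ])
  }
  match_of_ref <- integer(nr)  # 0 = free
  # recursive Kuhn augmenting-path search, visited refs shared via env
  aug <- function(i, visited_env) {
    for (j in adj[[i]]) {
      if (visited_env$v[j]) next
      visited_env$v[j] <- TRUE
      if (match_of_ref[j] == 0L || aug(match_of_ref[j], visited_env)) {
        match_of_ref[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(np)) {
    env <- new.env(); env$v <- logical(nr)
    aug(i, env)
  }
  mj <- which(match_of_ref > 0L)
  matched <- data.frame(pred_idx = match_of_ref[mj], ref_idx = mj,
                        distance_um = if (length(mj))
                          dum[cbind(match_of_ref[mj], mj)] else numeric(0))
  structure(list(matched_pairs = matched,
                 unmatched_pred = setdiff(seq_len(np), matched$pred_idx),
                 unmatched_ref = setdiff(seq_len(nr), mj),
                 class_aware = class_aware, hit_radius_um = hit_radius_um,
                 order = "ORACLE"),
            class = "match_result")
}

#' Detection metrics for a prediction/reference pair
#'
#' Per-class precision, recall and F1 from a class-aware matching; the
#' overall F1 is the unweighted mean of the three per-class F1 values; the
#' any-tumor F1 comes from an independent class-blind matching. A class with
#' zero reference and zero predicted cells scores F1 = 1; with only one side
#' empty, F1 = 0. Also computes lesion-style agreement on the whole sets:
#' `count_agreement` (1 - NAE of total counts) and `js_similarity` of the
#' class distributions.
#'
#' @inheritParams match_points
#' @param match optional precomputed class-aware `match_result`.
#' @return Object of class `metrics_bundle`.
#' @export
f1_scores <- function(pred, ref, hit_radius_um = 10,
                      order = c("DISTANCE", "CONFIDENCE"), match = NULL) {
  order <- match.arg(order)
  if (is.null(match))
    match <- match_points(pred, ref, hit_radius_um, TRUE, order)
  blind <- match_points(pred, ref, hit_radius_um, FALSE, order)
  P <- pred$points; R <- ref$points
  cls <- cell_classes()
  per <- data.frame(class = cls, tp = 0L, fp = 0L, fn = 0L,
                    precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  tp_class <- as.integer(R$class[match$matched_pairs$ref_idx])
  for (k in 1:3) {
    tp <- sum(tp_class == k)
    fp <- sum(as.integer(P$class[match$unmatched_pred]) == k)
    fn <- sum(as.integer(R$class[match$unmatched_ref]) == k)
    if (tp + fp + fn == 0L) {
      pr <- re <- f1 <- 1
    } else {
      pr <- if (tp + fp > 0L) tp / (tp + fp) else 0
      re <- if (tp + fn > 0L) tp / (tp + fn) else 0
      f1 <- if (pr + re > 0) 2 * pr * re / (pr + re) else 0
    }
    per[k, c("tp", "fp", "fn")] <- c(tp, fp, fn)
    per[k, c("precision", "recall", "f1")] <- c(pr, re, f1)
  }
  tp_b <- nrow(blind$matched_pairs)
  fp_b <- length(blind$unmatched_pred); fn_b <- length(blind$unmatched_ref)
  f1_any <- if (tp_b + fp_b + fn_b == 0L) 1 else {
    pr <- if (tp_b + fp_b > 0L) tp_b / (tp_b + fp_b) else 0
    re <- if (tp_b + fn_b > 0L) tp_b / (tp_b + fn_b) else 0
    if (pr + re > 0) 2 * pr * re / (pr + re) else 0
  }
  cnt_p <- tabulate(as.integer(P$class), 3L)
  cnt_r <- tabulate(as.integer(R$class), 3L)
  structure(list(per_class = per,
                 f1_overall = mean(per$f1),
                 f1_any_tumor = f1_any,
                 count_agreement = count_agreement(nrow(P), nrow(R)),
                 js_similarity = js_similarity(cnt_p, cnt_r),
                 n_pred = nrow(P), n_ref = nrow(R),
                 hit_radius_um = hit_radius_um, order = order),
            class = "metrics_bundle")
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat("<metrics_bundle> n_pred:", x$n_pred, " n_ref:", x$n_ref, "\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("  F1 overall %.4f | any-tumor %.4f | 1-NAE %.4f | JS sim %.4f\n",
              x$f1_overall, x$f1_any_tumor, x$count_agreement, x$js_similarity))
  invisible(x)
}

#' F1 as a function of the confidence threshold
#'
#' Scores predictions with confidence at or above each threshold and
#' reports the full curve plus the threshold maximizing the overall F1.
#'
#' @inheritParams f1_scores
#' @param thresholds numeric grid of confidence thresholds (non-empty).
#' @return List with `curve` (data.frame: threshold, f1_overall,
#'   f1_any_tumor, n_pred) and `best_threshold`.
#' @export
f1_versus_threshold <- function(pred, ref, thresholds, hit_radius_um = 10,
                                order = c("DISTANCE", "CONFIDENCE")) {
  order <- match.arg(order)
  if (length(thresholds) == 0L) stop("threshold grid must be non-empty")
  if (nrow(pred$points) && anyNA(pred$points$confidence))
    stop("f1_versus_threshold requires confidences on predictions")
  rows <- lapply(thresholds, function(t) {
    keep <- pred$points$confidence >= t
    sub <- point_annotation_set(pred$points[keep, , drop = FALSE],
                                lesions = pred$lesions, tissue = pred$tissue,
                                image_id = pred$image_id,
                                source_id = pred$source_id,
                                spacing_um_per_px = pred$spacing_um_per_px)
    mb <- f1_scores(sub, ref, hit_radius_um, order)
    data.frame(threshold = t, f1_overall = mb$f1_overall,
               f1_any_tumor = mb$f1_any_tumor, n_pred = mb$n_pred)
  })
  curve <- do.call(rbind, rows)
  list(curve = curve,
       best_threshold = curve$threshold[which.max(curve$f1_overall)])
}

#' Agreement between two cell counts (1 - NAE)
#'
#' Normalized absolute error with the symmetric, bounded normalization
#' `|a - b| / max(a, b, 1)`; returned as the agreement `1 - NAE` in
#' \[0, 1\]. Two empty lesions agree perfectly by convention.
#'
#' @param n_a,n_b non-negative counts.
#' @return Agreement value in \[0, 1\].
#' @export
count_agreement <- function(n_a, n_b) {
  if (any(n_a < 0) || any(n_b < 0)) stop("counts must be non-negative")
  1 - abs(n_a - n_b) / pmax(n_a, n_b, 1)
}

#' Jensen-Shannon similarity of two class distributions
#'
#' `1 - JSD(a, b)` with the Jensen-Shannon divergence computed in base-2
#' logarithms (so the divergence, and hence the similarity, lies in
#' \[0, 1\]). Inputs are normalized to sum 1; `0 * log 0 = 0`. Two all-zero
#' vectors (both lesions empty) are perfectly similar by convention; an
#' all-zero vector against a non-zero one scores 0.
#'
#' @param dist_a,dist_b non-negative numeric vectors of equal length
#'   (class counts or fractions).
#' @return Similarity in \[0, 1\].
#' @export
js_similarity <- function(dist_a, dist_b) {
  if (any(dist_a < 0) || any(dist_b < 0))
    stop("distribution entries must be non-negative")
  stopifnot(length(dist_a) == length(dist_b))
  sa <- sum(dist_a); sb <- sum(dist_b)
  if (sa == 0 && sb == 0) return(1)
  if (sa == 0 || sb == 0) return(0)
  a <- dist_a / sa; b <- dist_b / sb
  m <- (a + b) / 2
  kl <- function(p, q) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / q[nz]))
  }
  jsd <- (kl(a, m) + kl(b, m)) / 2
  1 - jsd
}

#' Restrict a point set to lesion regions
#'
#' Keeps points inside any lesion polygon dilated by `buffer_um`
#' (even-odd rule; boundary points kept).
#'
#' @param set a [point_annotation_set()].
#' @param lesions non-empty list of lesion [region_polygon()]s.
#' @param buffer_um dilation radius in micrometers (default 0).
#' @return The filtered [point_annotation_set()].
#' @export
restrict_to_lesions <- function(set, lesions, buffer_um = 0) {
  stopifnot(inherits(set, "point_annotation_set"))
  if (length(lesions) == 0L) stop("lesions must be non-empty")
  p <- set$points
  keep <- if (nrow(p)) point_in_dilated_polygons(p$x_px, p$y_px, lesions,
                                                 buffer_um,
                                                 set$spacing_um_per_px)
  else logical(0)
  point_annotation_set(p[keep, , drop = FALSE], lesions = set$lesions,
                       tissue = set$tissue, image_id = set$image_id,
                       source_id = set$source_id,
                       spacing_um_per_px = set$spacing_um_per_px,
                       bounds = set$bounds)
}

#' Per-lesion detection and agreement metrics
#'
#' For every lesion polygon: restrict both sets to the lesion, then compute
#' the F1 fields, the count agreement on total tumor-cell counts and the
#' Jensen-Shannon similarity of the class-count vectors.
#'
#' @inheritParams f1_scores
#' @param lesions list of lesion [region_polygon()]s (default: the
#'   reference set's lesions).
#' @param buffer_um lesion dilation in micrometers (default 0).
#' @return data.frame with one row per lesion: `lesion_id`, `f1_overall`,
#'   `f1_any_tumor`, `count_agreement`, `js_similarity`, `n_pred`, `n_ref`.
#' @export
lesion_metrics <- function(pred, ref, lesions = ref$lesions, buffer_um = 0,
                           hit_radius_um = 10,
                           order = c("DISTANCE", "CONFIDENCE")) {
  order <- match.arg(order)
  if (length(lesions) == 0L) stop("lesions must be non-empty")
  rows <- lapply(lesions, function(poly) {
    pr <- restrict_to_lesions(pred, list(poly), buffer_um)
    rr <- restrict_to_lesions(ref, list(poly), buffer_um)
    mb <- f1_scores(pr, rr, hit_radius_um, order)
    data.frame(lesion_id = poly$region_id, f1_overall = mb$f1_overall,
               f1_any_tumor = mb$f1_any_tumor,
               count_agreement = mb$count_agreement,
               js_similarity = mb$js_similarity,
               n_pred = mb$n_pred, n_ref = mb$n_ref)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
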