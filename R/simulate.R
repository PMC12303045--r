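# Synthetic slide, oracle-segmenter and noisy-reader simulators. These
# generate ground truth with known properties so the codec, metrics and
# statistics run end-to-end without any real whole-slide image.

#' Parameters for the synthetic slide generator
#'
#' Defaults emulate the structure of an annotated HDGC slide at desk scale:
#' a 2048 x 2048 px tissue region holding a few non-overlapping tumor
#' lesions, each exhaustively annotated with tumor cells whose class mix
#' follows the dataset-wide proportions of 39% typical SRC, 30% atypical
#' SRC and 31% non-SRC. `min_spacing_px` defaults to
#' `2 * max(body_radius + membrane_width) + 1` = 23 px for the default
#' [class_geometry()], which guarantees that encoded cell bodies stay
#' disconnected and the codec round trip is exact; pass a smaller value to
#' exercise crowded-cell suppression behavior.
#'
#' @param extent_px raster size `c(width_px, height_px)`.
#' @param n_lesions number of lesions (0 allowed).
#' @param cells_per_lesion integer, or length-2 range sampled uniformly.
#' @param class_mix length-3 non-negative vector summing to 1.
#' @param min_spacing_px minimum pairwise cell spacing (pixels).
#' @param background_cell_rate density (per pixel^2) of healthy-tissue
#'   distractor locations recorded alongside the truth.
#' @param lesion_radius_px mean lesion radius in pixels.
#' @param spacing_um_per_px pixel size.
#' @param seed integer seed.
#' @return Object of class `slide_sim_params`.
#' @export
slide_sim_params <- function(extent_px = c(2048L, 2048L), n_lesions = 3L,
                             cells_per_lesion = 70L,
                             class_mix = c(0.39, 0.30, 0.31),
                             min_spacing_px = 23,
                             background_cell_rate = 0,
                             lesion_radius_px = 220,
                             spacing_um_per_px = 0.5, seed = 1L) {
  stopifnot(length(extent_px) == 2L, all(extent_px >= 64L),
            n_lesions >= 0L, all(class_mix >= 0),
            abs(sum(class_mix) - 1) < 1e-9, min_spacing_px >= 0,
            background_cell_rate >= 0, lesion_radius_px > 0)
  structure(list(extent_px = as.integer(extent_px),
                 n_lesions = as.integer(n_lesions),
                 cells_per_lesion = cells_per_lesion,
                 class_mix = class_mix, min_spacing_px = min_spacing_px,
                 background_cell_rate = background_cell_rate,
                 lesion_radius_px = lesion_radius_px,
                 spacing_um_per_px = spacing_um_per_px,
                 seed = as.integer(seed)),
            class = "slide_sim_params")
}

# Irregular star-convex polygon around a center (radial jitter keeps it
# simple by construction).
.random_blob <- function(cx, cy, radius, n_vert = 12L, wobble = 0.25) {
  th <- seq(0, 2 * pi, length.out = n_vert + 1L)[-(n_vert + 1L)]
  r <- radius * (1 + stats::runif(n_vert, -wobble, wobble))
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Generate a synthetic annotated slide
#'
#' Places non-overlapping lesion polygons inside a tissue polygon, then
#' dart-throws cell points inside each lesion with pairwise spacing at
#' least `min_spacing_px` (globally, across lesions) and classes drawn from
#' `class_mix`. Deterministic under the seed.
#'
#' @param params a [slide_sim_params()].
#' @return A ground-truth [point_annotation_set()] (source `"truth"`) with
#'   lesions, tissue and declared bounds. Healthy-tissue distractor
#'   locations, when requested, are in attribute `distractors`.
#' @export
generate_slide <- function(params = slide_sim_params()) {
  stopifnot(inherits(params, "slide_sim_params"))
  with_seed(params$seed, {
    W <- params$extent_px[1]; H <- params$extent_px[2]
    marg <- 8
    # tissue: rectangle with clipped corners (octagon)
    cut <- round(0.08 * min(W, H))
    tissue <- region_polygon(
      x = c(marg + cut, W - 1 - marg - cut, W - 1 - marg, W - 1 - marg,
            W - 1 - marg - cut, marg + cut, marg, marg),
      y = c(marg, marg, marg + cut, H - 1 - marg - cut, H - 1 - marg,
            H - 1 - marg, H - 1 - marg - cut, marg + cut),
      region_id = "tissue", kind = "TISSUE")
    lesions <- list()
    if (params$n_lesions > 0L) {
      rad <- params$lesion_radius_px
      # rejection placement with full restarts so an early bad draw cannot
      # block the remaining lesions
      centers <- NULL
      for (restart in 1:60) {
        centers <- matrix(numeric(0), ncol = 2)
        tries <- 0L
        while (nrow(centers) < params$n_lesions && tries < 400L) {
          tries <- tries + 1L
          cx <- stats::runif(1, 1.4 * rad, W - 1 - 1.4 * rad)
          cy <- stats::runif(1, 1.4 * rad, H - 1 - 1.4 * rad)
          if (nrow(centers) &&
              any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) <
                    2.6 * rad)) next
          centers <- rbind(centers, c(cx, cy))
        }
        if (nrow(centers) == params$n_lesions) break
      }
      if (nrow(centers) < params$n_lesions)
        stop("could not place non-overlapping lesions; lower n_lesions or lesion_radius_px")
      for (i in seq_len(nrow(centers))) {
        b <- .random_blob(centers[i, 1], centers[i, 2], rad)
        lesions[[i]] <- region_polygon(b$x, b$y,
                                       region_id = sprintf("lesion_%d", i),
                                       kind = "LESION")
      }
    }
    # dart-throw cells inside each lesion, spacing enforced globally
    acc_x <- numeric(0); acc_y <- numeric(0); acc_lesion <- integer(0)
    s2 <- params$min_spacing_px^2
    for (i in seq_along(lesions)) {
      n_cells <- if (length(params$cells_per_lesion) == 2L)
        sample(params$cells_per_lesion[1]:params$cells_per_lesion[2], 1L)
      else as.integer(params$cells_per_lesion)
      placed <- 0L; fails <- 0L
      while (placed < n_cells) {
        if (fails > 200L * n_cells + 2000L)
          stop("could not place ", n_cells, " cells at min_spacing_px = ",
               params$min_spacing_px, "; lower the density")
        cand <- .sample_points_in_polygon(1L, lesions[[i]])
        if (length(acc_x) == 0L ||
            all((acc_x - cand[1, 1])^2 + (acc_y - cand[1, 2])^2 >= s2)) {
          acc_x <- c(acc_x, cand[1, 1]); acc_y <- c(acc_y, cand[1, 2])
          acc_lesion <- c(acc_lesion, i)
          placed <- placed + 1L
        } else fails <- fails + 1L
      }
    }
    n <- length(acc_x)
    cls <- if (n) sample(cell_classes(), n, replace = TRUE,
                         prob = params$class_mix) else character(0)
    pts <- if (n) data.frame(x_px = acc_x, y_px = acc_y, class = cls,
                             confidence = NA_real_) else NULL
    out <- point_annotation_set(pts, lesions = lesions,
                                tissue = list(tissue),
                                image_id = sprintf("sim_%d", params$seed),
                                source_id = "truth",
                                spacing_um_per_px = params$spacing_um_per_px,
                                bounds = c(W, H))
    if (params$background_cell_rate > 0) {
      area <- polygon_area_px(tissue)
      n_d <- stats::rpois(1, params$background_cell_rate * area)
      if (n_d > 0) {
        d <- .sample_points_in_polygon(n_d, tissue, exclude = lesions,
                                       spacing_um_per_px = params$spacing_um_per_px)
        attr(out, "distractors") <- data.frame(x_px = d[, 1], y_px = d[, 2])
      }
    }
    out
  })
}

#' Render an oracle probability raster from ground truth
#'
#' Builds the ideal body/membrane label raster via
#' [encode_points_to_mask()], converts it to one-hot per-class
#' probabilities, then applies optional degradation: per-channel Gaussian
#' blur, per-pixel label flips (the one-hot vector is replaced by that of a
#' uniformly drawn different label) and multiplicative amplitude jitter,
#' followed by per-pixel renormalization. With all noise at zero the output
#' is exactly one-hot. This stands in for a trained segmentation network
#' with a controllable error rate.
#'
#' @param truth a ground-truth [point_annotation_set()] with bounds.
#' @param geometry a [class_geometry()].
#' @param noise list with `prob_blur_sigma` (px), `label_flip_rate`
#'   (fraction), `amplitude_jitter` (lognormal sd); missing entries are 0.
#' @param seed integer seed.
#' @return A [probability_raster()].
#' @export
render_probability_raster <- function(truth, geometry = class_geometry(),
                                      noise = list(), seed = NULL) {
  blur <- noise$prob_blur_sigma %||% 0
  flip <- noise$label_flip_rate %||% 0
  jit <- noise$amplitude_jitter %||% 0
  lab <- encode_points_to_mask(truth, geometry)$labels
  h <- nrow(lab); w <- ncol(lab)
  probs <- array(0, c(h, w, 8L))
  for (k in 0:7) probs[, , k + 1L] <- (lab == k) * 1.0
  with_seed(seed, {
    if (flip > 0) {
      npix <- h * w
      hit <- which(stats::runif(npix) < flip)
      if (length(hit)) {
        old <- lab[hit]
        new <- (old + sample.int(7L, length(hit), replace = TRUE)) %% 8L
        for (k in 0:7) {
          ch <- probs[, , k + 1L]
          ch[hit[old == k]] <- 0
          ch[hit[new == k]] <- 1
          probs[, , k + 1L] <- ch
        }
      }
    }
    if (blur > 0) {
      for (k in 1:8)
        probs[, , k] <- EBImage::gblur(probs[, , k], sigma = blur)
      probs[probs < 0] <- 0
    }
    if (jit > 0)
      probs <- probs * exp(stats::rnorm(length(probs), 0, jit))
    if (flip > 0 || blur > 0 || jit > 0) {
      sums <- rowSums(probs, dims = 2L)
      sums[sums == 0] <- 1
      probs <- probs / as.vector(sums)
      probs[probs > 1] <- 1
    }
    probability_raster(probs, truth$spacing_um_per_px)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameters of the noisy-reader simulator
#'
#' An observation model for inter-pathologist variability: each true cell
#' is missed independently with `miss_rate`; surviving points are jittered
#' by an isotropic Gaussian; the class is reassigned through a
#' row-stochastic confusion matrix; spurious points (expected
#' `spurious_rate` per true point) are added uniformly inside lesions with
#' classes from the reader's marginal class mix.
#'
#' @param miss_rate fraction in \[0, 1).
#' @param spurious_rate expected spurious points per true point, in
#'   \[0, 1).
#' @param jitter_sigma_px standard deviation of the location jitter.
#' @param class_confusion 3 x 3 row-stochastic matrix (rows = true class).
#' @param seed integer seed.
#' @return Object of class `reader_noise_params`.
#' @export
reader_noise_params <- function(miss_rate = 0, spurious_rate = 0,
                                jitter_sigma_px = 0,
                                class_confusion = diag(3), seed = NULL) {
  stopifnot(miss_rate >= 0, miss_rate < 1, spurious_rate >= 0,
            spurious_rate < 1, jitter_sigma_px >= 0,
            is.matrix(class_confusion), all(dim(class_confusion) == 3L),
            all(class_confusion >= 0),
            all(abs(rowSums(class_confusion) - 1) < 1e-9))
  structure(list(miss_rate = miss_rate, spurious_rate = spurious_rate,
                 jitter_sigma_px = jitter_sigma_px,
                 class_confusion = class_confusion,
                 seed = seed),
            class = "reader_noise_params")
}

#' Simulate a noisy human reader
#'
#' @param truth a ground-truth [point_annotation_set()].
#' @param noise a [reader_noise_params()].
#' @param source_id identifier for the simulated reader.
#' @return A [point_annotation_set()] without confidences.
#' @export
simulate_reader <- function(truth, noise = reader_noise_params(),
                            source_id = "reader") {
  stopifnot(inherits(truth, "point_annotation_set"),
            inherits(noise, "reader_noise_params"))
  with_seed(noise$seed, {
    p <- truth$points
    n <- nrow(p)
    keep <- if (n) stats::runif(n) >= noise$miss_rate else logical(0)
    p <- p[keep, , drop = FALSE]
    m <- nrow(p)
    if (m && noise$jitter_sigma_px > 0) {
      p$x_px <- p$x_px + stats::rnorm(m, 0, noise$jitter_sigma_px)
      p$y_px <- p$y_px + stats::rnorm(m, 0, noise$jitter_sigma_px)
      if (!is.null(truth$bounds)) {
        p$x_px <- pmin(pmax(p$x_px, 0), truth$bounds[1] - 1)
        p$y_px <- pmin(pmax(p$y_px, 0), truth$bounds[2] - 1)
      } else {
        p$x_px <- pmax(p$x_px, 0); p$y_px <- pmax(p$y_px, 0)
      }
    }
    if (m) {
      old <- as.integer(factor(as.character(p$class), levels = cell_classes()))
      newc <- vapply(old, function(k)
        sample.int(3L, 1L, prob = noise$class_confusion[k, ]), 0L)
      p$class <- cell_classes()[newc]
    }
    # spurious points: confined to lesions (the reader saw lesion crops)
    if (n && noise$spurious_rate > 0 && length(truth$lesions)) {
      n_sp <- stats::rpois(1, noise$spurious_rate * n)
      if (n_sp > 0) {
        areas <- vapply(truth$lesions, polygon_area_px, 0)
        pick <- sample.int(length(truth$lesions), n_sp, replace = TRUE,
                           prob = areas)
        mix <- as.vector(prop.table(table(factor(
          as.character(truth$points$class), levels = cell_classes()))))
        if (all(mix == 0) || anyNA(mix)) mix <- rep(1 / 3, 3)
        marg <- as.vector(mix %*% noise$class_confusion)
        sp_rows <- lapply(seq_len(n_sp), function(i) {
          loc <- .sample_points_in_polygon(1L, truth$lesions[[pick[i]]])
          data.frame(x_px = loc[1, 1], y_px = loc[1, 2],
                     class = sample(cell_classes(), 1L, prob = marg),
                     confidence = NA_real_)
        })
        p <- rbind(p, do.call(rbind, sp_rows))
      }
    }
    p$confidence <- NA_real_
    point_annotation_set(p, lesions = truth$lesions, tissue = truth$tissue,
                         image_id = truth$image_id, source_id = source_id,
                         spacing_um_per_px = truth$spacing_um_per_px,
                         bounds = truth$bounds)
  })
}

#' Simulate a panel of independent noisy readers
#'
#' @param truth a ground-truth [point_annotation_set()].
#' @param noise_list list of [reader_noise_params()], one per reader.
#' @param seeds optional integer vector overriding each reader's seed.
#' @return List of [point_annotation_set()]s, sources `"reader_1"`, ...
#' @export
simulate_reader_panel <- function(truth, noise_list, seeds = NULL) {
  stopifnot(length(noise_list) >= 1L)
  if (!is.null(seeds)) stopifnot(length(seeds) == length(noise_list))
  lapply(seq_along(noise_list), function(i) {
    np <- noise_list[[i]]
    if (!is.null(seeds)) np$seed <- seeds[i]
    simulate_reader(truth, np, source_id = sprintf("reader_%d", i))
  })
}
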