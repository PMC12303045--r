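#' Tumor cell classes
#'
#' The three tumor cell classes of the HDGC annotation taxonomy, in their
#' fixed order: typical signet ring cells (`TYPICAL_SRC`), atypical signet
#' ring cells (`ATYPICAL_SRC`) and non-signet-ring tumor cells (`NON_SRC`).
#' The ordering is load-bearing: it drives deterministic tie-breaking in the
#' mask codec and the raster label assignment (body labels 2--4, membrane
#' labels 5--7 follow this order).
#'
#' @return Character vector of the three class codes, in canonical order.
#' @export
cell_classes <- function() {
  c("TYPICAL_SRC", "ATYPICAL_SRC", "NON_SRC")
}

#' Display names for the tumor cell classes
#' @return Named character vector mapping class code to display name.
#' @export
cell_class_names <- function() {
  c(TYPICAL_SRC = "typical signet ring cell",
    ATYPICAL_SRC = "atypical signet ring cell",
    NON_SRC = "non-signet-ring tumor cell")
}

# Case-insensitive aliases accepted when resolving class labels from files.
.class_aliases <- function(extra = NULL) {
  al <- c(
    typical_src = "TYPICAL_SRC", typical = "TYPICAL_SRC",
    `typical src` = "TYPICAL_SRC", src_typical = "TYPICAL_SRC",
    atypical_src = "ATYPICAL_SRC", atypical = "ATYPICAL_SRC",
    `atypical src` = "ATYPICAL_SRC", src_atypical = "ATYPICAL_SRC",
    non_src = "NON_SRC", `non src` = "NON_SRC", nonsrc = "NON_SRC",
    `non-src` = "NON_SRC"
  )
  if (!is.null(extra)) al <- c(al, extra)
  al
}

#' Resolve free-text class labels to canonical class codes
#'
#' @param x character vector of class labels (case-insensitive; common
#'   aliases such as `"typical_src"` or `"non-SRC"` are accepted).
#' @param aliases optional named character vector of extra aliases
#'   (names = lowercase input, values = canonical code).
#' @return Factor with levels `cell_classes()`.
#' @export
resolve_cell_class <- function(x, aliases = NULL) {
  cls <- cell_classes()
  al <- .class_aliases(aliases)
  lx <- tolower(trimws(as.character(x)))
  out <- character(length(lx))
  direct <- toupper(lx) %in% cls
  out[direct] <- toupper(lx[direct])
  rest <- !direct
  hit <- al[lx[rest]]
  if (anyNA(hit)) {
    bad <- unique(lx[rest][is.na(hit)])
    stop("unknown cell class label(s): ", paste(bad, collapse = ", "))
  }
  out[rest] <- hit
  factor(out, levels = cls)
}

#' Raster label semantics
#'
#' The flat 8-label space used by the body/membrane mask codec:
#' 0 background, 1 healthy tissue, 2--4 cell body of each tumor class,
#' 5--7 cell membrane of each tumor class (class order as
#' [cell_classes()]).
#'
#' @return Named integer vector mapping semantic names to label codes.
#' @export
label_semantics <- function() {
  cls <- cell_classes()
  structure(0:7, names = c("background", "healthy",
                           paste0("body_", cls), paste0("membrane_", cls)))
}

#' Body label code for a class
#' @param cell_class class code or factor.
#' @return Integer label in 2..4.
#' @export
body_label <- function(cell_class) {
  1L + as.integer(factor(as.character(cell_class), levels = cell_classes()))
}

#' Membrane label code for a class
#' @param cell_class class code or factor.
#' @return Integer label in 5..7.
#' @export
membrane_label <- function(cell_class) {
  4L + as.integer(factor(as.character(cell_class), levels = cell_classes()))
}

#' Per-class body/membrane geometry for the mask codec
#'
#' Radii of the inner disk ("cell body") and width of the surrounding
#' annulus ("cell membrane") used when encoding point annotations as
#' segmentation targets, in pixels at the working resolution. The defaults
#' (typical 8/3, atypical 6/2, non-SRC 5/2 at 0.5 um/px) are toolkit
#' defaults reflecting the relative average sizes of the three tumor cell
#' types (typical > atypical > non-SRC); they are configurable.
#'
#' @param body_radius_px integer vector of length 3 (one per class, order as
#'   [cell_classes()]), each >= 1.
#' @param membrane_width_px integer vector of length 3, each >= 1.
#' @return Object of class `class_geometry`.
#' @export
class_geometry <- function(body_radius_px = c(8L, 6L, 5L),
                           membrane_width_px = c(3L, 2L, 2L)) {
  cls <- cell_classes()
  body_radius_px <- as.integer(body_radius_px)
  membrane_width_px <- as.integer(membrane_width_px)
  stopifnot(length(body_radius_px) == 3L, length(membrane_width_px) == 3L)
  if (any(body_radius_px < 1L) || any(membrane_width_px < 1L))
    stop("body_radius_px and membrane_width_px must all be >= 1")
  structure(list(body_radius_px = stats::setNames(body_radius_px, cls),
                 membrane_width_px = stats::setNames(membrane_width_px, cls)),
            class = "class_geometry")
}

#' Toolkit configuration
#'
#' Bundles the numeric conventions shared across the toolkit. Defaults:
#' working resolution 0.5 um/px, patch size 512 px, hit radius 10 um,
#' postprocessing thresholds of 2 px minimum equivalent component radius and
#' 10 px minimum centroid distance, 1000 bootstrap iterations at the 95%
#' confidence level.
#'
#' @param spacing_um_per_px physical pixel size in micrometers (> 0).
#' @param patch_size_px training patch edge length in pixels.
#' @param hit_radius_um maximum prediction-to-annotation distance, in
#'   micrometers, for a detection to count as a true positive.
#' @param min_component_radius_px components with equivalent radius
#'   `sqrt(area/pi)` strictly below this are discarded when decoding.
#' @param min_centroid_distance_px centroids strictly closer than this to an
#'   already-kept centroid are suppressed when decoding.
#' @param class_geometry a [class_geometry()].
#' @param bootstrap_iterations resampling iterations for [bootstrap_ci()].
#' @param confidence_level nominal coverage for confidence intervals.
#' @param rng_seed integer seed recorded for reproducibility.
#' @return Object of class `toolkit_config`.
#' @export
toolkit_config <- function(spacing_um_per_px = 0.5,
                           patch_size_px = 512L,
                           hit_radius_um = 10,
                           min_component_radius_px = 2,
                           min_centroid_distance_px = 10,
                           class_geometry = hdgcellkit::class_geometry(),
                           bootstrap_iterations = 1000L,
                           confidence_level = 0.95,
                           rng_seed = 1L) {
  vals <- c(spacing_um_per_px, patch_size_px, hit_radius_um,
            min_component_radius_px, min_centroid_distance_px,
            bootstrap_iterations, confidence_level)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all toolkit_config thresholds must be strictly positive")
  stopifnot(inherits(class_geometry, "class_geometry"),
            confidence_level < 1)
  structure(list(spacing_um_per_px = spacing_um_per_px,
                 patch_size_px = as.integer(patch_size_px),
                 hit_radius_um = hit_radius_um,
                 min_component_radius_px = min_component_radius_px,
                 min_centroid_distance_px = min_centroid_distance_px,
                 class_geometry = class_geometry,
                 bootstrap_iterations = as.integer(bootstrap_iterations),
                 confidence_level = confidence_level,
                 rng_seed = as.integer(rng_seed)),
            class = "toolkit_config")
}

#' Region polygon (lesion or tissue outline)
#'
#' A simple (non-self-intersecting) closed polygon in 0-based pixel
#' coordinates, origin top-left, x = column, y = row. The closing edge from
#' the last to the first vertex is implicit.
#'
#' @param x,y numeric vertex coordinates (pixels); the polygon must not
#'   repeat the first vertex at the end.
#' @param region_id identifier text.
#' @param kind `"LESION"` or `"TISSUE"`.
#' @return Object of class `region_polygon` with fields `region_id`, `kind`
#'   and an n x 2 `vertices` matrix.
#' @export
region_polygon <- function(x, y, region_id = "region", kind = c("LESION", "TISSUE")) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (x[1] == x[length(x)] && y[1] == y[length(y)] && length(x) > 3L) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  v <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (!.polygon_is_simple(v))
    stop("polygon must be simple (non-self-intersecting)")
  if (abs(.polygon_area(v)) <= 0)
    stop("polygon must have positive area")
  structure(list(region_id = as.character(region_id), kind = kind,
                 vertices = v),
            class = "region_polygon")
}

#' Point annotation set
#'
#' Typed, optionally confidence-weighted cell point annotations for one
#' image and one source (a human reader or a model), plus region polygons.
#' Coordinates are 0-based pixels (x = column, y = row) at
#' `spacing_um_per_px`. Human annotations carry no confidence
#' (`NA`), which is distinct from confidence 1.0.
#'
#' @param points data.frame with columns `x_px`, `y_px`, `class`
#'   (character or factor, resolved via [resolve_cell_class()]) and
#'   optionally `confidence` in \[0, 1\] (`NA` = absent).
#' @param lesions list of `region_polygon` objects of kind `"LESION"`.
#' @param tissue optional list of `region_polygon` objects of kind
#'   `"TISSUE"`.
#' @param image_id,source_id identifier text.
#' @param spacing_um_per_px physical pixel size (> 0).
#' @param bounds optional `c(width_px, height_px)`; when declared, all
#'   points must lie inside `[0, width) x [0, height)`.
#' @return Object of class `point_annotation_set`.
#' @export
point_annotation_set <- function(points = NULL, lesions = list(), tissue = list(),
                                 image_id = "image", source_id = "source",
                                 spacing_um_per_px = 0.5, bounds = NULL) {
  if (is.null(points) || nrow(points) == 0L) {
    points <- data.frame(x_px = numeric(0), y_px = numeric(0),
                         class = factor(character(0), levels = cell_classes()),
                         confidence = numeric(0))
  } else {
    points <- as.data.frame(points)
    stopifnot(all(c("x_px", "y_px", "class") %in% names(points)))
    if (!"confidence" %in% names(points)) points$confidence <- NA_real_
    points <- points[, c("x_px", "y_px", "class", "confidence")]
    points$x_px <- as.numeric(points$x_px)
    points$y_px <- as.numeric(points$y_px)
    points$class <- resolve_cell_class(points$class)
    points$confidence <- as.numeric(points$confidence)
    if (any(!is.finite(points$x_px)) || any(!is.finite(points$y_px)) ||
        any(points$x_px < 0) || any(points$y_px < 0))
      stop("point coordinates must be finite and non-negative")
    conf <- points$confidence
    if (any(!is.na(conf) & (conf < 0 | conf > 1)))
      stop("confidence values must lie in [0, 1]")
  }
  if (spacing_um_per_px <= 0) stop("spacing_um_per_px must be > 0")
  stopifnot(all(vapply(lesions, inherits, TRUE, "region_polygon")),
            all(vapply(tissue, inherits, TRUE, "region_polygon")))
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2L, all(bounds > 0))
    if (nrow(points) &&
        (any(points$x_px >= bounds[1]) || any(points$y_px >= bounds[2])))
      stop("points must lie within the declared image bounds")
  }
  rownames(points) <- NULL
  structure(list(image_id = as.character(image_id),
                 source_id = as.character(source_id),
                 spacing_um_per_px = spacing_um_per_px,
                 points = points, lesions = lesions, tissue = tissue,
                 bounds = bounds),
            class = "point_annotation_set")
}

#' @export
print.point_annotation_set <- function(x, ...) {
  cat("<point_annotation_set> image:", x$image_id, " source:", x$source_id,
      "\n  spacing:", x$spacing_um_per_px, "um/px;",
      nrow(x$points), "points;", length(x$lesions), "lesion(s);",
      length(x$tissue), "tissue polygon(s)\n")
  if (nrow(x$points)) {
    tab <- table(x$points$class)
    cat("  per class:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.toolkit_config <- function(x, ...) {
  cat("<toolkit_config> spacing", x$spacing_um_per_px, "um/px; patch",
      x$patch_size_px, "px; hit radius", x$hit_radius_um, "um;",
      "min component radius", x$min_component_radius_px, "px;",
      "min centroid distance", x$min_centroid_distance_px, "px\n")
  invisible(x)
}

#' Label raster
#'
#' A 2-D integer grid of codec labels 0--7 (see [label_semantics()]) with
#' physical pixel spacing. Stored as a base R matrix indexed `[row, col]`.
#'
#' @param labels integer matrix with values in 0..7.
#' @param spacing_um_per_px physical pixel size (> 0).
#' @return Object of class `label_raster`.
#' @export
label_raster <- function(labels, spacing_um_per_px = 0.5) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 7L)) stop("label values must lie in 0..7")
  if (spacing_um_per_px <= 0) stop("spacing_um_per_px must be > 0")
  structure(list(labels = labels, spacing_um_per_px = spacing_um_per_px),
            class = "label_raster")
}

#' Probability raster
#'
#' Per-class pixel probabilities over the 8-label codec space, stored as a
#' rows x cols x 8 array (channel k+1 holds label code k). Channel values
#' lie in \[0, 1\] and per-pixel channel sums must be 1 within 1e-6.
#'
#' @param probs numeric array of dimension `c(rows, cols, 8)`.
#' @param spacing_um_per_px physical pixel size (> 0).
#' @return Object of class `probability_raster`.
#' @export
probability_raster <- function(probs, spacing_um_per_px = 0.5) {
  stopifnot(is.array(probs), length(dim(probs)) == 3L)
  if (dim(probs)[3] != 8L)
    stop("probability raster must have 8 channels, got ", dim(probs)[3])
  if (any(probs < 0 | probs > 1)) stop("channel values must lie in [0, 1]")
  sums <- rowSums(probs, dims = 2L)
  if (any(abs(sums - 1) > 1e-6))
    stop("per-pixel channel sums must equal 1 within 1e-6")
  if (spacing_um_per_px <= 0) stop("spacing_um_per_px must be > 0")
  structure(list(probs = probs, spacing_um_per_px = spacing_um_per_px),
            class = "probability_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  cat("<label_raster>", nrow(x$labels), "x", ncol(x$labels), "px at",
      x$spacing_um_per_px, "um/px\n")
  invisible(x)
}

#' @export
print.probability_raster <- function(x, ...) {
  d <- dim(x$probs)
  cat("<probability_raster>", d[1], "x", d[2], "px,", d[3], "channels at",
      x$spacing_um_per_px, "um/px\n")
  invisible(x)
}

#' Convert micrometers to pixels and back
#'
#' @param um,px physical / pixel distances.
#' @param spacing_um_per_px pixel size in micrometers.
#' @return Converted numeric vector.
#' @export
um_to_px <- function(um, spacing_um_per_px) um / spacing_um_per_px

#' @rdname um_to_px
#' @export
px_to_um <- function(px, spacing_um_per_px) px * spacing_um_per_px

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
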