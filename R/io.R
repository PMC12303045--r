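# Readers and writers for the annotation and raster interchange formats.
# Coordinates in annotation files are pixels for ASAP-XML (the native unit of
# that dialect) and micrometers for CSV/GeoJSON tables; conversion happens at
# this boundary so everything downstream works in pixels.

#' Read an ASAP-XML annotation file
#'
#' Parses the dot-annotation dialect of the ASAP viewer: `Dot` annotations
#' carry their cell class in `PartOfGroup` (case-insensitive aliases
#' accepted), polygon annotations in group `"lesion"` (or `"tissue"`) become
#' region polygons. Coordinates are pixels at `spacing_um_per_px`.
#'
#' @param path XML file path.
#' @param spacing_um_per_px pixel size of the coordinate frame.
#' @param image_id,source_id identifiers for the returned set (default: file
#'   name).
#' @param aliases optional extra class aliases, see [resolve_cell_class()].
#' @return A [point_annotation_set()].
#' @export
read_asap_xml <- function(path, spacing_um_per_px = 0.5,
                          image_id = NULL, source_id = NULL, aliases = NULL) {
  doc <- xml2::read_xml(path)
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  pts <- list(); lesions <- list(); tissue <- list()
  for (a in anns) {
    type <- tolower(xml2::xml_attr(a, "Type"))
    grp <- xml2::xml_attr(a, "PartOfGroup")
    co <- xml2::xml_find_all(a, ".//Coordinate")
    cx <- as.numeric(xml2::xml_attr(co, "X"))
    cy <- as.numeric(xml2::xml_attr(co, "Y"))
    if (identical(type, "dot")) {
      if (length(cx) != 1L)
        stop("Dot annotation must have exactly one coordinate")
      conf <- xml2::xml_attr(a, "Confidence")
      pts[[length(pts) + 1L]] <- data.frame(
        x_px = cx, y_px = cy,
        class = as.character(resolve_cell_class(grp, aliases)),
        confidence = if (is.na(conf)) NA_real_ else as.numeric(conf))
    } else if (tolower(grp) %in% c("lesion", "tissue")) {
      ord <- order(as.integer(xml2::xml_attr(co, "Order")))
      poly <- region_polygon(cx[ord], cy[ord],
                             region_id = xml2::xml_attr(a, "Name"),
                             kind = toupper(grp))
      if (poly$kind == "LESION") lesions[[length(lesions) + 1L]] <- poly
      else tissue[[length(tissue) + 1L]] <- poly
    } else {
      stop("unknown annotation group: ", grp)
    }
  }
  base <- if (is.null(image_id)) sub("\\.[^.]*$", "", basename(path)) else image_id
  point_annotation_set(
    points = if (length(pts)) do.call(rbind, pts) else NULL,
    lesions = lesions, tissue = tissue,
    image_id = base,
    source_id = if (is.null(source_id)) base else source_id,
    spacing_um_per_px = spacing_um_per_px)
}

#' Write an ASAP-XML annotation file
#'
#' Emits the dialect read by [read_asap_xml()]: one `Dot` annotation per
#' point (class in `PartOfGroup`, confidence — when present — in a
#' `Confidence` attribute) and one polygon annotation per lesion/tissue
#' region. Coordinates are written at full double precision.
#'
#' @param set a [point_annotation_set()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_asap_xml <- function(set, path) {
  stopifnot(inherits(set, "point_annotation_set"))
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  fmt <- function(z) sprintf("%.17g", z)
  p <- set$points
  for (i in seq_len(nrow(p))) {
    a <- xml2::xml_add_child(anns, "Annotation",
                             Name = sprintf("cell_%d", i), Type = "Dot",
                             PartOfGroup = tolower(as.character(p$class[i])))
    if (!is.na(p$confidence[i]))
      xml2::xml_set_attr(a, "Confidence", fmt(p$confidence[i]))
    cs <- xml2::xml_add_child(a, "Coordinates")
    xml2::xml_add_child(cs, "Coordinate", Order = "0",
                        X = fmt(p$x_px[i]), Y = fmt(p$y_px[i]))
  }
  regions <- c(set$lesions, set$tissue)
  for (i in seq_along(regions)) {
    poly <- regions[[i]]
    a <- xml2::xml_add_child(anns, "Annotation", Name = poly$region_id,
                             Type = "Polygon",
                             PartOfGroup = tolower(poly$kind))
    cs <- xml2::xml_add_child(a, "Coordinates")
    for (k in seq_len(nrow(poly$vertices)))
      xml2::xml_add_child(cs, "Coordinate", Order = as.character(k - 1L),
                          X = fmt(poly$vertices[k, 1]),
                          Y = fmt(poly$vertices[k, 2]))
  }
  groups <- xml2::xml_add_child(doc, "AnnotationGroups")
  for (g in c(tolower(cell_classes()), "lesion", "tissue"))
    xml2::xml_add_child(groups, "Group", Name = g, PartOfGroup = "None")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a point table (CSV or GeoJSON)
#'
#' CSV columns are `x_um,y_um,class[,confidence]` with coordinates in
#' micrometers; GeoJSON is a FeatureCollection of `Point` features with a
#' `class` (and optional `confidence`) property and micrometer coordinates.
#' Micrometers are converted to pixels by dividing by `spacing_um_per_px`.
#'
#' @param path file path.
#' @param format `"CSV"` or `"GeoJSON"` (default: from the file extension).
#' @param spacing_um_per_px pixel size used for the conversion.
#' @param image_id,source_id identifiers for the returned set.
#' @return A [point_annotation_set()].
#' @export
read_points_table <- function(path, format = NULL, spacing_um_per_px = 0.5,
                              image_id = NULL, source_id = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "GeoJSON" else "CSV"
  }
  format <- match.arg(toupper(format), c("CSV", "GEOJSON"))
  base <- if (is.null(image_id)) sub("\\.[^.]*$", "", basename(path)) else image_id
  src <- if (is.null(source_id)) base else source_id
  if (format == "CSV") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("x_um", "y_um", "class")
    if (!all(need %in% names(tab)))
      stop("CSV is missing required column(s): ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    pts <- if (nrow(tab)) data.frame(
      x_px = tab$x_um / spacing_um_per_px,
      y_px = tab$y_um / spacing_um_per_px,
      class = tab$class,
      confidence = if ("confidence" %in% names(tab))
        as.numeric(tab$confidence) else NA_real_) else NULL
    return(point_annotation_set(pts, image_id = base, source_id = src,
                                spacing_um_per_px = spacing_um_per_px))
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pts <- list(); lesions <- list(); tissue <- list()
  for (feat in gj$features) {
    geom <- feat$geometry
    props <- feat$properties
    if (identical(geom$type, "Point")) {
      if (is.null(props$class)) stop("GeoJSON Point feature lacks a class property")
      conf <- props$confidence
      pts[[length(pts) + 1L]] <- data.frame(
        x_px = geom$coordinates[[1]] / spacing_um_per_px,
        y_px = geom$coordinates[[2]] / spacing_um_per_px,
        class = props$class,
        confidence = if (is.null(conf)) NA_real_ else as.numeric(conf))
    } else if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]
      vx <- vapply(ring, function(c) c[[1]], 0) / spacing_um_per_px
      vy <- vapply(ring, function(c) c[[2]], 0) / spacing_um_per_px
      kind <- toupper(if (is.null(props$kind)) "LESION" else props$kind)
      poly <- region_polygon(vx, vy,
                             region_id = if (is.null(props$region_id))
                               sprintf("region_%d", length(lesions) + length(tissue) + 1L)
                             else props$region_id,
                             kind = kind)
      if (kind == "LESION") lesions[[length(lesions) + 1L]] <- poly
      else tissue[[length(tissue) + 1L]] <- poly
    }
  }
  point_annotation_set(if (length(pts)) do.call(rbind, pts) else NULL,
                       lesions = lesions, tissue = tissue,
                       image_id = base, source_id = src,
                       spacing_um_per_px = spacing_um_per_px)
}

#' Write a point table (CSV or GeoJSON)
#'
#' Inverse of [read_points_table()]; pixel coordinates are converted back to
#' micrometers.
#'
#' @param set a [point_annotation_set()].
#' @param path output path.
#' @param format `"CSV"` or `"GeoJSON"` (default: from the extension).
#' @return Invisibly, `path`.
#' @export
write_points_table <- function(set, path, format = NULL) {
  stopifnot(inherits(set, "point_annotation_set"))
  if (is.null(format)) {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "GeoJSON" else "CSV"
  }
  format <- match.arg(toupper(format), c("CSV", "GEOJSON"))
  s <- set$spacing_um_per_px
  p <- set$points
  if (format == "CSV") {
    tab <- data.frame(x_um = p$x_px * s, y_um = p$y_px * s,
                      class = as.character(p$class), confidence = p$confidence)
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  feat_point <- function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(p$x_px[i] * s, p$y_px[i] * s)),
    properties = c(list(class = as.character(p$class[i])),
                   if (!is.na(p$confidence[i]))
                     list(confidence = p$confidence[i])))
  feat_poly <- function(poly) list(
    type = "Feature",
    geometry = list(type = "Polygon", coordinates = list(
      lapply(seq_len(nrow(poly$vertices)), function(k)
        c(poly$vertices[k, 1] * s, poly$vertices[k, 2] * s)))),
    properties = list(region_id = poly$region_id, kind = poly$kind))
  features <- c(lapply(seq_len(nrow(p)), feat_point),
                lapply(c(set$lesions, set$tissue), feat_poly))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a label raster to PNG (or single-page TIFF)
#'
#' Labels 0--7 are stored in an 8-bit grayscale image (value = label / 255),
#' which round-trips exactly.
#'
#' @param raster a [label_raster()].
#' @param path output path (`.png` or `.tif`).
#' @return Invisibly, `path`.
#' @export
write_label_raster <- function(raster, path) {
  stopifnot(inherits(raster, "label_raster"))
  img <- raster$labels / 255
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  else png::writePNG(img, path)
  invisible(path)
}

#' Write a probability raster to multi-page 32-bit float TIFF
#'
#' One page per channel (8 pages), in label-code order.
#'
#' @param raster a [probability_raster()].
#' @param path output path (`.tif`).
#' @return Invisibly, `path`.
#' @export
write_probability_raster <- function(raster, path) {
  stopifnot(inherits(raster, "probability_raster"))
  pages <- lapply(seq_len(dim(raster$probs)[3]),
                  function(k) raster$probs[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a raster (label or probability) by class
#'
#' Dispatches to [write_label_raster()] or [write_probability_raster()].
#'
#' @param raster a [label_raster()] or [probability_raster()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(raster, path) {
  if (inherits(raster, "label_raster")) write_label_raster(raster, path)
  else if (inherits(raster, "probability_raster"))
    write_probability_raster(raster, path)
  else stop("raster must be a label_raster or probability_raster")
}

#' Read a label or probability raster
#'
#' Single-page PNG/TIFF images load as a [label_raster()]; multi-page TIFFs
#' load as a [probability_raster()] and must have exactly 8 channels with
#' per-pixel sums of 1.
#'
#' @param path image path.
#' @param spacing_um_per_px pixel size to attach.
#' @return A [label_raster()] or [probability_raster()].
#' @export
read_raster <- function(path, spacing_um_per_px = 0.5) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(label_raster(round(img * 255), spacing_um_per_px))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1L) {
    img <- pages[[1]]
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(label_raster(round(img * 255), spacing_um_per_px))
  }
  if (length(pages) != 8L)
    stop("probability raster must have 8 channels, got ", length(pages))
  probs <- array(0, c(dim(pages[[1]]), 8L))
  for (k in 1:8) probs[, , k] <- pages[[k]]
  # float32 storage: renormalize away sub-1e-6 rounding, then validate
  sums <- rowSums(probs, dims = 2L)
  if (any(abs(sums - 1) > 1e-6))
    stop("probability raster channel sums deviate from 1 beyond 1e-6")
  probs <- probs / as.vector(sums)
  probability_raster(probs, spacing_um_per_px)
}

#' Read/write a toolkit configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_toolkit_config()]: a [toolkit_config()].
#' @export
read_toolkit_config <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- if (!is.null(y$class_geometry))
    class_geometry(unlist(y$class_geometry$body_radius_px),
                   unlist(y$class_geometry$membrane_width_px))
  else class_geometry()
  y$class_geometry <- NULL
  do.call(toolkit_config, c(y, list(class_geometry = geom)))
}

#' @rdname read_toolkit_config
#' @param config a [toolkit_config()].
#' @export
write_toolkit_config <- function(config, path) {
  stopifnot(inherits(config, "toolkit_config"))
  y <- unclass(config)
  y$class_geometry <- list(
    body_radius_px = as.integer(config$class_geometry$body_radius_px),
    membrane_width_px = as.integer(config$class_geometry$membrane_width_px))
  yaml::write_yaml(y, path)
  invisible(path)
}
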