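# Polygon utilities shared by the metrics, sampling and simulation modules.
# All coordinates are pixels (x = column, y = row, origin top-left).

# Signed shoelace area (positive for counter-clockwise in a y-down frame the
# sign is irrelevant here; callers use abs()).
.polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2]) / 2
}

#' Polygon area in square pixels
#' @param polygon a [region_polygon()].
#' @return Non-negative numeric area.
#' @export
polygon_area_px <- function(polygon) {
  abs(.polygon_area(polygon$vertices))
}

# Proper-intersection test between non-adjacent edges; O(n^2), polygons here
# are small (tens of vertices).
.polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (shared vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      o1 <- orient(a[1], a[2], b[1], b[2], c[1], c[2])
      o2 <- orient(a[1], a[2], b[1], b[2], d[1], d[2])
      o3 <- orient(c[1], c[2], d[1], d[2], a[1], a[2])
      o4 <- orient(c[1], c[2], d[1], d[2], b[1], b[2])
      if (o1 != o2 && o3 != o4 && o1 * o2 < 0 && o3 * o4 < 0) return(FALSE)
    }
  }
  TRUE
}

#' Even-odd point-in-polygon test
#'
#' Vectorized even-odd (ray crossing) rule; points exactly on the boundary
#' count as inside.
#'
#' @param px,py numeric point coordinates.
#' @param polygon a [region_polygon()] or an n x 2 vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, polygon) {
  v <- if (inherits(polygon, "region_polygon")) polygon$vertices else polygon
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | .on_polygon_boundary(px, py, v)
}

.on_polygon_boundary <- function(px, py, v, tol = 1e-9) {
  d <- .dist_to_polygon_boundary(px, py, v)
  d <= tol
}

# Minimum Euclidean distance from each point to the polygon boundary.
.dist_to_polygon_boundary <- function(px, py, v) {
  n <- nrow(v)
  dmin <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- v[j, 1]; ay <- v[j, 2]; bx <- v[i, 1]; by <- v[i, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2)) else 0
    qx <- ax + t * dx; qy <- ay + t * dy
    dmin <- pmin(dmin, sqrt((px - qx)^2 + (py - qy)^2))
    j <- i
  }
  dmin
}

#' Test points against polygons dilated by a physical buffer
#'
#' A point lies inside a polygon dilated by `buffer_um` iff it is inside the
#' polygon (even-odd rule, boundary inclusive) or within `buffer_um /
#' spacing` pixels of its boundary — the exact Minkowski dilation by a disk,
#' without constructing the offset polygon.
#'
#' @param px,py point coordinates in pixels.
#' @param polygons list of [region_polygon()] objects.
#' @param buffer_um non-negative dilation radius in micrometers.
#' @param spacing_um_per_px pixel size.
#' @return Logical vector: inside any dilated polygon.
#' @export
point_in_dilated_polygons <- function(px, py, polygons, buffer_um = 0,
                                      spacing_um_per_px = 0.5) {
  stopifnot(buffer_um >= 0)
  buf_px <- buffer_um / spacing_um_per_px
  inside <- rep(FALSE, length(px))
  for (poly in polygons) {
    v <- poly$vertices
    todo <- !inside
    if (!any(todo)) break
    hit <- point_in_polygon(px[todo], py[todo], v)
    if (buf_px > 0) {
      near <- .dist_to_polygon_boundary(px[todo], py[todo], v) <= buf_px
      hit <- hit | near
    }
    inside[todo] <- hit
  }
  inside
}

# Uniform sample of n points inside a polygon (rejection from the bbox).
.sample_points_in_polygon <- function(n, polygon, exclude = NULL,
                                      spacing_um_per_px = 0.5,
                                      exclude_buffer_um = 0, max_tries = 1000L) {
  v <- if (inherits(polygon, "region_polygon")) polygon$vertices else polygon
  xr <- range(v[, 1]); yr <- range(v[, 2])
  out_x <- numeric(0); out_y <- numeric(0)
  tries <- 0L
  while (length(out_x) < n && tries < max_tries) {
    m <- max(2L * (n - length(out_x)), 32L)
    cx <- stats::runif(m, xr[1], xr[2])
    cy <- stats::runif(m, yr[1], yr[2])
    keep <- point_in_polygon(cx, cy, v)
    if (!is.null(exclude) && length(exclude)) {
      keep <- keep & !point_in_dilated_polygons(cx, cy, exclude,
                                                exclude_buffer_um,
                                                spacing_um_per_px)
    }
    out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
    tries <- tries + 1L
  }
  if (length(out_x) < n)
    stop("could not place ", n, " points in polygon; region too constrained")
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}
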