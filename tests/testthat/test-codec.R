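test_that("a single encoded cell has the stated disk, annulus and tissue labels", {
  tis <- square_tissue(200, 200, margin = 0)
  s <- make_set(100, 100, "TYPICAL_SRC", tissue = list(tis),
                bounds = c(200, 200))
  geom <- class_geometry(c(8, 6, 5), c(3, 2, 2))
  m <- encode_points_to_mask(s, geom)$labels
  # disk area = count of pixels with center distance <= 8
  xs <- rep(0:199, each = 200); ys <- rep(0:199, 200)
  d <- sqrt((xs - 100)^2 + (ys - 100)^2)
  expect_equal(sum(m == 2L), sum(d <= 8))
  expect_equal(sum(m == 5L), sum(d > 8 & d <= 11))
  expect_equal(sum(m == 1L), sum(d > 11))
  expect_equal(sum(m == 0L), 0L)
})

test_that("empty point set with tissue covering all encodes to an all-healthy raster", {
  tis <- square_tissue(64, 64, margin = 0)
  s <- make_set(numeric(0), numeric(0), character(0), tissue = list(tis),
                bounds = c(64, 64))
  m <- encode_points_to_mask(s)$labels
  expect_true(all(m == 1L))
})

test_that("encode rejects points outside the extent and zero-area extents", {
  s <- make_set(500, 10, "TYPICAL_SRC")
  expect_error(encode_points_to_mask(s, extent = c(100, 100)), "outside")
  expect_error(encode_points_to_mask(s, extent = c(0, 100)), "positive area")
})

test_that("two separated same-class cells decode to two detections", {
  s <- make_set(c(60, 60 + 2 * 11 + 2), c(60, 60), rep("TYPICAL_SRC", 2),
                tissue = list(square_tissue(150, 150)), bounds = c(150, 150))
  m <- encode_points_to_mask(s)
  d <- decode_mask_to_points(m)
  expect_equal(nrow(d$points), 2L)
  expect_true(all(d$points$class == "TYPICAL_SRC"))
})

test_that("overlapping bodies resolve to the nearest center with class-order ties", {
  # two points 6 px apart, radius 8: overlap region split by proximity
  s <- make_set(c(50, 56), c(50, 50), c("NON_SRC", "TYPICAL_SRC"),
                bounds = c(100, 100))
  geom <- class_geometry(c(8, 8, 8), c(2, 2, 2))
  m <- encode_points_to_mask(s, geom)$labels
  expect_equal(m[51, 51], 4L)  # at first center -> NON_SRC body
  expect_equal(m[51, 57], 2L)  # at second center -> TYPICAL body
  # midpoint x = 53 is equidistant: tie goes to the lower class order (TYPICAL)
  expect_equal(m[51, 54], 2L)
})

test_that("ensemble combination averages then argmaxes with low-label ties", {
  # one-hot identity
  p <- array(0, c(4, 4, 8)); p[, , 3] <- 1
  r <- probability_raster(p)
  cmb <- combine_ensemble(list(r))
  expect_true(all(cmb$labels$labels == 2L))
  # channel means 0.4 / 0.6 for labels 2 and 3 -> label 3
  a <- array(0, c(1, 1, 8)); a[1, 1, 3] <- 0.8; a[1, 1, 4] <- 0.2
  b <- array(0, c(1, 1, 8)); b[1, 1, 3] <- 0.0; b[1, 1, 4] <- 1.0
  cmb2 <- combine_ensemble(list(probability_raster(a), probability_raster(b)))
  expect_equal(as.integer(cmb2$labels$labels), 3L)
  expect_equal(cmb2$mean_probs$probs[1, 1, 4], 0.6)
  # exact tie 0.5/0.5 between labels 2 and 5 -> label 2
  t1 <- array(0, c(1, 1, 8)); t1[1, 1, 3] <- 0.5; t1[1, 1, 6] <- 0.5
  cmb3 <- combine_ensemble(list(probability_raster(t1)))
  expect_equal(as.integer(cmb3$labels$labels), 2L)
  # k identical rasters equal a single one
  cmb4 <- combine_ensemble(list(r, r, r))
  expect_identical(cmb4$labels$labels, cmb$labels$labels)
  expect_equal(cmb4$mean_probs$probs, cmb$mean_probs$probs)
  small <- array(0, c(2, 2, 8)); small[, , 1] <- 1
  expect_error(combine_ensemble(list(r, probability_raster(small))),
               "share shape")
})

test_that("small-component and close-centroid thresholds follow the stated rules", {
  cfg <- toolkit_config()
  mk <- function(areas, gap) {
    # horizontal runs of given pixel areas (height 1), far apart vertically
    m <- matrix(0L, 60, 200)
    for (i in seq_along(areas)) m[10 + 20 * (i - 1), 1:areas[i]] <- 2L
    label_raster(m)
  }
  # area 12 -> equivalent radius sqrt(12/pi) < 2 -> dropped
  expect_equal(nrow(decode_mask_to_points(mk(12), config = cfg)$points), 0L)
  # area 13 -> kept
  expect_equal(nrow(decode_mask_to_points(mk(13), config = cfg)$points), 1L)
  # centroids 8 px apart -> one survives; 12 px apart -> both survive
  two_disks <- function(dx) {
    # radius-3 disks (area 29 > pi*2^2) that stay disconnected at dx = 8
    m <- matrix(0L, 80, 80)
    for (cx in c(30, 30 + dx)) {
      xs <- rep(1:80, each = 80); ys <- rep(1:80, 80)
      sel <- (xs - cx)^2 + (ys - 40)^2 <= 3^2
      m[cbind(ys[sel], xs[sel])] <- 2L
    }
    label_raster(m)
  }
  expect_equal(nrow(decode_mask_to_points(two_disks(8), config = cfg)$points), 1L)
  expect_equal(nrow(decode_mask_to_points(two_disks(12), config = cfg)$points), 2L)
  # suppression keeps the larger component
  m <- matrix(0L, 40, 120)
  m[10, 1:50] <- 2L   # area 50, centroid x ~ 24.5
  m[12, 20:49] <- 3L  # area 30, centroid x ~ 33.5, ~9.2 px away
  d <- decode_mask_to_points(label_raster(m), config = cfg)
  expect_equal(nrow(d$points), 1L)
  expect_equal(as.character(d$points$class), "TYPICAL_SRC")
})

test_that("decode confidence is the component mean of the class body channel", {
  m <- matrix(0L, 30, 30)
  m[10:14, 10:14] <- 2L  # 25-px square body
  p <- array(0, c(30, 30, 8)); p[, , 1] <- 1
  p[10:14, 10:14, 1] <- 0.4; p[10:14, 10:14, 3] <- 0.6
  d <- decode_mask_to_points(label_raster(m), probability_raster(p))
  expect_equal(d$points$confidence, 0.6)
  d2 <- decode_mask_to_points(label_raster(m))
  expect_equal(d2$points$confidence, 1.0)
})

test_that("connected component labelling is 8-connected (matches a BFS oracle)", {
  set.seed(42)
  for (i in 1:20) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    got <- hdgcellkit:::.label_components8(mask)
    want <- oracle_components8(mask)
    expect_equal(max(got), max(want))
    # same partition: component ids co-vary
    if (max(want) > 0) {
      key <- paste(got[mask], want[mask])
      expect_equal(length(unique(key)), max(want))
    }
  }
})

test_that("codec round trip recovers all points within 1.5 px on random well-spaced sets", {
  set.seed(99)
  for (i in 1:10) {
    truth <- small_slide(seed = 1000 + i)
    m <- encode_points_to_mask(truth)
    d <- decode_mask_to_points(m)
    expect_equal(nrow(d$points), nrow(truth$points))
    mm <- match_points(d, truth, hit_radius_um = 1.5 * truth$spacing_um_per_px,
                       class_aware = TRUE)
    expect_equal(nrow(mm$matched_pairs), nrow(truth$points))
  }
})

test_that("decode is idempotent in per-class counts under re-encoding", {
  truth <- small_slide(seed = 5, cells = 40L)
  d1 <- decode_mask_to_points(encode_points_to_mask(truth))
  d1$bounds <- truth$bounds
  d2 <- decode_mask_to_points(encode_points_to_mask(d1, extent = truth$bounds))
  expect_equal(table(d2$points$class), table(d1$points$class))
})

test_that("detection counts are monotone non-increasing in both postprocessing thresholds", {
  truth <- generate_slide(slide_sim_params(extent_px = c(600, 600),
                                           n_lesions = 1, cells_per_lesion = 60,
                                           lesion_radius_px = 150,
                                           min_spacing_px = 12, seed = 21))
  m <- encode_points_to_mask(truth)
  n_at <- function(rmin, dmin) nrow(decode_mask_to_points(
    m, config = toolkit_config(min_component_radius_px = rmin,
                               min_centroid_distance_px = dmin))$points)
  rs <- c(0.5, 2, 4, 6); ds <- c(1, 5, 10, 20)
  expect_true(all(diff(vapply(rs, n_at, 0, dmin = 10)) <= 0))
  expect_true(all(diff(vapply(ds, n_at, 0, rmin = 2)) <= 0))
})

test_that("boxes convert to center points with class and score", {
  boxes <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 20,
                      class = "TYPICAL_SRC", score = 0.7)
  s <- boxes_to_points(boxes)
  expect_equal(s$points$x_px, 5)
  expect_equal(s$points$y_px, 10)
  expect_equal(s$points$confidence, 0.7)
  expect_equal(nrow(boxes_to_points(data.frame())$points), 0L)
  set.seed(3)
  b5 <- data.frame(x_min = runif(5, 0, 10), y_min = runif(5, 0, 10),
                   x_max = runif(5, 20, 30), y_max = runif(5, 20, 30),
                   class = sample(cell_classes(), 5, TRUE),
                   score = runif(5))
  s5 <- boxes_to_points(b5)
  expect_equal(s5$points$confidence, b5$score)
  expect_equal(s5$points$x_px, (b5$x_min + b5$x_max) / 2)
  bad <- b5; bad$x_max[1] <- bad$x_min[1]
  expect_error(boxes_to_points(bad), "degenerate")
})
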