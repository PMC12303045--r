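test_that("hit-radius matching follows the distance and class rules", {
  ref <- make_set(0, 0, "TYPICAL_SRC")
  # 15 px at 0.5 um/px = 7.5 um <= 10 -> matched
  m1 <- match_points(make_set(15, 0, "TYPICAL_SRC"), ref)
  expect_equal(nrow(m1$matched_pairs), 1L)
  expect_equal(m1$matched_pairs$distance_um, 7.5)
  # 25 px = 12.5 um -> FP + FN
  m2 <- match_points(make_set(25, 0, "TYPICAL_SRC"), ref)
  expect_equal(nrow(m2$matched_pairs), 0L)
  expect_equal(m2$unmatched_pred, 1L)
  expect_equal(m2$unmatched_ref, 1L)
  # class-aware: wrong class at zero distance is no match
  m3 <- match_points(make_set(0, 0, "ATYPICAL_SRC"), ref, class_aware = TRUE)
  expect_equal(nrow(m3$matched_pairs), 0L)
  m4 <- match_points(make_set(0, 0, "ATYPICAL_SRC"), ref, class_aware = FALSE)
  expect_equal(nrow(m4$matched_pairs), 1L)
  # identical sets fully match
  set.seed(1); s <- random_set(20)
  m5 <- match_points(s, s)
  expect_equal(nrow(m5$matched_pairs), 20L)
  expect_length(m5$unmatched_pred, 0L)
  # spacing mismatch is an error
  expect_error(match_points(s, random_set(3, spacing = 0.25)), "spacing")
})

test_that("confidence-ordered matching takes predictions by descending confidence", {
  ref <- make_set(0, 0, "TYPICAL_SRC")
  pred <- make_set(c(8, 2), c(0, 0), rep("TYPICAL_SRC", 2),
                   confidence = c(0.9, 0.2))
  m <- match_points(pred, ref, order = "CONFIDENCE")
  # higher-confidence pred (index 1, farther) claims the only reference
  expect_equal(m$matched_pairs$pred_idx, 1L)
  expect_equal(m$unmatched_pred, 2L)
  expect_error(match_points(make_set(0, 0, "TYPICAL_SRC"), ref,
                            order = "CONFIDENCE"), "confidence")
})

test_that("F1 follows the formula and the empty-class conventions", {
  # TP=3 FP=1 FN=2 in one class: P=0.75 R=0.6 F1=0.666...
  ref <- make_set(c(0, 30, 60, 90, 120), rep(0, 5), rep("TYPICAL_SRC", 5))
  pred <- make_set(c(0, 30, 60, 300), rep(0, 4), rep("TYPICAL_SRC", 4))
  mb <- f1_scores(pred, ref)
  expect_equal(mb$per_class$tp[1], 3L)
  expect_equal(mb$per_class$fp[1], 1L)
  expect_equal(mb$per_class$fn[1], 2L)
  expect_equal(mb$per_class$precision[1], 0.75)
  expect_equal(mb$per_class$recall[1], 0.6)
  expect_equal(mb$per_class$f1[1], 2 * 0.45 / 1.35)
  # classes absent on both sides score 1; overall is the plain mean
  expect_equal(mb$per_class$f1[2:3], c(1, 1))
  expect_equal(mb$f1_overall, mean(mb$per_class$f1))
  # identical sets -> all ones
  mb2 <- f1_scores(ref, ref)
  expect_true(all(mb2$per_class$f1 == 1))
  expect_equal(mb2$f1_any_tumor, 1)
  # empty predictions vs non-empty reference -> 0 for the populated class
  mb3 <- f1_scores(make_set(numeric(0), numeric(0), character(0)), ref)
  expect_equal(mb3$per_class$f1[1], 0)
  expect_equal(mb3$f1_any_tumor, 0)
})

test_that("threshold sweep reproduces explicit filtering and finds the best threshold", {
  set.seed(8)
  ref <- random_set(30)
  pred <- random_set(40, with_conf = TRUE)
  th <- seq(0, 1, by = 0.25)
  sweep <- f1_versus_threshold(pred, ref, th)
  expect_equal(nrow(sweep$curve), length(th))
  # threshold 0 reproduces plain scoring
  expect_equal(sweep$curve$f1_overall[1], f1_scores(pred, ref)$f1_overall)
  # pointwise oracle: filter then score
  for (k in seq_along(th)) {
    keep <- pred$points$confidence >= th[k]
    sub <- make_set(pred$points$x_px[keep], pred$points$y_px[keep],
                    as.character(pred$points$class)[keep],
                    pred$points$confidence[keep])
    expect_equal(sweep$curve$f1_overall[k], f1_scores(sub, ref)$f1_overall)
  }
  # threshold above max confidence -> empty predictions convention
  above <- f1_versus_threshold(pred, ref, 1.01)
  expect_equal(above$curve$n_pred, 0L)
  expect_error(f1_versus_threshold(pred, ref, numeric(0)), "non-empty")
})

test_that("count agreement uses the symmetric max-denominator normalization", {
  expect_equal(count_agreement(10, 10), 1.0)
  expect_equal(count_agreement(0, 0), 1.0)
  expect_equal(count_agreement(8, 10), 0.8)
  expect_equal(count_agreement(10, 8), 0.8)
  expect_equal(count_agreement(0, 5), 0)
  expect_error(count_agreement(-1, 3), "non-negative")
})

test_that("JS similarity matches a brute-force divergence evaluation", {
  expect_equal(js_similarity(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 1.0)
  expect_equal(js_similarity(c(1, 0, 0), c(0, 1, 0)), 0.0)
  v <- js_similarity(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5))
  expect_equal(v, oracle_js_similarity(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)),
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:200) {
    a <- rgamma(3, 1); b <- rgamma(3, 1)
    expect_equal(js_similarity(a, b), oracle_js_similarity(a, b),
                 tolerance = 1e-12)
    expect_gte(js_similarity(a, b), 0)
    expect_lte(js_similarity(a, b), 1)
  }
  expect_equal(js_similarity(c(0, 0, 0), c(0, 0, 0)), 1)
  expect_equal(js_similarity(c(0, 0, 0), c(1, 0, 0)), 0)
  expect_error(js_similarity(c(-1, 0, 0), c(1, 0, 0)), "non-negative")
})

test_that("lesion restriction honors the even-odd rule and the physical buffer", {
  les <- square_lesion(50, 50, 20)  # covers [30, 70]^2 px
  s <- make_set(c(50, 90, 75), c(50, 90, 50), rep("TYPICAL_SRC", 3))
  r0 <- restrict_to_lesions(s, list(les), buffer_um = 0)
  expect_equal(nrow(r0$points), 1L)  # centroid only
  # 5 px = 2.5 um outside; buffer 10 um keeps it
  r1 <- restrict_to_lesions(s, list(les), buffer_um = 10)
  expect_equal(nrow(r1$points), 2L)
  expect_error(restrict_to_lesions(s, list()), "non-empty")
})

test_that("per-lesion metrics decompose and decouple count from distribution", {
  lesA <- square_lesion(40, 40, 25, "A")
  lesB <- square_lesion(150, 150, 25, "B")
  set.seed(4)
  mkpts <- function(cx, cy, n, cls) {
    data.frame(x_px = runif(n, cx - 20, cx + 20),
               y_px = runif(n, cy - 20, cy + 20), class = cls,
               confidence = NA_real_)
  }
  ref <- point_annotation_set(rbind(mkpts(40, 40, 10, "TYPICAL_SRC"),
                                    mkpts(150, 150, 8, "NON_SRC")),
                              lesions = list(lesA, lesB))
  lm <- lesion_metrics(ref, ref)
  expect_equal(lm$f1_overall, c(1, 1))
  expect_equal(lm$count_agreement, c(1, 1))
  expect_equal(lm$js_similarity, c(1, 1))
  # same counts, disjoint classes: perfect count agreement, zero JS similarity
  pred <- point_annotation_set(mkpts(40, 40, 10, "ATYPICAL_SRC"),
                               lesions = list(lesA))
  lmA <- lesion_metrics(pred, ref, lesions = list(lesA))
  expect_equal(lmA$count_agreement, 1.0)
  expect_equal(lmA$js_similarity, 0.0)
  # scoring two lesions jointly equals scoring each alone
  joint <- lesion_metrics(ref, ref, lesions = list(lesA, lesB))
  aloneA <- lesion_metrics(ref, ref, lesions = list(lesA))
  aloneB <- lesion_metrics(ref, ref, lesions = list(lesB))
  expect_equal(joint[joint$lesion_id == "A", -1], aloneA[, -1])
  expect_equal(joint[joint$lesion_id == "B", -1], aloneB[, -1],
               ignore_attr = TRUE)
})

test_that("greedy matching is bounded by the maximum-matching oracle", {
  set.seed(31)
  for (i in 1:300) {
    np <- sample(0:8, 1); nr <- sample(0:8, 1)
    pred <- random_set(np, w = 30, h = 30)
    ref <- random_set(nr, w = 30, h = 30)
    g <- match_points(pred, ref, hit_radius_um = 5, class_aware = TRUE)
    o <- oracle_max_matching(pred, ref, hit_radius_um = 5, class_aware = TRUE)
    ng <- nrow(g$matched_pairs); no <- nrow(o$matched_pairs)
    expect_lte(ng, no)
    expect_gte(ng, ceiling(no / 2))
    expect_lte(ng, min(np, nr))
  }
  expect_error(oracle_max_matching(random_set(101), random_set(101)),
               "too large")
})

test_that("distance-ordered F1 is symmetric and translation/permutation invariant", {
  set.seed(77)
  for (i in 1:20) {
    a <- random_set(sample(3:25, 1))
    b <- random_set(sample(3:25, 1))
    f_ab <- f1_scores(a, b)
    f_ba <- f1_scores(b, a)
    expect_equal(f_ab$f1_overall, f_ba$f1_overall)
    expect_equal(f_ab$f1_any_tumor, f_ba$f1_any_tumor)
    # rigid translation of both sets
    shift <- function(s, dx, dy) make_set(s$points$x_px + dx,
                                          s$points$y_px + dy,
                                          as.character(s$points$class))
    f_sh <- f1_scores(shift(a, 13.7, 8.2), shift(b, 13.7, 8.2))
    expect_equal(f_sh$f1_overall, f_ab$f1_overall)
    # point-order permutation
    perm <- sample(nrow(a$points))
    ap <- make_set(a$points$x_px[perm], a$points$y_px[perm],
                   as.character(a$points$class)[perm])
    expect_equal(f1_scores(ap, b)$f1_overall, f_ab$f1_overall)
  }
})

test_that("greedy equals the oracle when points are separated beyond twice the hit radius", {
  set.seed(55)
  for (i in 1:30) {
    # well-separated reference grid, jittered predictions
    gx <- seq(10, 190, by = 45); gy <- seq(10, 190, by = 45)
    g <- expand.grid(x = gx, y = gy)
    keep <- runif(nrow(g)) < 0.7
    cls <- sample(cell_classes(), sum(keep), TRUE)
    ref <- make_set(g$x[keep], g$y[keep], cls)
    pred <- make_set(g$x[keep] + runif(sum(keep), -6, 6),
                     g$y[keep] + runif(sum(keep), -6, 6), cls)
    gm <- match_points(pred, ref, hit_radius_um = 10)
    om <- oracle_max_matching(pred, ref, hit_radius_um = 10)
    expect_equal(nrow(gm$matched_pairs), nrow(om$matched_pairs))
  }
})
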