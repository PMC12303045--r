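# Shared fixtures and independent oracles for the test suite. The oracles
# deliberately use different formulations than the package implementation.

# Quick point set construction from vectors.
make_set <- function(x, y, class, confidence = NA_real_, spacing = 0.5,
                     image_id = "img", source_id = "src", lesions = list(),
                     tissue = list(), bounds = NULL) {
  pts <- if (length(x)) data.frame(x_px = x, y_px = y, class = class,
                                   confidence = confidence) else NULL
  point_annotation_set(pts, lesions = lesions, tissue = tissue,
                       image_id = image_id, source_id = source_id,
                       spacing_um_per_px = spacing, bounds = bounds)
}

square_lesion <- function(cx, cy, half, id = "L1") {
  region_polygon(c(cx - half, cx + half, cx + half, cx - half),
                 c(cy - half, cy - half, cy + half, cy + half),
                 region_id = id, kind = "LESION")
}

square_tissue <- function(w, h, margin = 2) {
  region_polygon(c(margin, w - 1 - margin, w - 1 - margin, margin),
                 c(margin, margin, h - 1 - margin, h - 1 - margin),
                 region_id = "tissue", kind = "TISSUE")
}

# Random point set inside a box, optionally with confidences.
random_set <- function(n, w = 100, h = 100, with_conf = FALSE, spacing = 0.5,
                       source_id = "src") {
  make_set(runif(n, 0, w - 1), runif(n, 0, h - 1),
           sample(cell_classes(), n, replace = TRUE),
           confidence = if (with_conf) runif(n) else NA_real_,
           spacing = spacing, source_id = source_id)
}

# --- Jensen-Shannon divergence oracle: entropy form, base-2 ---------------
oracle_js_similarity <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(1)
  if (sa == 0 || sb == 0) return(0)
  a <- a / sa; b <- b / sb
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  m <- (a + b) / 2
  1 - (H(m) - (H(a) + H(b)) / 2)
}

# --- Wilcoxon rank-sum oracle: exhaustive enumeration of assignments ------
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  all_r <- rank(pooled)
  us <- apply(combos, 2, function(idx) sum(all_r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  if (u_obs > mu) min(1, 2 * mean(us >= u_obs))
  else min(1, 2 * mean(us <= u_obs))
}

# --- Wilcoxon signed-rank oracle: exhaustive sign enumeration -------------
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  if (v_obs > mu) min(1, 2 * mean(vs >= v_obs))
  else min(1, 2 * mean(vs <= v_obs))
}

# --- connected components oracle: BFS flood fill, 8-connectivity ----------
oracle_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- pr + dr; cc <- pc + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# Default-geometry slide fixture small enough for fast unit tests.
small_slide <- function(seed, extent = 700, n_lesions = 1L, cells = 30L) {
  generate_slide(slide_sim_params(extent_px = c(extent, extent),
                                  n_lesions = n_lesions,
                                  cells_per_lesion = cells,
                                  lesion_radius_px = 0.28 * extent,
                                  seed = seed))
}
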