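# Independent oracles and fixture builders used across the suite. These
# deliberately use different algorithms from the package internals.

# Rectangle landmark set: height h, width w, mid points at mid-width.
rect_landmarks <- function(h = 25, w = 35, level = "L1") {
  vertebra_landmarks(
    anterior_superior = c(w, 0), anterior_inferior = c(w, h),
    posterior_superior = c(0, 0), posterior_inferior = c(0, h),
    middle_superior = c(w / 2, 0), middle_inferior = c(w / 2, h),
    level = level)
}

# Landmarks with prescribed heights (trapezoid, horizontal superior plate).
heights_landmarks <- function(h_a, h_p, h_m, w, level = "L1") {
  mid_c <- (0 + 0 + h_p + h_a) / 4
  vertebra_landmarks(
    anterior_superior = c(w, 0), anterior_inferior = c(w, h_a),
    posterior_superior = c(0, 0), posterior_inferior = c(0, h_p),
    middle_superior = c(w / 2, mid_c - h_m / 2),
    middle_inferior = c(w / 2, mid_c + h_m / 2),
    level = level)
}

# Coordinate-level morphometry oracle: plain arithmetic on the six points,
# no shared code with compute_morphometry.
oracle_morphometry <- function(l) {
  d <- function(p, q) sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)
  h_a <- d(l$anterior_superior, l$anterior_inferior)
  h_p <- d(l$posterior_superior, l$posterior_inferior)
  h_m <- d(l$middle_superior, l$middle_inferior)
  w <- (d(l$anterior_superior, l$posterior_superior) +
          d(l$anterior_inferior, l$posterior_inferior)) / 2
  hi <- if (h_a > h_p) h_a else h_p
  lo <- if (h_a < h_p) h_a else h_p
  list(h_a = h_a, h_p = h_p, h_m = h_m, w = w,
       r1 = lo / hi, r2 = h_m / hi, r3 = hi / w,
       c1 = lo / hi < 0.8, c2 = h_m / hi < 0.6, c3 = hi / w < 0.55)
}

# Random (possibly irregular but simple) landmark hexagon, in mm.
random_landmarks <- function() {
  w <- runif(1, 20, 45)
  h_a <- runif(1, 8, 35)
  h_p <- runif(1, 8, 35)
  hi <- max(h_a, h_p)
  h_m <- runif(1, 0.35 * hi, 1.05 * hi)
  jitter <- function(p) p + runif(2, -0.5, 0.5)
  mid_c <- (h_a + h_p) / 4
  vertebra_landmarks(
    anterior_superior = jitter(c(w, 0)), anterior_inferior = jitter(c(w, h_a)),
    posterior_superior = jitter(c(0, 0)), posterior_inferior = jitter(c(0, h_p)),
    middle_superior = c(w / 2, mid_c - h_m / 2),
    middle_inferior = c(w / 2, mid_c + h_m / 2))
}

apply_similarity <- function(l, theta, s, tx, ty) {
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  tf <- function(p) as.numeric(s * R %*% p + c(tx, ty))
  vertebra_landmarks(
    anterior_superior = tf(l$anterior_superior),
    anterior_inferior = tf(l$anterior_inferior),
    posterior_superior = tf(l$posterior_superior),
    posterior_inferior = tf(l$posterior_inferior),
    middle_superior = tf(l$middle_superior),
    middle_inferior = tf(l$middle_inferior),
    level = l$level, pixel_spacing = l$pixel_spacing)
}

# Winding-number point-in-polygon oracle (angle summation), boundary treated
# as inside via a tolerance on the winding sum. Different algorithm from the
# package's ray casting.
oracle_inside <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(k) {
    dx <- poly[, 1] - px[k]; dy <- poly[, 2] - py[k]
    if (any(dx == 0 & dy == 0)) return(TRUE) # on a vertex
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    total <- sum(d)
    abs(total) > pi # winding number != 0
  }, logical(1))
}

# Brute-force maximum over all map cells whose centres fall in the polygon.
oracle_roi_max <- function(grid, poly) {
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    for (cc in seq_len(ncol(grid))) {
      if (oracle_inside(cc, r, poly)) best <- max(best, grid[r, cc])
    }
  }
  best
}

# O(n^2) concordance AUROC oracle.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Step-sum average-precision oracle via explicit per-threshold counting.
oracle_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels)
  prev_r <- 0; ap <- 0
  for (t in th) {
    called <- scores >= t
    tp <- sum(labels[called])
    r <- tp / n1
    p <- tp / sum(called)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# Exhaustive threshold-scan oracle for the PPV/NPV search.
oracle_threshold <- function(values, labels, target, type) {
  cand <- c(-Inf, sort(unique(values)), Inf)
  best <- NULL
  for (t in cand) {
    if (type == "ppv") {
      called <- values < t
      if (!any(called)) next
      v <- sum(labels[called]) / sum(called)
      if (v >= target && (is.null(best) || t > best$t))
        best <- list(t = t, val = v, n = sum(called))
    } else {
      called <- values >= t
      if (!any(called)) next
      v <- sum(!labels[called]) / sum(called)
      if (v >= target && (is.null(best) || t < best$t))
        best <- list(t = t, val = v, n = sum(called))
    }
  }
  best
}
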