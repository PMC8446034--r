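#' Six-point vertebral landmarks
#'
#' A vertebra is described by six landmarks on its body outline: the two
#' anterior corners, the two posterior corners, and the two mid-plate points
#' of the superior and inferior endplates. Coordinates are in millimetres,
#' x rightward and y downward (image convention); pixel coordinates are
#' converted by multiplying by `pixel_spacing` before construction (0-based
#' indices at pixel centres).
#'
#' @param anterior_superior,anterior_inferior,posterior_superior,posterior_inferior,middle_superior,middle_inferior
#'   numeric length-2 `(x, y)` points in mm.
#' @param level vertebral level, one of `"L1"`–`"L4"`.
#' @param pixel_spacing source pixel spacing in mm/pixel (metadata; must be > 0).
#' @return an object of class `vertebra_landmarks`.
#' @seealso [compute_morphometry()]
#' @export
vertebra_landmarks <- function(anterior_superior, anterior_inferior,
                               posterior_superior, posterior_inferior,
                               middle_superior, middle_inferior,
                               level = "L1", pixel_spacing = 0.15) {
  pts <- list(
    anterior_superior = anterior_superior,
    anterior_inferior = anterior_inferior,
    posterior_superior = posterior_superior,
    posterior_inferior = posterior_inferior,
    middle_superior = middle_superior,
    middle_inferior = middle_inferior
  )
  for (nm in names(pts)) assert_point(pts[[nm]], nm)
  level <- match.arg(level, c("L1", "L2", "L3", "L4"))
  assert_scalar_number(pixel_spacing, "pixel_spacing", lower = 0, strict_lower = TRUE)
  for (pair in list(c("anterior_superior", "anterior_inferior"),
                    c("posterior_superior", "posterior_inferior"),
                    c("middle_superior", "middle_inferior"))) {
    if (euclid(pts[[pair[1]]], pts[[pair[2]]]) == 0)
      stop_validation("coincident landmark pair: ", pair[1], " / ", pair[2])
  }
  structure(c(pts, list(level = level, pixel_spacing = pixel_spacing)),
            class = "vertebra_landmarks")
}

# TRUE when segments p1-p2 and p3-p4 properly intersect (shared endpoints do
# not count). Used to reject self-intersecting landmark hexagons.
segments_cross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  d1 <- orient(p3, p4, p1); d2 <- orient(p3, p4, p2)
  d3 <- orient(p1, p2, p3); d4 <- orient(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Compute six-point vertebral morphometry
#'
#' Derives the three vertebral heights and the width from six landmarks, the
#' three Genant-modified deformity ratios, and the corresponding criterion
#' flags. The heights are the pairwise distances within the anterior,
#' posterior, and middle landmark pairs; the width is the mean of the
#' superior-edge (anterior-superior to posterior-superior) and inferior-edge
#' distances.
#'
#' The three criteria fire on strict inequalities:
#' \describe{
#'   \item{c1 (wedge/crush)}{`min(h_a, h_p) / max(h_a, h_p) < 0.8`}
#'   \item{c2 (biconcave)}{`h_m / max(h_a, h_p) < 0.6`}
#'   \item{c3 (severe collapse)}{`max(h_a, h_p) / w < 0.55`}
#' }
#' A ratio exactly equal to its threshold does not fire. A vertebra is
#' `abnormal` when any criterion fires. The criteria target moderate-to-severe
#' compression deformity; mild (grade 1) deformities are deliberately not
#' graded.
#'
#' @param landmarks a [vertebra_landmarks()] object.
#' @return an object of class `vertebral_morphometry`: list with `h_a`, `h_p`,
#'   `h_m`, `w` (mm), ratios `r1`, `r2`, `r3`, flags `c1`, `c2`, `c3`,
#'   `abnormal`, and `level`.
#' @export
compute_morphometry <- function(landmarks) {
  if (!inherits(landmarks, "vertebra_landmarks"))
    stop_validation("landmarks must be a vertebra_landmarks object")
  l <- landmarks
  # reject self-intersecting outlines (superior edge crossing inferior edge,
  # or anterior/posterior sides crossing each other)
  hex <- list(l$anterior_superior, l$middle_superior, l$posterior_superior,
              l$posterior_inferior, l$middle_inferior, l$anterior_inferior)
  n <- length(hex)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (segments_cross(hex[[i]], hex[[i %% n + 1]], hex[[j]], hex[[j %% n + 1]]))
        stop_validation("degenerate geometry: landmark hexagon is self-intersecting")
    }
  }
  h_a <- euclid(l$anterior_superior, l$anterior_inferior)
  h_p <- euclid(l$posterior_superior, l$posterior_inferior)
  h_m <- euclid(l$middle_superior, l$middle_inferior)
  w <- mean(c(euclid(l$anterior_superior, l$posterior_superior),
              euclid(l$anterior_inferior, l$posterior_inferior)))
  if (min(h_a, h_p, h_m, w) <= 0)
    stop_validation("degenerate geometry: zero height or width")
  r1 <- min(h_a, h_p) / max(h_a, h_p)
  r2 <- h_m / max(h_a, h_p)
  r3 <- max(h_a, h_p) / w
  c1 <- r1 < 0.8
  c2 <- r2 < 0.6
  c3 <- r3 < 0.55
  structure(list(h_a = h_a, h_p = h_p, h_m = h_m, w = w,
                 r1 = r1, r2 = r2, r3 = r3,
                 c1 = c1, c2 = c2, c3 = c3,
                 abnormal = c1 || c2 || c3,
                 level = l$level),
            class = "vertebral_morphometry")
}

#' Classify the deformity pattern of a measured vertebra
#'
#' Maps the three criterion flags to a deformity label. When several criteria
#' fire simultaneously, severity wins: the severe-collapse criterion (c3)
#' takes precedence over wedge/crush (c1), which takes precedence over
#' biconcave (c2). `normal` iff no criterion fires.
#'
#' @param m a `vertebral_morphometry` object.
#' @return a character scalar: `"normal"`, `"wedge_or_crush"`, `"biconcave"`,
#'   or `"severe"`.
#' @export
classify_deformity <- function(m) {
  if (!inherits(m, "vertebral_morphometry"))
    stop_validation("m must be a vertebral_morphometry object")
  if (m$c3) "severe"
  else if (m$c1) "wedge_or_crush"
  else if (m$c2) "biconcave"
  else "normal"
}

#' @export
print.vertebral_morphometry <- function(x, ...) {
  cat(sprintf("Vertebral morphometry (%s)\n", x$level))
  cat(sprintf("  heights (mm): anterior %.2f, posterior %.2f, middle %.2f; width %.2f\n",
              x$h_a, x$h_p, x$h_m, x$w))
  cat(sprintf("  ratios: r1 = %.3f (c1 %s), r2 = %.3f (c2 %s), r3 = %.3f (c3 %s)\n",
              x$r1, if (x$c1) "FIRES" else "ok",
              x$r2, if (x$c2) "FIRES" else "ok",
              x$r3, if (x$c3) "FIRES" else "ok"))
  cat(sprintf("  %s\n", if (x$abnormal)
    paste0("ABNORMAL: ", classify_deformity(x)) else "normal"))
  invisible(x)
}

#' Tabulate morphometry for several vertebrae
#'
#' @param morphs list of `vertebral_morphometry` objects.
#' @return data.frame with one row per vertebra (levels, measures, ratios,
#'   flags, label); suitable for writing as CSV.
#' @export
morphometry_table <- function(morphs) {
  stopifnot(length(morphs) >= 1)
  do.call(rbind, lapply(morphs, function(m) {
    data.frame(level = m$level, h_a = m$h_a, h_p = m$h_p, h_m = m$h_m, w = m$w,
               r1 = m$r1, r2 = m$r2, r3 = m$r3,
               c1 = m$c1, c2 = m$c2, c3 = m$c3,
               abnormal = m$abnormal, label = classify_deformity(m),
               stringsAsFactors = FALSE)
  }))
}
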