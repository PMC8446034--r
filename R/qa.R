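#' Detection probability map
#'
#' A probability grid aligned to a source image, as produced by a pluggable
#' fracture/implant/VCF detector. Grid cell `(row, col)` has its centre at
#' `x = col`, `y = row` (1-based, matching the image pixels).
#'
#' @param grid numeric matrix with values in `[0, 1]`.
#' @param channel `"fracture"`, `"implant"`, or `"vcf"`.
#' @return object of class `detection_map`.
#' @export
detection_map <- function(grid, channel = c("fracture", "implant", "vcf")) {
  channel <- match.arg(channel)
  if (!is.matrix(grid) || !is.numeric(grid) ||
      any(grid < 0 | grid > 1 | !is.finite(grid)))
    stop_validation("grid must be a numeric matrix with values in [0, 1]")
  structure(list(grid = grid, channel = channel), class = "detection_map")
}

# Ray-casting point-in-polygon with boundary-inclusive convention: points on
# an edge or vertex count as inside. `px`/`py` are vectors; polygon is an
# n x 2 matrix of (x, y) vertices.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # boundary test: point on segment (i, j)
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    within <- px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    # even-odd crossing test
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Aggregate a detection map over an ROI polygon
#'
#' The classification score of an ROI is the maximum detector response over
#' the grid cells whose centres fall inside the polygon; cells whose centres
#' lie exactly on the boundary are included.
#'
#' @param map a [detection_map()].
#' @param roi_polygon n x 2 matrix of polygon vertices (x = column,
#'   y = row, same coordinates as the map grid), n >= 3, nonzero area.
#' @return scalar score in `[0, 1]`.
#' @export
aggregate_roi_score <- function(map, roi_polygon) {
  stopifnot(inherits(map, "detection_map"))
  roi_polygon <- as.matrix(roi_polygon)
  if (nrow(roi_polygon) < 3) stop_validation("polygon needs >= 3 vertices")
  if (polygon_area(roi_polygon) == 0) stop_validation("polygon has zero area")
  g <- map$grid
  rr <- max(1L, floor(min(roi_polygon[, 2]))):min(nrow(g), ceiling(max(roi_polygon[, 2])))
  cc <- max(1L, floor(min(roi_polygon[, 1]))):min(ncol(g), ceiling(max(roi_polygon[, 1])))
  if (min(roi_polygon[, 2]) > nrow(g) || max(roi_polygon[, 2]) < 1 ||
      min(roi_polygon[, 1]) > ncol(g) || max(roi_polygon[, 1]) < 1)
    stop_validation("polygon lies fully outside the map")
  px <- rep(cc, each = length(rr))
  py <- rep(rr, times = length(cc))
  keep <- points_in_polygon(px, py, roi_polygon)
  if (!any(keep)) stop_validation("polygon contains no grid-cell centres")
  max(g[cbind(py[keep], px[keep])])
}

#' Per-ROI quality-assessment result
#'
#' @param roi_id identifier.
#' @param reasons character vector of exclusion reasons (subset of
#'   `"fracture"`, `"implant"`, `"vcf_detected"`, `"morphometric_deformity"`,
#'   `"neighbor_deviation"`, `"too_few_vertebrae"`); empty means admissible.
#' @param scores named numeric vector of aggregated detector scores.
#' @return object of class `qa_result`; `admissible` is TRUE iff `reasons`
#'   is empty.
#' @export
qa_result <- function(roi_id, reasons = character(), scores = numeric()) {
  allowed <- c("fracture", "implant", "vcf_detected", "morphometric_deformity",
               "neighbor_deviation", "too_few_vertebrae")
  if (!all(reasons %in% allowed))
    stop_validation("unknown QA reason: ", setdiff(reasons, allowed)[1])
  structure(list(roi_id = roi_id, admissible = length(reasons) == 0,
                 reasons = unique(reasons), scores = scores),
            class = "qa_result")
}

#' @export
print.qa_result <- function(x, ...) {
  cat(sprintf("QA %s: %s%s\n", x$roi_id,
              if (x$admissible) "admissible" else "EXCLUDED",
              if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Hip radiograph quality assessment
#'
#' Aggregates the fracture- and implant-detector maps over the hip ROI and
#' excludes the ROI when either score reaches its threshold (inclusive `>=`).
#'
#' @param image numeric matrix (the radiograph or ROI pixels) passed to the
#'   detectors.
#' @param roi_polygon hip ROI polygon (n x 2, map coordinates).
#' @param detectors named list of detector functions; each maps `image` to a
#'   [detection_map()]. Channels `"fracture"` and `"implant"` are required.
#' @param thresholds named numeric, score thresholds per channel
#'   (default 0.5 each).
#' @param roi_id identifier for the result.
#' @return a [qa_result()].
#' @export
hip_qa <- function(image, roi_polygon, detectors,
                   thresholds = c(fracture = 0.5, implant = 0.5),
                   roi_id = "hip") {
  for (ch in c("fracture", "implant"))
    if (is.null(detectors[[ch]]))
      stop_validation("missing detector channel: ", ch)
  scores <- vapply(c("fracture", "implant"), function(ch) {
    m <- detectors[[ch]](image)
    if (!inherits(m, "detection_map"))
      stop_validation("detector ", ch, " must return a detection_map")
    aggregate_roi_score(m, roi_polygon)
  }, numeric(1))
  reasons <- character()
  if (scores[["fracture"]] >= thresholds[["fracture"]]) reasons <- c(reasons, "fracture")
  if (scores[["implant"]] >= thresholds[["implant"]]) reasons <- c(reasons, "implant")
  qa_result(roi_id, reasons, scores)
}

#' Neighbour-deviation vertebral exclusion
#'
#' Implements the adjacent-vertebra consistency rule: a vertebra whose
#' T-score differs from its peers by more than `delta` (default 1.0 T-score
#' units, strict `>`) is excluded. The decision is made in a single pass on
#' the pre-exclusion values; exclusions never cascade.
#'
#' Two reference definitions are available. `"loo"` (default) compares each
#' vertebra with the mean of all *other* assessable vertebrae, which isolates
#' the deviant vertebra itself rather than also discarding its innocent
#' neighbours; `"adjacent"` compares with the mean of the chain-adjacent
#' assessable vertebrae only.
#'
#' @param values named numeric vector of per-vertebra T-scores in L1-L4 chain
#'   order (>= 2 values).
#' @param delta exclusion margin in T-score units (strict `>`).
#' @param method `"loo"` or `"adjacent"`.
#' @return character vector of excluded vertebra names (possibly empty).
#' @export
neighbor_exclusion <- function(values, delta = 1.0, method = c("loo", "adjacent")) {
  method <- match.arg(method)
  if (length(values) < 2) stop_validation("need >= 2 vertebrae with values")
  if (is.null(names(values))) names(values) <- paste0("V", seq_along(values))
  n <- length(values)
  dev <- vapply(seq_len(n), function(i) {
    ref <- if (method == "loo") mean(values[-i])
    else mean(values[setdiff(c(i - 1, i + 1), c(0, n + 1))])
    abs(values[i] - ref)
  }, numeric(1))
  names(values)[dev > delta]
}

#' Three-step spine radiograph quality assessment
#'
#' Applies the spine admissibility procedure to a contiguous set of L1-L4
#' vertebrae: (1) vertebrae with a positive implant or VCF detection are
#' excluded; (2) survivors are measured by six-point morphometry and excluded
#' if any deformity criterion fires; (3) survivors' predicted T-scores go
#' through [neighbor_exclusion()]. If fewer than two vertebrae remain, the
#' whole scan is inadmissible and the surviving vertebrae are additionally
#' flagged `too_few_vertebrae`. Decisions are per-vertebra and independent of
#' input order; a vertebra excluded at one step never contributes to later
#' steps.
#'
#' @param vertebrae named list (names `"L1"`–`"L4"`), each element a list with
#'   `landmarks` (a [vertebra_landmarks()]) and either `scores` (named numeric
#'   with `implant`, `vcf`) or `maps` (named list of [detection_map()]s) plus
#'   `polygon` for aggregation.
#' @param t_scores named numeric vector of predicted per-vertebra T-scores
#'   (names matching `vertebrae`).
#' @param threshold detector positivity threshold (inclusive `>=`,
#'   default 0.5).
#' @param delta neighbour-deviation margin (see [neighbor_exclusion()]).
#' @param method neighbour reference definition (see [neighbor_exclusion()]).
#' @return list of [qa_result()]s, one per vertebra in L1-L4 order, with
#'   attribute `scan_admissible`.
#' @export
spine_qa <- function(vertebrae, t_scores, threshold = 0.5, delta = 1.0,
                     method = c("loo", "adjacent")) {
  if (length(vertebrae) == 0) stop_validation("empty vertebra set")
  lv <- names(vertebrae)
  if (is.null(lv) || !all(lv %in% c("L1", "L2", "L3", "L4")))
    stop_validation("vertebrae must be named L1-L4")
  ord <- order(match(lv, c("L1", "L2", "L3", "L4")))
  vertebrae <- vertebrae[ord]
  lv <- names(vertebrae)
  reasons <- stats::setNames(vector("list", length(lv)), lv)
  scores <- stats::setNames(vector("list", length(lv)), lv)
  # step 1: implant / VCF detection
  for (v in lv) {
    entry <- vertebrae[[v]]
    sc <- if (!is.null(entry$scores)) entry$scores
    else vapply(c("implant", "vcf"), function(ch) {
      aggregate_roi_score(entry$maps[[ch]], entry$polygon)
    }, numeric(1))
    scores[[v]] <- sc
    if (sc[["implant"]] >= threshold) reasons[[v]] <- c(reasons[[v]], "implant")
    if (sc[["vcf"]] >= threshold) reasons[[v]] <- c(reasons[[v]], "vcf_detected")
  }
  survivors <- lv[vapply(reasons, length, integer(1)) == 0]
  # step 2: six-point morphometry on survivors only
  for (v in survivors) {
    m <- compute_morphometry(vertebrae[[v]]$landmarks)
    if (m$abnormal) reasons[[v]] <- c(reasons[[v]], "morphometric_deformity")
  }
  survivors <- lv[vapply(reasons, length, integer(1)) == 0]
  # step 3: neighbour deviation on surviving T-scores
  if (length(survivors) >= 2) {
    excl <- neighbor_exclusion(t_scores[survivors], delta = delta,
                               method = method)
    for (v in excl) reasons[[v]] <- c(reasons[[v]], "neighbor_deviation")
  }
  survivors <- lv[vapply(reasons, length, integer(1)) == 0]
  scan_ok <- length(survivors) >= 2
  if (!scan_ok)
    for (v in survivors) reasons[[v]] <- c(reasons[[v]], "too_few_vertebrae")
  out <- lapply(lv, function(v) qa_result(v, reasons[[v]], scores[[v]]))
  names(out) <- lv
  attr(out, "scan_admissible") <- scan_ok
  out
}

#' Synthetic ground-truth detector
#'
#' A detector plug-in for testing: instead of a trained network it reads the
#' phantom's ground-truth labels and returns a flat probability map —
#' `hit` (default 0.9) when the requested channel is among the phantom's
#' `flags`, `miss` (default 0.02) otherwise.
#'
#' @param flags character vector of truth labels attached to the phantom
#'   (e.g. `c("implant")`).
#' @param channel which channel this detector reports.
#' @param hit,miss flat map values for flagged / clean phantoms.
#' @return a detector function: `image -> detection_map`.
#' @export
synthetic_detector <- function(flags, channel, hit = 0.9, miss = 0.02) {
  force(flags); force(channel); force(hit); force(miss)
  function(image) {
    val <- if (channel %in% flags) hit else miss
    detection_map(matrix(val, nrow(image), ncol(image)), channel = channel)
  }
}

#' Tabulate QA results
#'
#' @param results list of [qa_result()] objects.
#' @return data.frame, one row per ROI: id, admissibility, reasons
#'   (semicolon-separated), scores; suitable for CSV export.
#' @export
qa_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(roi_id = r$roi_id, admissible = r$admissible,
               reasons = paste(r$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
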