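#' Radiograph region-of-interest image
#'
#' Container for a single-channel ROI extracted around a hip or a lumbar
#' vertebra. Pixels are stored as a numeric matrix on the 16-bit scale
#' (source bit depth is recorded by the caller if needed); `pixel_spacing`
#' is in mm/pixel.
#'
#' @param pixels numeric matrix of intensities in `[0, 65535]`.
#' @param pixel_spacing mm per pixel, > 0.
#' @param site `"hip_left"`, `"hip_right"` or `"vertebra"`.
#' @param level vertebral level (`"L1"`–`"L4"`); required iff
#'   `site = "vertebra"`.
#' @return an object of class `roi_image`.
#' @export
roi_image <- function(pixels, pixel_spacing, site = "vertebra", level = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) == 0))
    stop_validation("pixels must be a nonempty numeric matrix")
  assert_scalar_number(pixel_spacing, "pixel_spacing", lower = 0, strict_lower = TRUE)
  site <- match.arg(site, c("hip_left", "hip_right", "vertebra"))
  if (identical(site, "vertebra")) {
    if (is.null(level)) stop_validation("vertebra ROIs need a level (L1-L4)")
    level <- match.arg(level, c("L1", "L2", "L3", "L4"))
  } else if (!is.null(level)) {
    stop_validation("level is only meaningful for vertebra ROIs")
  }
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 site = site, level = level),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("ROI image: %dx%d px @ %.3f mm/px, site %s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing, x$site,
              if (!is.null(x$level)) paste0(" (", x$level, ")") else ""))
  invisible(x)
}

# Bilinear warp engine. Output pixel centres are 0-based (row r, col c);
# each maps through the affine `M` (2x3, acting on (x, y, 1) with x = col,
# y = row) to input coordinates, where the value is sampled bilinearly.
# Samples outside the input grid return `fill` (augmentation) or replicate
# the border when `edge = "clamp"` (resampling). Identity `M` with equal
# dims is an exact pass-through.
warp_bilinear <- function(mat, M, out_dim, fill = 0, edge = c("fill", "clamp")) {
  edge <- match.arg(edge)
  nr <- out_dim[1]; nc <- out_dim[2]
  cc <- rep(seq_len(nc) - 1, each = nr)
  rr <- rep(seq_len(nr) - 1, times = nc)
  xs <- M[1, 1] * cc + M[1, 2] * rr + M[1, 3]
  ys <- M[2, 1] * cc + M[2, 2] * rr + M[2, 3]
  if (edge == "clamp") {
    xs <- pmin(pmax(xs, 0), ncol(mat) - 1)
    ys <- pmin(pmax(ys, 0), nrow(mat) - 1)
  }
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  inr <- nrow(mat); inc <- ncol(mat)
  get <- function(r0, c0) {
    ok <- r0 >= 0 & r0 <= inr - 1 & c0 >= 0 & c0 <= inc - 1
    v <- rep(fill, length(r0))
    v[ok] <- mat[cbind(r0[ok] + 1, c0[ok] + 1)]
    v
  }
  v <- (1 - fx) * (1 - fy) * get(y0, x0) +
    fx * (1 - fy) * get(y0, x0 + 1) +
    (1 - fx) * fy * get(y0 + 1, x0) +
    fx * fy * get(y0 + 1, x0 + 1)
  matrix(v, nr, nc)
}

#' Preprocess an ROI into the model input grid
#'
#' Applies the fixed preprocessing contract: resample to 0.15 mm/pixel
#' (bilinear), min-max normalise intensities to `[0, 1]` (a constant image
#' maps to 0.5 everywhere), and letterbox into a `size x size` grid,
#' preserving the physical aspect ratio and padding symmetrically with zeros.
#' Deterministic, and idempotent: preprocessing a preprocessed grid returns
#' it unchanged.
#'
#' @param roi an [roi_image()] or a `model_input` from a previous call.
#' @param size output side length in pixels (default 512).
#' @param target_spacing output spacing in mm/pixel (default 0.15).
#' @return a `model_input` object: normalised `size x size` matrix in
#'   `pixels`, plus spacing and the ROI's site/level.
#' @export
preprocess_roi <- function(roi, size = 512, target_spacing = 0.15) {
  if (inherits(roi, "model_input")) {
    # an already-preprocessed grid at the requested geometry passes through
    # unchanged (idempotence)
    if (all(dim(roi$pixels) == c(size, size)) &&
        isTRUE(all.equal(roi$pixel_spacing, target_spacing)))
      return(roi)
    roi <- roi_image(roi$pixels * 65535, roi$pixel_spacing, roi$site, roi$level)
  }
  stopifnot(inherits(roi, "roi_image"))
  px <- roi$pixels
  if (any(dim(px) == 0)) stop_validation("zero-extent image")
  # 1. resample to target spacing (physical extent preserved)
  scale <- roi$pixel_spacing / target_spacing
  out_dim <- pmax(1L, as.integer(round(dim(px) * scale)))
  if (!all(out_dim == dim(px)) || scale != 1) {
    sr <- dim(px)[1] / out_dim[1]; sc <- dim(px)[2] / out_dim[2]
    # map output centre k to input coordinate sr*(k + .5) - .5
    M <- matrix(c(sc, 0, sc * 0.5 - 0.5,
                  0, sr, sr * 0.5 - 0.5), 2, 3, byrow = TRUE)
    px <- warp_bilinear(px, M, out_dim, edge = "clamp")
  }
  # 2. intensity normalisation
  rng <- range(px)
  px <- if (rng[1] == rng[2]) matrix(0.5, nrow(px), ncol(px))
  else (px - rng[1]) / (rng[2] - rng[1])
  # 3. letterbox into size x size
  if (!all(dim(px) == c(size, size))) {
    fit <- size / max(dim(px))
    inner <- pmax(1L, as.integer(round(dim(px) * fit)))
    if (!all(inner == dim(px))) {
      sr <- dim(px)[1] / inner[1]; sc <- dim(px)[2] / inner[2]
      M <- matrix(c(sc, 0, sc * 0.5 - 0.5,
                    0, sr, sr * 0.5 - 0.5), 2, 3, byrow = TRUE)
      px <- warp_bilinear(px, M, inner, edge = "clamp")
    }
    out <- matrix(0, size, size)
    r0 <- floor((size - nrow(px)) / 2); c0 <- floor((size - ncol(px)) / 2)
    out[r0 + seq_len(nrow(px)), c0 + seq_len(ncol(px))] <- px
    px <- out
  }
  structure(list(pixels = px, pixel_spacing = target_spacing,
                 site = roi$site, level = roi$level),
            class = "model_input")
}

#' Random affine augmentation of a model input grid
#'
#' Samples an affine transform (rotation, isotropic scale, translation,
#' shear) uniformly within the configured ranges and applies it about the
#' grid centre with bilinear interpolation, zero fill outside. With all
#' ranges zero the transform is the exact identity; a fixed seed reproduces
#' the transform bit-for-bit. Training-time only.
#'
#' @param grid a `model_input` (or plain matrix).
#' @param ranges list with `rotate` (degrees), `scale`, `translate` (fraction
#'   of side), `shear` (radians); each the half-width of a symmetric uniform
#'   range. Defaults: 10 degrees, 5\% scale and translation, no shear.
#' @param seed integer seed for the transform draw.
#' @param transform optional explicit 2x3 inverse-mapping matrix (output
#'   pixel coordinates `(x, y, 1)` to input coordinates); when supplied, no
#'   random draw happens and the matrix is applied directly.
#' @return object of the same shape as `grid` with warped pixels; the applied
#'   2x3 matrix is attached as attribute `"transform"`.
#' @export
augment_roi <- function(grid, ranges = augment_ranges(), seed = 1L,
                        transform = NULL) {
  px <- if (inherits(grid, "model_input")) grid$pixels else grid
  stopifnot(is.matrix(px))
  if (!is.null(transform)) {
    stopifnot(is.matrix(transform), all(dim(transform) == c(2, 3)))
    out <- warp_bilinear(px, transform, dim(px))
    res <- if (inherits(grid, "model_input")) { grid$pixels <- out; grid } else out
    attr(res, "transform") <- transform
    return(res)
  }
  par <- with_seed(seed, c(
    rot = stats::runif(1, -ranges$rotate, ranges$rotate) * pi / 180,
    sc = 1 + stats::runif(1, -ranges$scale, ranges$scale),
    tx = stats::runif(1, -ranges$translate, ranges$translate) * ncol(px),
    ty = stats::runif(1, -ranges$translate, ranges$translate) * nrow(px),
    sh = stats::runif(1, -ranges$shear, ranges$shear)
  ))
  cx <- (ncol(px) - 1) / 2; cy <- (nrow(px) - 1) / 2
  # inverse mapping (output -> input): rotate/scale/shear about centre, then
  # shift; composed as A %*% (p - c - t) + c
  A <- matrix(c(cos(par["rot"]), -sin(par["rot"]),
                sin(par["rot"]), cos(par["rot"])), 2, 2, byrow = TRUE)
  A <- A %*% matrix(c(1, par["sh"], 0, 1), 2, 2, byrow = TRUE) / par["sc"]
  M <- cbind(A, c(cx, cy) - A %*% c(cx + par["tx"], cy + par["ty"]))
  out <- warp_bilinear(px, M, dim(px))
  res <- if (inherits(grid, "model_input")) {
    grid$pixels <- out; grid
  } else out
  attr(res, "transform") <- M
  res
}

#' @rdname augment_roi
#' @param rotate,scale,translate,shear range half-widths (see `ranges`).
#' @export
augment_ranges <- function(rotate = 10, scale = 0.05, translate = 0.05,
                           shear = 0) {
  list(rotate = rotate, scale = scale, translate = translate, shear = shear)
}

#' Reference backbone: intensity-summary encoder
#'
#' Encodes a preprocessed grid as a fixed-length feature vector: mean,
#' standard deviation, five quantiles, and the mean over the central half of
#' the grid (where the bone ROI sits after letterboxing). Any function with
#' this signature can stand in as the backbone of the regressor.
#'
#' @param grid a `model_input` or matrix with values in `[0, 1]`.
#' @return named numeric feature vector.
#' @export
intensity_backbone <- function(grid) {
  px <- if (inherits(grid, "model_input")) grid$pixels else grid
  n <- dim(px)
  cr <- seq.int(floor(n[1] / 4) + 1, ceiling(3 * n[1] / 4))
  cc <- seq.int(floor(n[2] / 4) + 1, ceiling(3 * n[2] / 4))
  q <- stats::quantile(px, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  c(mean = mean(px), sd = stats::sd(px),
    q10 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q90 = q[5],
    centre = mean(px[cr, cc]))
}

#' Training configuration for the reference BMD regressor
#'
#' @param epochs number of optimisation epochs (majorize-minimize updates of
#'   the smoothed-L1 objective).
#' @param l1_eps smoothing half-width of the L1 loss (g/cm^2).
#' @param n_augment augmented copies added per training image.
#' @param ranges augmentation ranges, see [augment_ranges()].
#' @param input_size preprocessed grid side length.
#' @param seed seed controlling fold assignment and augmentation draws.
#' @param backbone feature-extractor function (`model_input` -> numeric).
#' @return a config list of class `bmd_config`.
#' @export
bmd_config <- function(epochs = 30, l1_eps = 1e-3, n_augment = 1,
                       ranges = augment_ranges(), input_size = 512,
                       seed = 1L, backbone = intensity_backbone) {
  structure(list(epochs = epochs, l1_eps = l1_eps, n_augment = n_augment,
                 ranges = ranges, input_size = input_size,
                 seed = as.integer(seed), backbone = backbone),
            class = "bmd_config")
}

# Seeded balanced assignment of n items to k folds (sizes differ by <= 1).
fold_partition <- function(n, k = 4, seed = 1L) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# Smoothed-L1 linear fit by majorize-minimize IRLS; returns coefficients and
# the per-epoch smoothed-L1 loss (non-increasing by the MM property).
fit_l1_linear <- function(X, y, epochs, eps, ridge = 1e-6) {
  Xa <- cbind(1, X)
  beta <- solve(crossprod(Xa) + diag(ridge, ncol(Xa)), crossprod(Xa, y))
  log_loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    r <- drop(y - Xa %*% beta)
    log_loss[e] <- mean(sqrt(r^2 + eps^2))
    wgt <- 1 / sqrt(r^2 + eps^2)
    XtW <- t(Xa * wgt)
    beta <- solve(XtW %*% Xa + diag(ridge, ncol(Xa)), XtW %*% y)
  }
  list(coef = drop(beta), loss = log_loss)
}

levels_onehot <- function(level) {
  v <- as.numeric(c("L1", "L2", "L3", "L4") == level)
  names(v) <- paste0("onehot_", c("L1", "L2", "L3", "L4"))
  v
}

#' Fit the reference four-member BMD ensemble
#'
#' Trains the reference regressor under the standard contract: each ROI is
#' preprocessed ([preprocess_roi()]), optionally expanded with random affine
#' augmentations, encoded by the backbone, and — for vertebra ROIs — the
#' vertebral level is appended as a one-hot vector of length 4 before the
#' linear read-out. The data are split into four seeded folds of near-equal
#' size; member *m* is trained on the three folds other than *m* with an L1
#' (least-absolute-deviation) loss, smoothed and minimised by a
#' majorize-minimize scheme whose per-epoch loss is logged. Inference
#' averages the four members.
#'
#' @param rois list of [roi_image()] objects, all of the same site family
#'   (hip or vertebra).
#' @param bmd numeric vector of ground-truth areal BMD (g/cm^2), one per ROI.
#' @param config a [bmd_config()].
#' @return an object of class `bmd_ensemble` with components `members`
#'   (per-member coefficients), `scaling`, `folds`, `training_log`
#'   (epochs x 4 loss matrix), `site`, `config`.
#' @seealso [predict.bmd_ensemble()], [predict_bmd()]
#' @export
fit_bmd_ensemble <- function(rois, bmd, config = bmd_config()) {
  stopifnot(is.list(rois), length(rois) == length(bmd))
  if (length(rois) < 8)
    stop_validation("need at least 8 ROIs to form four folds of >= 2")
  sites <- vapply(rois, function(r) r$site, character(1))
  fam <- ifelse(startsWith(sites, "hip"), "hip", "vertebra")
  if (length(unique(fam)) != 1)
    stop_validation("all ROIs must belong to one site family (hip or vertebra)")
  spine <- fam[1] == "vertebra"
  feat_one <- function(roi) {
    g <- preprocess_roi(roi, size = config$input_size)
    f <- config$backbone(g)
    if (spine) f <- c(f, levels_onehot(roi$level))
    f
  }
  X <- t(vapply(rois, feat_one, feat_one(rois[[1]])))
  y <- bmd
  if (config$n_augment > 0) {
    extra <- list()
    for (a in seq_len(config$n_augment)) {
      Xa <- t(vapply(seq_along(rois), function(i) {
        g <- preprocess_roi(rois[[i]], size = config$input_size)
        g <- augment_roi(g, config$ranges,
                         seed = config$seed + 1000L * a + i)
        f <- config$backbone(g)
        if (spine) f <- c(f, levels_onehot(rois[[i]]$level))
        f
      }, X[1, ]))
      extra[[a]] <- Xa
    }
  }
  folds <- fold_partition(length(rois), 4, seed = config$seed)
  mu <- colMeans(X); sdev <- apply(X, 2, stats::sd); sdev[sdev == 0] <- 1
  scale_X <- function(M) sweep(sweep(M, 2, mu), 2, sdev, "/")
  members <- vector("list", 4)
  training_log <- matrix(NA_real_, config$epochs, 4,
                         dimnames = list(NULL, paste0("member", 1:4)))
  for (m in 1:4) {
    tr <- folds != m
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (config$n_augment > 0) {
      for (a in seq_len(config$n_augment)) {
        Xtr <- rbind(Xtr, extra[[a]][tr, , drop = FALSE])
        ytr <- c(ytr, y[tr])
      }
    }
    fit <- fit_l1_linear(scale_X(Xtr), ytr, config$epochs, config$l1_eps)
    members[[m]] <- fit$coef
    training_log[, m] <- fit$loss
  }
  structure(list(members = members, scaling = list(mu = mu, sd = sdev),
                 folds = folds, training_log = training_log,
                 site = fam[1], spine = spine, config = config,
                 n_train = length(rois), call = match.call()),
            class = "bmd_ensemble")
}

ensemble_features <- function(object, roi) {
  g <- preprocess_roi(roi, size = object$config$input_size)
  f <- object$config$backbone(g)
  if (object$spine) f <- c(f, levels_onehot(roi$level))
  (f - object$scaling$mu) / object$scaling$sd
}

#' Predict BMD for ROIs with a fitted ensemble
#'
#' Each of the four members predicts independently; the reported BMD is their
#' arithmetic mean. Predictions are clamped below at a small positive floor
#' (0.05 g/cm^2; clamping is recorded in the `clamped` column).
#'
#' @param object a fitted `bmd_ensemble`.
#' @param newdata an [roi_image()] or list of them.
#' @param members optional subset of member indices to use (default all 4).
#' @param ... unused.
#' @return data.frame of class `bmd_prediction`: `roi_id`, `site`, `level`,
#'   `member1`–`member4` (NA for unused members), `predicted_bmd`, `clamped`.
#' @export
predict.bmd_ensemble <- function(object, newdata, members = 1:4, ...) {
  if (inherits(newdata, "roi_image")) newdata <- list(newdata)
  stopifnot(length(newdata) >= 1)
  rows <- lapply(seq_along(newdata), function(i) {
    roi <- newdata[[i]]
    fam <- if (startsWith(roi$site, "hip")) "hip" else "vertebra"
    if (!identical(fam, object$site))
      stop_validation("ROI site ", roi$site, " does not match ensemble site ",
                      object$site)
    x <- ensemble_features(object, roi)
    pred <- rep(NA_real_, 4)
    pred[members] <- vapply(object$members[members],
                            function(b) unname(b[1] + sum(b[-1] * x)),
                            numeric(1))
    clamped <- any(pred[members] < 0.05)
    pred[members] <- pmax(pred[members], 0.05)
    data.frame(roi_id = i, site = roi$site,
               level = if (is.null(roi$level)) NA_character_ else roi$level,
               member1 = pred[1], member2 = pred[2], member3 = pred[3],
               member4 = pred[4],
               predicted_bmd = mean(pred[members]), clamped = clamped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bmd_prediction", "data.frame")
  out
}

#' Predict BMD for a single ROI
#'
#' Convenience wrapper around [predict.bmd_ensemble()] for one ROI.
#'
#' @param roi an [roi_image()].
#' @param ensemble a fitted `bmd_ensemble`.
#' @return one-row `bmd_prediction` data.frame.
#' @export
predict_bmd <- function(roi, ensemble) {
  stopifnot(inherits(ensemble, "bmd_ensemble"))
  predict(ensemble, roi)
}

#' @export
print.bmd_ensemble <- function(x, ...) {
  cat(sprintf("Reference BMD ensemble (%s): 4 members, %d training ROIs\n",
              x$site, x$n_train))
  cat(sprintf("  final smoothed-L1 losses: %s g/cm^2\n",
              paste(sprintf("%.4f", x$training_log[nrow(x$training_log), ]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.bmd_ensemble <- function(object, ...) {
  cat(sprintf("Reference BMD ensemble, site family: %s\n", object$site))
  cat(sprintf("  training ROIs: %d; fold sizes: %s\n", object$n_train,
              paste(tabulate(object$folds, 4), collapse = "/")))
  cat(sprintf("  epochs: %d; augmented copies/image: %d\n",
              object$config$epochs, object$config$n_augment))
  cat("  training loss (first -> last epoch):\n")
  tl <- object$training_log
  for (m in 1:4)
    cat(sprintf("    member %d: %.5f -> %.5f\n", m, tl[1, m], tl[nrow(tl), m]))
  invisible(object)
}

#' @export
coef.bmd_ensemble <- function(object, ...) {
  do.call(cbind, lapply(object$members, function(b) b))
}
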