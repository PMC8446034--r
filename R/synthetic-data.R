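#' Phantom specification
#'
#' Describes one synthetic vertebra/hip phantom: the ground-truth areal BMD,
#' an optional vertebral deformity family with a severity fraction, the
#' additive image-noise level, and the RNG seed that makes every derived
#' artefact reproducible.
#'
#' @param true_bmd areal bone mineral density in g/cm^2, in `[0.2, 1.6]`.
#' @param deformity one of `"none"`, `"wedge"`, `"biconcave"`, `"crush"`,
#'   `"severe_flat"`.
#' @param severity deformity severity fraction in `[0, 1]`; `0` reproduces the
#'   `"none"` geometry exactly regardless of `deformity`.
#' @param noise_sd standard deviation of additive Gaussian pixel noise, in
#'   16-bit grayscale units (default 500, about 1\% of full scale).
#' @param seed integer RNG seed; all randomness of artefacts derived from this
#'   spec flows from it (no global state is consumed or left behind).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(true_bmd, deformity = "none", severity = 0,
                         noise_sd = 500, seed = 1L) {
  assert_scalar_number(true_bmd, "true_bmd", lower = 0.2, upper = 1.6)
  deformity <- match.arg(deformity,
                         c("none", "wedge", "biconcave", "crush", "severe_flat"))
  assert_scalar_number(severity, "severity", lower = 0, upper = 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(seed, "seed")
  structure(list(true_bmd = true_bmd, deformity = deformity,
                 severity = severity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate six-point landmarks for a phantom vertebra
#'
#' Emits landmark coordinates whose morphometry reproduces a requested
#' deformity family by construction:
#' \describe{
#'   \item{none}{`h_a = h_p = h_m = base_height`.}
#'   \item{wedge}{anterior height reduced to `(1 - severity) * base_height`,
#'     posterior unchanged, middle height the mean of the two (linear plate
#'     tilt), so `r1 = 1 - severity`.}
#'   \item{biconcave}{middle height reduced to `(1 - severity) * base_height`,
#'     so `r2 = 1 - severity`.}
#'   \item{crush}{both anterior and posterior heights reduced, asymmetrically
#'     (`h_a = (1 - severity) * H`, `h_p = (1 - 0.6 * severity) * H`).}
#'   \item{severe_flat}{all three heights scaled by `(1 - severity)`, so
#'     `r3 = (1 - severity) * base_height / base_width`.}
#' }
#' The superior endplate is horizontal at `y = 0` with the posterior wall at
#' `x = 0`, so the superior anterior-posterior distance equals `base_width`
#' exactly; height loss is taken on the inferior plate (y grows downward).
#'
#' @param spec a [phantom_spec()].
#' @param base_height,base_width undeformed vertebral body height/width in mm.
#' @param level vertebral level `"L1"`–`"L4"`.
#' @return a [vertebra_landmarks()] object.
#' @export
generate_vertebra_landmarks <- function(spec, base_height = 25, base_width = 35,
                                        level = "L1") {
  stopifnot(inherits(spec, "phantom_spec"))
  assert_scalar_number(base_height, "base_height", lower = 0, strict_lower = TRUE)
  assert_scalar_number(base_width, "base_width", lower = 0, strict_lower = TRUE)
  H <- base_height; W <- base_width; s <- spec$severity
  hts <- switch(spec$deformity,
    none = c(a = H, p = H, m = H),
    wedge = c(a = (1 - s) * H, p = H, m = (1 - s / 2) * H),
    biconcave = c(a = H, p = H, m = (1 - s) * H),
    crush = c(a = (1 - s) * H, p = (1 - 0.6 * s) * H,
              m = (1 - 0.8 * s) * H),
    severe_flat = c(a = (1 - s) * H, p = (1 - s) * H, m = (1 - s) * H)
  )
  if (min(hts) <= 0)
    stop_validation("severity 1 collapses the vertebra to zero height")
  post_sup <- c(0, 0)
  ant_sup <- c(W, 0)
  post_inf <- c(0, hts[["p"]])
  ant_inf <- c(W, hts[["a"]])
  mid_sup_y <- (post_sup[2] + ant_sup[2] + post_inf[2] + ant_inf[2]) / 4 -
    hts[["m"]] / 2
  vertebra_landmarks(
    anterior_superior = ant_sup, anterior_inferior = ant_inf,
    posterior_superior = post_sup, posterior_inferior = post_inf,
    middle_superior = c(W / 2, mid_sup_y),
    middle_inferior = c(W / 2, mid_sup_y + hts[["m"]]),
    level = level, pixel_spacing = 0.15
  )
}

# Phantom image layout (size s >= 32, all blocks axis-aligned so the
# noise-free mean has an exact closed form):
#   background           intensity 4000
#   calibration marker   top-left square, side floor(s/8), intensity 62000
#   bone block           centred square, side floor(s/2), intensity
#                        10000 + 30000 * true_bmd  (affine, strictly monotone)
phantom_geometry <- function(size_px) {
  list(bg = 4000, marker = 62000,
       marker_side = max(1L, floor(size_px / 8)),
       bone_side = floor(size_px / 2),
       bone_from = floor((size_px - floor(size_px / 2)) / 2) + 1L)
}

#' Noise-free mean intensity of a phantom ROI
#'
#' The documented intensity-density map: the phantom's bone block intensity is
#' affine in `true_bmd` (`10000 + 30000 * bmd`), and with the fixed block
#' geometry the noise-free image mean follows in closed form from pixel
#' counts. Strictly increasing in `true_bmd`.
#'
#' @param true_bmd areal BMD in g/cm^2.
#' @param size_px image side length in pixels (>= 32).
#' @return expected mean intensity in 16-bit grayscale units.
#' @export
phantom_mean_intensity <- function(true_bmd, size_px = 96) {
  g <- phantom_geometry(size_px)
  n <- size_px^2
  n_marker <- g$marker_side^2
  n_bone <- g$bone_side^2
  bone <- 10000 + 30000 * true_bmd
  (n_marker * g$marker + n_bone * bone +
      (n - n_marker - n_bone) * g$bg) / n
}

#' Generate a phantom radiograph ROI
#'
#' Renders the phantom described by `spec` as a single-channel 16-bit image:
#' a flat background, a fixed full-intensity calibration marker (so per-image
#' min-max normalisation downstream cannot erase the density signal), and a
#' central bone block whose intensity is the documented affine function of
#' `true_bmd`. Gaussian noise of `spec$noise_sd` is added and the result is
#' clamped to `[0, 65535]` and rounded. Identical `(spec, size_px)` give a
#' bit-identical image.
#'
#' @param spec a [phantom_spec()].
#' @param size_px side length in pixels, >= 32.
#' @param pixel_spacing spacing of the emitted ROI in mm/pixel.
#' @param site `"hip_left"`, `"hip_right"` or `"vertebra"`.
#' @param level vertebral level when `site = "vertebra"`.
#' @return an [roi_image()] object.
#' @export
generate_phantom_roi <- function(spec, size_px = 96, pixel_spacing = 0.3,
                                 site = "vertebra", level = "L1") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(size_px) || length(size_px) != 1 || size_px < 32)
    stop_validation("size_px must be a single number >= 32")
  size_px <- as.integer(size_px)
  g <- phantom_geometry(size_px)
  px <- matrix(g$bg, size_px, size_px)
  px[seq_len(g$marker_side), seq_len(g$marker_side)] <- g$marker
  idx <- g$bone_from:(g$bone_from + g$bone_side - 1L)
  px[idx, idx] <- 10000 + 30000 * spec$true_bmd
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(size_px^2, sd = spec$noise_sd),
                              size_px, size_px))
    px <- px + noise
  }
  px <- round(pmin(pmax(px, 0), 65535))
  roi_image(px, pixel_spacing = pixel_spacing, site = site,
            level = if (identical(site, "vertebra")) level else NULL)
}

#' Generate a synthetic paired radiograph/DXA cohort
#'
#' Emulates the paired-cohort structure used to evaluate opportunistic
#' screening: each patient has a ground-truth lowest T-score drawn so that
#' the osteoporotic fraction (lowest T <= -2.5) follows a Bernoulli law with
#' the requested prevalence; per-ROI true BMD values are derived through the
#' reference table and a DXA-precision measurement error is added. Default
#' prevalences are 0.215 (hip) and 0.433 (spine), matching screening cohorts
#' of this kind.
#'
#' @param n number of patients (>= 1).
#' @param site `"hip"` or `"spine"`.
#' @param prevalence fraction of osteoporotic patients in `[0, 1]`; default
#'   0.215 for hip, 0.433 for spine.
#' @param dxa_noise_sd DXA measurement-error SD in g/cm^2 (default 0.01,
#'   precision-level).
#' @param reference a [reference_table()] used to convert T-scores to BMD.
#' @param seed integer RNG seed.
#' @return data.frame of class `cohort`: one row per ROI with columns
#'   `patient_id`, `age`, `sex`, `site`, `roi` (hip_left/hip_right or L1-L4),
#'   `true_bmd`, `measured_bmd`, `true_t`, `days_between`, `osteoporotic`
#'   (patient-level truth).
#' @export
generate_cohort <- function(n, site = c("hip", "spine"), prevalence = NULL,
                            dxa_noise_sd = 0.01, reference = default_reference(),
                            seed = 1L) {
  site <- match.arg(site)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop_validation("n must be a single number >= 1")
  n <- as.integer(n)
  if (is.null(prevalence)) prevalence <- if (site == "hip") 0.215 else 0.433
  assert_scalar_number(prevalence, "prevalence", lower = 0, upper = 1)
  assert_scalar_number(dxa_noise_sd, "dxa_noise_sd", lower = 0)
  median_gap <- if (site == "hip") 29 else 16
  rois <- if (site == "hip") c("hip_left", "hip_right") else
    c("L1", "L2", "L3", "L4")
  with_seed(seed, {
    osteo <- stats::runif(n) < prevalence
    # lowest T-score: osteoporotic patients in (-4.5, -2.5], others in (-2.5, 1.5)
    t_low <- ifelse(osteo,
                    -2.5 - stats::runif(n, 0, 2.0),
                    -2.5 + stats::runif(n, 1e-6, 4.0))
    age <- round(stats::runif(n, 40, 90))
    sex <- ifelse(stats::runif(n) < 0.78, "F", "M")
    gap <- pmin(180L, as.integer(round(stats::rexp(n, log(2) / median_gap))))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- length(rois)
      # one ROI sits exactly at the patient's lowest T; the others above it
      offs <- c(0, stats::runif(k - 1, 0, 0.8))[sample.int(k)]
      t_roi <- t_low[i] + offs
      true_bmd <- vapply(seq_len(k), function(j) {
        ref <- reference_entry(reference, site, if (site == "spine") rois[j] else NULL)
        bmd_from_t(t_roi[j], ref)
      }, numeric(1))
      measured <- pmax(0.05, true_bmd + stats::rnorm(k, sd = dxa_noise_sd))
      rows[[i]] <- data.frame(
        patient_id = sprintf("P%05d", i), age = age[i], sex = sex[i],
        site = site, roi = rois, true_bmd = true_bmd, measured_bmd = measured,
        true_t = t_roi, days_between = gap[i], osteoporotic = osteo[i],
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("cohort", "data.frame")
    out
  })
}
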