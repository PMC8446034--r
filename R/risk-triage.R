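#' Young-adult reference table for T-score conversion
#'
#' T-scores are `(BMD - young-adult mean) / young-adult SD`. Reference means
#' and SDs are device- and site-specific and are supplied as configuration;
#' they are not bundled clinical constants.
#'
#' @param entries data.frame with columns `site` (`"hip"`/`"spine"`), `level`
#'   (`NA` for hip, `"L1"`–`"L4"` for spine), `mean`, `sd` (g/cm^2, `sd > 0`).
#' @return object of class `reference_table`.
#' @export
reference_table <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("site", "level", "mean", "sd") %in% names(entries)))
  if (any(entries$sd <= 0)) stop_validation("reference SDs must be > 0")
  structure(entries, class = c("reference_table", "data.frame"))
}

#' Default reference table
#'
#' The hip entry (mean 0.83683, SD 0.11167 g/cm^2) is derived from the
#' internal consistency of the published dual-form triage thresholds, where
#' 0.513 g/cm^2 corresponds to T = -2.9 and 0.580 g/cm^2 to T = -2.3; those
#' two equations pin down the young-adult mean and SD exactly. The per-level
#' spine entries are synthetic defaults chosen to be consistent with typical
#' Hologic lumbar reference ranges (L1 lowest, L4 highest); no published
#' values are reproduced. Replace with device-specific values for any real
#' use.
#'
#' @return a [reference_table()].
#' @export
default_reference <- function() {
  sd_hip <- 0.067 / 0.6 # from (0.580 - 0.513) = (2.9 - 2.3) * sd
  reference_table(data.frame(
    site = c("hip", rep("spine", 4)),
    level = c(NA, "L1", "L2", "L3", "L4"),
    mean = c(0.513 + 2.9 * sd_hip, 0.95, 1.00, 1.03, 1.05),
    sd = c(sd_hip, 0.11, 0.11, 0.11, 0.11),
    stringsAsFactors = FALSE
  ))
}

reference_entry <- function(ref, site, level = NULL) {
  stopifnot(inherits(ref, "reference_table"))
  row <- if (identical(site, "hip")) which(ref$site == "hip")
  else which(ref$site == "spine" & ref$level == level)
  if (length(row) != 1)
    stop_validation("no unique reference entry for site ", site,
                    if (!is.null(level)) paste0(" level ", level))
  list(mean = ref$mean[row], sd = ref$sd[row])
}

#' T-score from areal BMD
#'
#' @param bmd areal BMD in g/cm^2 (vectorised).
#' @param ref a reference entry: list/row with `mean` and `sd`.
#' @return T-score(s), `(bmd - mean) / sd`.
#' @seealso [bmd_from_t()] for the exact inverse.
#' @export
t_score <- function(bmd, ref) {
  if (ref$sd <= 0) stop_validation("reference sd must be > 0")
  (bmd - ref$mean) / ref$sd
}

#' @rdname t_score
#' @param t T-score(s).
#' @export
bmd_from_t <- function(t, ref) {
  if (ref$sd <= 0) stop_validation("reference sd must be > 0")
  ref$mean + t * ref$sd
}

#' Lowest T-score over assessable ROIs
#'
#' The patient-level statistic: the minimum T-score over the ROIs that
#' survived quality assessment. ROIs excluded by QA never contribute.
#'
#' @param t_scores numeric vector of per-ROI T-scores.
#' @param assessable logical vector, same length (default all).
#' @return the minimum assessable T-score.
#' @export
lowest_t <- function(t_scores, assessable = rep(TRUE, length(t_scores))) {
  stopifnot(length(t_scores) == length(assessable))
  keep <- assessable & !is.na(t_scores)
  if (!any(keep)) stop_validation("no assessable ROI with a T-score")
  min(t_scores[keep])
}

#' Classify osteoporosis and fracture-risk categories
#'
#' Applies the standard cut-offs, all inclusive: osteoporosis when the lowest
#' T-score is <= -2.5; high 10-year major-osteoporotic-fracture risk when the
#' risk score is >= 20\%; high 10-year hip-fracture risk when >= 3\%.
#'
#' @param patient_id identifier.
#' @param lowest_t lowest assessable T-score.
#' @param major_risk_pct,hip_risk_pct optional 10-year risk scores in
#'   `[0, 100]` from a pluggable risk model.
#' @return object of class `risk_assessment`.
#' @export
classify_risk <- function(patient_id, lowest_t, major_risk_pct = NULL,
                          hip_risk_pct = NULL) {
  assert_scalar_number(lowest_t, "lowest_t")
  for (r in list(major_risk_pct, hip_risk_pct))
    if (!is.null(r)) assert_scalar_number(r, "risk score", lower = 0, upper = 100)
  structure(list(
    patient_id = patient_id, lowest_t = lowest_t,
    osteoporotic = lowest_t <= -2.5,
    major_risk_pct = major_risk_pct, hip_risk_pct = hip_risk_pct,
    high_major = if (is.null(major_risk_pct)) NULL else major_risk_pct >= 20,
    high_hip = if (is.null(hip_risk_pct)) NULL else hip_risk_pct >= 3
  ), class = "risk_assessment")
}

#' Toy 10-year fracture-risk model (NOT FRAX)
#'
#' A documented logistic toy model mapping age, sex, and the lowest T-score
#' to plausible 10-year major-osteoporotic and hip fracture risk percentages.
#' It exists so the risk-classification plumbing is testable; it is NOT the
#' FRAX calculator, shares none of its coefficients, and must not be used
#' clinically. Any function returning `list(major_pct, hip_pct)` can be
#' plugged in instead.
#'
#' @param age years.
#' @param sex `"F"` or `"M"`.
#' @param lowest_t lowest T-score.
#' @return list with `major_pct` and `hip_pct`, each in `[0, 100]`.
#' @export
toy_risk_model <- function(age, sex, lowest_t) {
  fem <- as.numeric(sex == "F")
  major <- 100 * stats::plogis(-3.3 + 0.045 * (age - 65) - 0.55 * lowest_t +
                                 0.35 * fem)
  hip <- 100 * stats::plogis(-4.6 + 0.06 * (age - 65) - 0.75 * lowest_t +
                               0.25 * fem)
  list(major_pct = major, hip_pct = hip)
}

#' Cross-calibrate BMD between densitometer devices
#'
#' Affine conversion `slope * bmd + intercept`, with device- and
#' site-specific coefficients supplied as configuration (manufacturer
#' cross-calibration equations are typically linear). Identity by default.
#'
#' @param bmd areal BMD (vectorised).
#' @param slope,intercept conversion coefficients.
#' @return converted BMD.
#' @export
convert_device <- function(bmd, slope = 1, intercept = 0) {
  assert_scalar_number(slope, "slope")
  assert_scalar_number(intercept, "intercept")
  slope * bmd + intercept
}

#' Dual-threshold triage of a predicted BMD or T-score
#'
#' Routes each value through the dual thresholds `t1 < t2` (both on the same
#' scale as `value`, either g/cm^2 or T-score units):
#' `value < t1` is classified osteoporotic without DXA; `t1 <= value < t2`
#' is referred for confirmatory DXA; `value >= t2` is classified
#' non-osteoporotic. `t1` is chosen upstream for >= 95\% PPV and `t2` for
#' >= 95\% NPV (see [find_threshold()]). Published hip operating points:
#' `t1 = 0.513` g/cm^2 (T -2.9), `t2 = 0.580` (T -2.3); spine (T-score form):
#' `t1 = -3.0`, `t2 = -2.1`.
#'
#' @param value numeric vector of predicted BMD or T-scores (one scale per
#'   call; never mix).
#' @param t1,t2 thresholds, `t1 < t2`.
#' @param patient_id optional identifiers.
#' @return data.frame of class `triage_decision` with columns `patient_id`,
#'   `value`, `category` (factor: `classified_osteoporotic`, `refer_dxa`,
#'   `classified_non_osteoporotic`), `t1`, `t2`.
#' @export
triage <- function(value, t1, t2, patient_id = seq_along(value)) {
  assert_scalar_number(t1, "t1"); assert_scalar_number(t2, "t2")
  if (!(t1 < t2)) stop_validation("t1 must be < t2")
  if (any(!is.finite(value))) stop_validation("values must be finite")
  cat3 <- c("classified_osteoporotic", "refer_dxa", "classified_non_osteoporotic")
  category <- factor(ifelse(value < t1, cat3[1],
                            ifelse(value < t2, cat3[2], cat3[3])),
                     levels = cat3)
  out <- data.frame(patient_id = patient_id, value = value,
                    category = category, t1 = t1, t2 = t2,
                    stringsAsFactors = FALSE)
  class(out) <- c("triage_decision", "data.frame")
  out
}

#' Summarise triage decisions
#'
#' Counts and percentages per triage category, percentages rounded half-up
#' to one decimal as in clinical report tables.
#'
#' @param decisions a `triage_decision` data.frame from [triage()].
#' @param cohort_n denominator (defaults to `nrow(decisions)`).
#' @return data.frame with `category`, `n`, `pct`.
#' @export
triage_summary <- function(decisions, cohort_n = nrow(decisions)) {
  stopifnot(inherits(decisions, "triage_decision"), nrow(decisions) >= 1)
  tab <- table(decisions$category)
  data.frame(category = names(tab), n = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / cohort_n, 1),
             stringsAsFactors = FALSE)
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("Risk assessment for %s: lowest T = %.2f -> %s\n", x$patient_id,
              x$lowest_t, if (x$osteoporotic) "osteoporotic" else "not osteoporotic"))
  if (!is.null(x$major_risk_pct))
    cat(sprintf("  10-y major fracture risk %.2f%% (high: %s)\n",
                x$major_risk_pct, x$high_major))
  if (!is.null(x$hip_risk_pct))
    cat(sprintf("  10-y hip fracture risk %.2f%% (high: %s)\n",
                x$hip_risk_pct, x$high_hip))
  invisible(x)
}
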