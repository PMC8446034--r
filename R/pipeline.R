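#' Pipeline configuration
#'
#' Every implicit operating constant of the screening pipeline lives here:
#' detector thresholds, neighbour-deviation margin, triage thresholds
#' (T-score scale), reference table, risk model, phantom/simulation settings,
#' and seeds. Unknown keys are rejected.
#'
#' @param site `"hip"` or `"spine"`.
#' @param n_patients number of patients to simulate/screen.
#' @param prevalence osteoporosis prevalence (defaults: 0.215 hip,
#'   0.433 spine, see [generate_cohort()]).
#' @param implant_rate per-ROI probability of a ground-truth implant.
#' @param fracture_rate per-ROI probability of a ground-truth fracture flag
#'   (hip) or detector-visible VCF (spine).
#' @param deformity_rate per-vertebra probability of a moderate-to-severe
#'   morphometric deformity (spine only).
#' @param detector_threshold positivity threshold on aggregated detector
#'   scores (inclusive).
#' @param neighbor_delta neighbour-deviation margin, T-score units.
#' @param neighbor_method `"loo"` or `"adjacent"` (see [neighbor_exclusion()]).
#' @param t1,t2 triage thresholds on the T-score scale; defaults are the
#'   published operating points (hip -2.9/-2.3, spine -3.0/-2.1).
#' @param reference a [reference_table()].
#' @param risk_model function `(age, sex, lowest_t) -> list(major_pct,
#'   hip_pct)`; default [toy_risk_model()].
#' @param roi_size phantom ROI side length in pixels.
#' @param bmd a [bmd_config()] for the reference regressor.
#' @param seed master seed; all stage seeds derive from it.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(site = "hip", n_patients = 50, prevalence = NULL,
                            implant_rate = 0.05, fracture_rate = 0.03,
                            deformity_rate = 0.08,
                            detector_threshold = 0.5,
                            neighbor_delta = 1.0, neighbor_method = "loo",
                            t1 = NULL, t2 = NULL,
                            reference = default_reference(),
                            risk_model = toy_risk_model,
                            roi_size = 64,
                            bmd = bmd_config(input_size = 128),
                            seed = 1L) {
  site <- match.arg(site, c("hip", "spine"))
  if (is.null(t1)) t1 <- if (site == "hip") -2.9 else -3.0
  if (is.null(t2)) t2 <- if (site == "hip") -2.3 else -2.1
  cfg <- list(site = site, n_patients = as.integer(n_patients), prevalence = prevalence,
              implant_rate = implant_rate, fracture_rate = fracture_rate,
              deformity_rate = deformity_rate,
              detector_threshold = detector_threshold,
              neighbor_delta = neighbor_delta,
              neighbor_method = neighbor_method,
              t1 = t1, t2 = t2, reference = reference,
              risk_model = risk_model, roi_size = roi_size, bmd = bmd,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
}

pipeline_config_keys <- function() {
  c("site", "n_patients", "prevalence", "implant_rate", "fracture_rate",
    "deformity_rate", "detector_threshold", "neighbor_delta",
    "neighbor_method", "t1", "t2", "reference", "risk_model", "roi_size",
    "bmd", "seed")
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), pipeline_config_keys())
  if (length(unknown))
    stop_validation("unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(pipeline_config_keys(), names(cfg))
  if (length(missing))
    stop_validation("missing config keys: ", paste(missing, collapse = ", "))
  if (!cfg$site %in% c("hip", "spine")) stop_validation("site must be hip or spine")
  if (!(cfg$t1 < cfg$t2)) stop_validation("t1 must be < t2")
  for (k in c("implant_rate", "fracture_rate", "deformity_rate"))
    assert_scalar_number(cfg[[k]], k, lower = 0, upper = 1)
  if (!is.function(cfg$risk_model)) stop_validation("risk_model must be a function")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys are taken from the file; the reference table may be given as
#' a list of entries (`site`, `level`, `mean`, `sd`). Keys not in the schema
#' are rejected; the risk model and regressor config stay at their defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), pipeline_config_keys())
  if (length(unknown))
    stop_validation("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$reference))
    raw$reference <- reference_table(
      do.call(rbind, lapply(raw$reference, function(e)
        data.frame(site = e$site, level = e$level %||% NA, mean = e$mean,
                   sd = e$sd, stringsAsFactors = FALSE))))
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full synthetic screening study
#'
#' Generates the paired cohort ([generate_cohort()]) and, per ROI, a phantom
#' spec, ground-truth QA flags (implant/fracture/VCF/deformity), six-point
#' landmarks (spine), and the phantom ROI image. This is the input surface
#' of [run_screen()].
#'
#' @param config a [pipeline_config()].
#' @return list of class `screen_study` with `cohort` (data.frame) and
#'   `rois` (list parallel to cohort rows: `spec`, `flags`, `landmarks`,
#'   `roi`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$n_patients, site = config$site,
                            prevalence = config$prevalence,
                            reference = config$reference,
                            seed = config$seed)
  nr <- nrow(cohort)
  draws <- with_seed(config$seed + 1L, list(
    implant = stats::runif(nr) < config$implant_rate,
    fracture = stats::runif(nr) < config$fracture_rate,
    deform = stats::runif(nr) < config$deformity_rate,
    dtype = sample(c("wedge", "biconcave", "severe_flat"), nr, replace = TRUE),
    sev = stats::runif(nr, 0.45, 0.7)
  ))
  rois <- lapply(seq_len(nr), function(i) {
    spine <- cohort$site[i] == "spine"
    deformity <- if (spine && draws$deform[i]) draws$dtype[i] else "none"
    severity <- if (deformity == "none") 0 else draws$sev[i]
    spec <- phantom_spec(
      true_bmd = min(1.6, max(0.2, cohort$true_bmd[i])),
      deformity = deformity, severity = severity,
      seed = config$seed + 10L * i)
    flags <- character()
    if (draws$implant[i]) flags <- c(flags, "implant")
    if (draws$fracture[i])
      flags <- c(flags, if (spine) "vcf" else "fracture")
    site_lab <- if (spine) "vertebra" else cohort$roi[i]
    level <- if (spine) cohort$roi[i] else NULL
    list(spec = spec, flags = flags,
         landmarks = if (spine)
           generate_vertebra_landmarks(spec, level = level) else NULL,
         roi = generate_phantom_roi(spec, size_px = config$roi_size,
                                    site = site_lab, level = level))
  })
  structure(list(cohort = cohort, rois = rois, config = config),
            class = "screen_study")
}

screen_one_hip <- function(rows, rois, ensemble, config) {
  ref <- reference_entry(config$reference, "hip")
  qa <- lapply(seq_along(rois), function(k) {
    det <- list(
      fracture = synthetic_detector(rois[[k]]$flags, "fracture"),
      implant = synthetic_detector(rois[[k]]$flags, "implant"))
    img <- rois[[k]]$roi$pixels
    poly <- cbind(c(1, ncol(img), ncol(img), 1), c(1, 1, nrow(img), nrow(img)))
    hip_qa(img, poly, det, roi_id = rows$roi[k],
           thresholds = c(fracture = config$detector_threshold,
                          implant = config$detector_threshold))
  })
  ok <- vapply(qa, function(q) q$admissible, logical(1))
  reasons <- unique(unlist(lapply(qa, function(q) q$reasons)))
  if (!any(ok))
    return(list(status = "inadmissible", reasons = reasons, qa = qa))
  preds <- predict(ensemble, lapply(which(ok), function(k) rois[[k]]$roi))
  tt <- t_score(preds$predicted_bmd, ref)
  list(status = "ok", reasons = reasons, qa = qa,
       n_assessable = sum(ok), lowest_t = min(tt))
}

screen_one_spine <- function(rows, rois, ensemble, config) {
  levels <- rows$roi
  preds <- predict(ensemble, lapply(rois, function(r) r$roi))
  tt <- vapply(seq_along(levels), function(k) {
    t_score(preds$predicted_bmd[k],
            reference_entry(config$reference, "spine", levels[k]))
  }, numeric(1))
  names(tt) <- levels
  vertebrae <- stats::setNames(lapply(seq_along(levels), function(k) {
    fl <- rois[[k]]$flags
    list(landmarks = rois[[k]]$landmarks,
         scores = c(implant = if ("implant" %in% fl) 0.9 else 0.02,
                    vcf = if ("vcf" %in% fl) 0.9 else 0.02))
  }), levels)
  qa <- spine_qa(vertebrae, tt, threshold = config$detector_threshold,
                 delta = config$neighbor_delta,
                 method = config$neighbor_method)
  ok <- vapply(qa, function(q) q$admissible, logical(1))
  reasons <- unique(unlist(lapply(qa, function(q) q$reasons)))
  if (!attr(qa, "scan_admissible"))
    return(list(status = "inadmissible", reasons = reasons, qa = qa))
  list(status = "ok", reasons = reasons, qa = qa,
       n_assessable = sum(ok), lowest_t = lowest_t(tt, ok))
}

#' Run the end-to-end screening pipeline
#'
#' For every patient of a simulated study: radiograph QA (hip
#' fracture/implant exclusion or the three-step spine procedure), per-ROI BMD
#' prediction with the four-member ensemble, lowest assessable T-score,
#' osteoporosis and fracture-risk classification, and dual-threshold triage.
#' Patients failing QA are reported with their exclusion reasons, never
#' dropped; per-patient errors are caught and recorded while the run
#' continues.
#'
#' @param study a `screen_study` from [simulate_study()].
#' @param ensemble a fitted `bmd_ensemble` for the study's site family.
#' @param config a [pipeline_config()] (defaults to the study's own).
#' @return data.frame of class `screen_report`, one row per patient:
#'   `patient_id`, `status` (`ok`/`inadmissible`/`error`), `reasons`,
#'   `n_assessable`, `lowest_t`, `osteoporotic`, `major_risk_pct`,
#'   `hip_risk_pct`, `high_major`, `high_hip`, `triage`.
#' @export
run_screen <- function(study, ensemble, config = study$config) {
  stopifnot(inherits(study, "screen_study"), inherits(ensemble, "bmd_ensemble"))
  ids <- unique(study$cohort$patient_id)
  rows <- lapply(ids, function(pid) {
    idx <- which(study$cohort$patient_id == pid)
    sub <- study$cohort[idx, , drop = FALSE]
    res <- tryCatch({
      r <- if (config$site == "hip")
        screen_one_hip(sub, study$rois[idx], ensemble, config)
      else screen_one_spine(sub, study$rois[idx], ensemble, config)
      if (r$status != "ok") {
        data.frame(patient_id = pid, status = r$status,
                   reasons = paste(r$reasons, collapse = ";"),
                   n_assessable = 0L, lowest_t = NA_real_,
                   osteoporotic = NA, major_risk_pct = NA_real_,
                   hip_risk_pct = NA_real_, high_major = NA, high_hip = NA,
                   triage = NA_character_, stringsAsFactors = FALSE)
      } else {
        risk <- config$risk_model(sub$age[1], sub$sex[1], r$lowest_t)
        ra <- classify_risk(pid, r$lowest_t, risk$major_pct, risk$hip_pct)
        tr <- triage(r$lowest_t, config$t1, config$t2, patient_id = pid)
        data.frame(patient_id = pid, status = "ok",
                   reasons = paste(r$reasons, collapse = ";"),
                   n_assessable = r$n_assessable, lowest_t = r$lowest_t,
                   osteoporotic = ra$osteoporotic,
                   major_risk_pct = ra$major_risk_pct,
                   hip_risk_pct = ra$hip_risk_pct,
                   high_major = ra$high_major, high_hip = ra$high_hip,
                   triage = as.character(tr$category),
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      data.frame(patient_id = pid, status = "error",
                 reasons = conditionMessage(e), n_assessable = 0L,
                 lowest_t = NA_real_, osteoporotic = NA,
                 major_risk_pct = NA_real_, hip_risk_pct = NA_real_,
                 high_major = NA, high_hip = NA, triage = NA_character_,
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screen_report", "data.frame")
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Screening report: %d patients (%d ok, %d inadmissible, %d error)\n",
              nrow(x), sum(x$status == "ok"), sum(x$status == "inadmissible"),
              sum(x$status == "error")))
  ok <- x[x$status == "ok", ]
  if (nrow(ok)) {
    tab <- table(factor(ok$triage, levels = c("classified_osteoporotic",
                                              "refer_dxa",
                                              "classified_non_osteoporotic")))
    for (nm in names(tab)) cat(sprintf("  %-28s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

run_manifest <- function(config, dir, stage) {
  atomic_only <- function(l) l[vapply(l, function(x)
    is.atomic(x) && !is.matrix(x), logical(1))]
  cfg <- atomic_only(config)
  cfg$bmd <- atomic_only(config$bmd)
  manifest <- list(stage = stage, seed = config$seed,
                   package_version = as.character(utils::packageVersion("osteoscreen")),
                   config = cfg)
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Pipeline stage wrappers
#'
#' Thin wrappers over the module entry points that write their artefacts
#' (cohort CSV, landmark files, ROI TIFFs, training log, metrics JSON) plus a
#' manifest recording the seed, package version, and configuration.
#'
#' @param config a [pipeline_config()].
#' @param dir output directory (created if needed).
#' @return `run_simulate`: the `screen_study` (invisibly, after writing
#'   artefacts); `run_train`: the fitted `bmd_ensemble`; `run_evaluate`: the
#'   metrics list.
#' @export
run_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config)
  write_cohort_csv(study$cohort, file.path(dir, "cohort.csv"))
  spine <- config$site == "spine"
  if (spine) {
    lms <- lapply(study$rois, function(r) r$landmarks)
    write_landmarks(lms, file.path(dir, "landmarks.txt"))
  }
  for (i in seq_along(study$rois))
    write_roi_tiff(study$rois[[i]]$roi,
                   file.path(dir, sprintf("roi_%04d.tif", i)))
  run_manifest(config, dir, "simulate")
  invisible(study)
}

#' @rdname run_simulate
#' @param study optional pre-simulated `screen_study` to train on; by default
#'   a fresh training study is simulated with `seed + 1000`.
#' @export
run_train <- function(config, dir = NULL, study = NULL) {
  if (is.null(study)) {
    tcfg <- config
    tcfg$seed <- config$seed + 1000L
    study <- simulate_study(tcfg)
  }
  rois <- lapply(study$rois, function(r) r$roi)
  ensemble <- fit_bmd_ensemble(rois, study$cohort$measured_bmd, config$bmd)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(ensemble$training_log),
                     file.path(dir, "training_log.csv"), row.names = FALSE)
    run_manifest(config, dir, "train")
  }
  ensemble
}

#' @rdname run_simulate
#' @param report a `screen_report` from [run_screen()].
#' @export
run_evaluate <- function(config, study, report, dir = NULL) {
  truth <- stats::aggregate(true_t ~ patient_id, data = study$cohort, FUN = min)
  merged <- merge(report[report$status == "ok", ], truth, by = "patient_id")
  m <- metrics_report(predicted = merged$lowest_t, measured = merged$true_t,
                      positive = merged$true_t <= -2.5,
                      pred_positive = merged$lowest_t <= -2.5)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    flat <- m[!vapply(m, is.list, logical(1))]
    jsonlite::write_json(flat, file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    run_manifest(config, dir, "evaluate")
  }
  m
}
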