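# Plain-text landmark files, 16-bit TIFF ROI images, cohort CSVs.

#' Write and read landmark files
#'
#' Landmarks are exchanged as structured text: one record per vertebra,
#' starting with a `vertebra <level> spacing <mm/px>` line followed by six
#' `<name> <x> <y>` lines (mm), records separated by blank lines.
#'
#' @param landmarks a [vertebra_landmarks()] or list of them.
#' @param path file path.
#' @return `write_landmarks` returns `path` invisibly; `read_landmarks`
#'   returns a list of [vertebra_landmarks()].
#' @export
write_landmarks <- function(landmarks, path) {
  if (inherits(landmarks, "vertebra_landmarks")) landmarks <- list(landmarks)
  point_names <- c("anterior_superior", "anterior_inferior",
                   "posterior_superior", "posterior_inferior",
                   "middle_superior", "middle_inferior")
  blocks <- vapply(landmarks, function(l) {
    paste(c(sprintf("vertebra %s spacing %.17g", l$level, l$pixel_spacing),
            vapply(point_names, function(nm)
              sprintf("%s %.17g %.17g", nm, l[[nm]][1], l[[nm]][2]),
              character(1))),
          collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lines <- trimws(readLines(path))
  starts <- grep("^vertebra ", lines)
  if (length(starts) == 0) stop_validation("no vertebra records in ", path)
  lapply(starts, function(s) {
    hdr <- strsplit(lines[s], "\\s+")[[1]]
    pts <- list()
    for (k in 1:6) {
      f <- strsplit(lines[s + k], "\\s+")[[1]]
      pts[[f[1]]] <- as.numeric(f[2:3])
    }
    vertebra_landmarks(
      anterior_superior = pts$anterior_superior,
      anterior_inferior = pts$anterior_inferior,
      posterior_superior = pts$posterior_superior,
      posterior_inferior = pts$posterior_inferior,
      middle_superior = pts$middle_superior,
      middle_inferior = pts$middle_inferior,
      level = hdr[2], pixel_spacing = as.numeric(hdr[4]))
  })
}

#' Write and read a 16-bit TIFF ROI image
#'
#' Pixels are stored as 16-bit grayscale; the spacing, site, and level are
#' not carried by the TIFF and must travel in a sidecar (see the cohort CSV
#' and landmark files), so `read_roi_tiff` takes them as arguments.
#'
#' @param roi an [roi_image()].
#' @param path file path.
#' @return `write_roi_tiff` returns `path` invisibly.
#' @export
write_roi_tiff <- function(roi, path) {
  stopifnot(inherits(roi, "roi_image"))
  tiff::writeTIFF(roi$pixels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_roi_tiff
#' @inheritParams roi_image
#' @export
read_roi_tiff <- function(path, pixel_spacing, site = "vertebra", level = NULL) {
  px <- round(tiff::readTIFF(path) * 65535)
  roi_image(px, pixel_spacing = pixel_spacing, site = site, level = level)
}

#' Write and read a cohort CSV
#'
#' Header: `patient_id, age, sex, site, roi, true_bmd, measured_bmd, true_t,
#' days_between, osteoporotic` — one row per ROI.
#'
#' @param cohort a `cohort` data.frame from [generate_cohort()].
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}
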