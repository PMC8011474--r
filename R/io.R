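# ---- plain-text / image I/O for the pipeline's external formats ----

#' Write and read per-slice SRF masks as PNG files
#'
#' One single-channel PNG per B-scan, nonzero = SRF, laid out as
#' `<dir>/slice_<s>.png` (0-based slice index).
#'
#' @param masks list of binary slice matrices
#' @param dir output directory (created)
#' @export
write_masks_png <- function(masks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(masks)) {
    png::writePNG(pmin(masks[[s]], 1),
                  file.path(dir, sprintf("slice_%03d.png", s - 1)))
  }
  invisible(dir)
}

#' @rdname write_masks_png
#' @export
read_masks_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.png$", full.names = TRUE))
  lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    (m > 0) * 1L
  })
}

#' Serialize an OCT geometry to JSON
#' @param g an [oct_geometry()]
#' @param path file path
#' @export
write_geometry_json <- function(g, path) {
  jsonlite::write_json(unclass(g), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  oct_geometry(g$n_slices, g$y0, g$dy, g$x0, g$sx, g$n_cols, g$depth)
}

# polynomial rolling hash of a string, as 8 hex digits (manifest fingerprint)
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_csv_quiet <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}

#' Validate pipeline input files against the expected schemas
#'
#' Checks visits.csv (eye_id, visit_date, n_slices), spots.csv (eye_id,
#' x, y), and geometry.json for presence, required columns, and value
#' sanity (non-negative coordinates/dates). Never raises: every finding is
#' returned as a row.
#'
#' @param visits_csv,spots_csv,geometry_json file paths (NA to skip)
#' @return data.frame with columns file, row, finding (zero rows when all
#'   inputs conform)
#' @export
validate_inputs <- function(visits_csv = NA, spots_csv = NA, geometry_json = NA) {
  findings <- data.frame(file = character(0), row = integer(0),
                         finding = character(0))
  note <- function(file, row, what) {
    findings <<- rbind(findings,
                       data.frame(file = file, row = row, finding = what))
  }
  if (!is.na(visits_csv)) {
    if (!file.exists(visits_csv)) note(visits_csv, NA, "file missing")
    else {
      v <- tryCatch(utils::read.csv(visits_csv), error = function(e) NULL)
      if (is.null(v)) note(visits_csv, NA, "unreadable CSV")
      else {
        need <- c("eye_id", "visit_date", "n_slices")
        miss <- setdiff(need, names(v))
        if (length(miss) > 0)
          note(visits_csv, NA, paste("missing columns:", paste(miss, collapse = ", ")))
        else {
          if (nrow(v) == 0) note(visits_csv, NA, "no visits")
          bad <- which(v$visit_date < 0)
          for (r in bad) note(visits_csv, r, "negative visit_date")
        }
      }
    }
  }
  if (!is.na(spots_csv)) {
    if (!file.exists(spots_csv)) note(spots_csv, NA, "file missing")
    else {
      s <- tryCatch(utils::read.csv(spots_csv), error = function(e) NULL)
      if (is.null(s)) note(spots_csv, NA, "unreadable CSV")
      else {
        need <- c("eye_id", "x", "y")
        miss <- setdiff(need, names(s))
        if (length(miss) > 0)
          note(spots_csv, NA, paste("missing columns:", paste(miss, collapse = ", ")))
        else {
          for (r in which(s$x < 0 | s$y < 0))
            note(spots_csv, r, "negative spot coordinate")
        }
      }
    }
  }
  if (!is.na(geometry_json)) {
    if (!file.exists(geometry_json)) note(geometry_json, NA, "file missing")
    else {
      g <- tryCatch(read_geometry_json(geometry_json), error = function(e) NULL)
      if (is.null(g)) note(geometry_json, NA, "invalid geometry JSON")
    }
  }
  findings
}

#' Write a synthetic cohort to disk in the pipeline's external formats
#'
#' visits.csv, spots.csv, geometry.json, truth.json, and per-eye per-visit
#' PNG mask directories under `masks/`.
#'
#' @param cohort output of [generate_cohort()]
#' @param dir output directory
#' @param write_mask_png also materialise the (bulky) PNG masks
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir, write_mask_png = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_quiet(cohort$visits, file.path(dir, "visits.csv"))
  write_csv_quiet(cohort$spots, file.path(dir, "spots.csv"))
  write_geometry_json(cohort$geometry, file.path(dir, "geometry.json"))
  truth <- lapply(cohort$truth, function(e) {
    list(eye_id = e$eye_id, baseline_srf = e$baseline_srf,
         activity_onset = e$activity_onset,
         conversion_interval = e$conversion_interval,
         lesions = lapply(e$lesions, function(l)
           l[c("cx", "cy", "ax", "ay", "onset", "kind")]))
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (write_mask_png) {
    for (e in cohort$truth) {
      vd <- cohort$visits$visit_date[cohort$visits$eye_id == e$eye_id]
      series <- generate_srf_series(e, cohort$config, visit_dates = vd,
                                    geom = cohort$geometry)
      for (j in seq_along(series))
        write_masks_png(series[[j]]$masks,
                        file.path(dir, "masks", e$eye_id, sprintf("visit_%02d", j - 1)))
    }
  }
  invisible(dir)
}
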