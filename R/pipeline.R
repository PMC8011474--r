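#' Pipeline run configuration
#'
#' Bundles the synthetic-cohort settings with every analysis threshold the
#' pipeline uses, so that each constant of the method (DARC-count split 5,
#' high/low SRF split 2000 px, 6-month windows, spot-SRF overlap
#' tolerance, detector settings) is sweepable rather than hard-coded.
#'
#' @param cohort a [cohort_config()] (the synthetic data source)
#' @param detector a [detector_config()]
#' @param darc_threshold DARC-count grouping cutoff for survival analysis
#' @param srf_split_threshold high/low SRF split, pixels per scan
#' @param srf_min_pixels SRF-positivity threshold (px/scan)
#' @param tol_slices,tol_cols spot-SRF overlap tolerance window
#' @param use_planted_spots if TRUE the generator's ground-truth spot
#'   coordinates feed the analysis directly (isolating the linkage logic);
#'   if FALSE spots are detected from rendered images
#' @param outdir optional output directory for the CSV/JSON report bundle
#' @return a `run_config` list
#' @export
run_config <- function(cohort = cohort_config(),
                       detector = detector_config(),
                       darc_threshold = 5,
                       srf_split_threshold = 2000,
                       srf_min_pixels = 0,
                       tol_slices = 1, tol_cols = 10,
                       use_planted_spots = FALSE,
                       outdir = NULL) {
  stopifnot(darc_threshold >= 0, srf_split_threshold > 0,
            tol_slices >= 0, tol_cols >= 0)
  structure(as.list(environment()), class = "run_config")
}

# spots entering analysis for one eye: planted coordinates or detection on
# rendered baseline-AF and post-injection images, with baseline subtraction
eye_analysis_spots <- function(eye, rc) {
  cfg <- rc$cohort
  if (rc$use_planted_spots) {
    sp <- eye$spots
    darc <- sp[sp$label != "autofluorescent", c("x", "y"), drop = FALSE]
    af <- sp[sp$label == "autofluorescent", c("x", "y"), drop = FALSE]
    kept <- subtract_baseline(darc, af, rc$detector$baseline_radius)
    return(list(spots = kept, darc_count = nrow(kept)))
  }
  af_img <- render_fundus_image(eye$spots[eye$spots$label == "autofluorescent", ,
                                          drop = FALSE], cfg)
  darc_img <- render_fundus_image(eye$spots, cfg)  # AF spots glow in both
  af_det <- detect_spots(af_img, rc$detector)
  darc_det <- detect_spots(darc_img, rc$detector)
  kept <- subtract_baseline(darc_det, af_det, rc$detector$baseline_radius)
  list(spots = kept[, c("x", "y"), drop = FALSE], darc_count = nrow(kept))
}

# per-interval SRF column-occupancy for one eye from ground truth
eye_interval_occupancy <- function(eye, cfg, geom) {
  lapply(0:(cfg$n_intervals - 1), function(k)
    runs_occupancy(eye_srf_runs(eye, k, geom, cfg), geom))
}

#' Read a pipeline run configuration from a YAML file
#'
#' One file with per-module sections (`cohort`, `detector`, plus top-level
#' analysis thresholds) so every constant of the method is sweepable.
#' Fields not present keep their documented defaults.
#'
#' @param path YAML file path
#' @return a [run_config()]
#' @export
read_run_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, if (is.null(y$cohort)) list() else y$cohort)
  detector <- do.call(detector_config,
                      if (is.null(y$detector)) list() else y$detector)
  rest <- y[setdiff(names(y), c("cohort", "detector"))]
  do.call(run_config, c(list(cohort = cohort, detector = detector), rest))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes generate -> detect/subtract (or planted spots) -> map to OCT
#' coordinates -> quantify SRF per visit and interval -> conversion and
#' unique-spot analysis -> confusion matrices, survival curves, group
#' statistics and SRF-magnitude association. Fully determined by
#' `rc$cohort$seed`.
#'
#' @param rc a [run_config()]
#' @return list with `timelines`, `labels` (per eye x interval TP/FP/FN/TN),
#'   `confusion` (per-interval matrix + metrics), `conversion`
#'   (per-interval cumulative rate), `survival`, `group_tests`,
#'   `association`, `eye_summary`, and `manifest`
#' @export
run_pipeline <- function(rc = run_config()) {
  cfg <- rc$cohort
  cohort <- generate_cohort(cfg)
  if (cfg$n_eyes == 0) stop("empty cohort")
  geom <- cohort$geometry
  timelines <- list()
  labels <- list()
  unique_rows <- list()
  eye_summary <- list()
  for (eye in cohort$truth) {
    det <- eye_analysis_spots(eye, rc)
    vd <- cohort$visits$visit_date[cohort$visits$eye_id == eye$eye_id]
    amounts <- vapply(vd, function(d) {
      runs <- eye_srf_runs(eye, visit_interval(d, cfg$interval_length), geom, cfg)
      runs_pixel_count(runs, geom, cfg)
    }, numeric(1))
    tl <- build_timeline(eye$eye_id, vd, amounts, cfg$n_intervals,
                         cfg$interval_length, rc$srf_min_pixels,
                         darc_count = det$darc_count)
    timelines[[eye$eye_id]] <- tl
    occ <- eye_interval_occupancy(eye, cfg, geom)
    base_occ <- runs_occupancy(eye_srf_runs(eye, -1L, geom, cfg), geom)
    us <- unique_spots(det$spots, occ, base_occ, geom,
                       rc$tol_slices, rc$tol_cols)
    if (nrow(us) > 0)
      unique_rows[[eye$eye_id]] <- cbind(eye_id = eye$eye_id, us)
    ucount <- tabulate(us$interval + 1, nbins = cfg$n_intervals)
    lab <- vapply(seq_len(cfg$n_intervals), function(k)
      classify_eye_interval(ucount[k], tl$intervals$new_srf[k]), character(1))
    labels[[eye$eye_id]] <- data.frame(
      eye_id = eye$eye_id, interval = 0:(cfg$n_intervals - 1),
      unique_count = ucount, new_srf = tl$intervals$new_srf,
      accum_srf = tl$intervals$accum_srf, carried = tl$intervals$carried,
      label = lab)
    eye_summary[[eye$eye_id]] <- data.frame(
      eye_id = eye$eye_id, darc_count = det$darc_count,
      baseline_srf = tl$baseline_srf,
      conversion_interval = tl$conversion_interval,
      true_conversion = eye$conversion_interval)
  }
  labels <- do.call(rbind, labels)
  rownames(labels) <- NULL
  confusion <- confusion_table(labels)
  conversion <- data.frame(
    interval = 0:(cfg$n_intervals - 1),
    rate = vapply(0:(cfg$n_intervals - 1),
                  function(k) conversion_rate(timelines, k), numeric(1)))
  survival <- srf_free_survival(timelines, rc$darc_threshold)
  group_tests <- tryCatch(compare_groups(survival), error = function(e) NULL)
  assoc_in <- labels[!labels$carried, c("interval", "unique_count", "accum_srf")]
  association <- spot_srf_association(assoc_in, rc$srf_split_threshold)
  eye_summary <- do.call(rbind, eye_summary)
  rownames(eye_summary) <- NULL
  manifest <- list(
    seed = cfg$seed,
    config_hash = fnv1a(paste(deparse(rc[setdiff(names(rc), "outdir")]),
                              collapse = "")),
    thresholds = list(darc = rc$darc_threshold,
                      srf_split = rc$srf_split_threshold,
                      srf_min_pixels = rc$srf_min_pixels,
                      tol_slices = rc$tol_slices, tol_cols = rc$tol_cols),
    n_eyes = cfg$n_eyes, n_intervals = cfg$n_intervals,
    package_version = as.character(utils::packageVersion("darcsrf")))
  result <- list(timelines = timelines, labels = labels, confusion = confusion,
                 conversion = conversion, survival = survival,
                 group_tests = group_tests, association = association,
                 eye_summary = eye_summary,
                 unique_spots = if (length(unique_rows) > 0)
                   do.call(rbind, unique_rows) else NULL,
                 manifest = manifest)
  if (!is.null(rc$outdir)) write_report(result, rc$outdir)
  result
}

#' Write the pipeline report bundle
#'
#' table1.csv (per-interval predictive metrics and cumulative conversion
#' rate, proportions given both as fractions and rounded percentages),
#' confusion.csv, survival.csv, association.csv, timelines.csv and
#' manifest.json.
#'
#' @param result a [run_pipeline()] result
#' @param dir output directory (created)
#' @export
write_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  conf <- result$confusion
  table1 <- data.frame(
    interval = conf$interval,
    months = (conf$interval + 1) * 6,
    ppv = conf$ppv, specificity = conf$specificity,
    sensitivity = conf$sensitivity, npv = conf$npv,
    ppv_pct = round(100 * conf$ppv), specificity_pct = round(100 * conf$specificity),
    sensitivity_pct = round(100 * conf$sensitivity), npv_pct = round(100 * conf$npv),
    conversion_rate = result$conversion$rate[match(conf$interval,
                                                   result$conversion$interval)])
  write_csv_quiet(table1, file.path(dir, "table1.csv"))
  write_csv_quiet(conf, file.path(dir, "confusion.csv"))
  write_csv_quiet(result$survival, file.path(dir, "survival.csv"))
  write_csv_quiet(result$association, file.path(dir, "association.csv"))
  tl <- do.call(rbind, lapply(result$timelines, function(t)
    cbind(eye_id = t$eye_id, t$intervals)))
  rownames(tl) <- NULL
  write_csv_quiet(tl, file.path(dir, "timelines.csv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
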