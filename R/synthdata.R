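#' Synthetic cohort configuration
#'
#' Parameters of the synthetic longitudinal AMD cohort: per-eye DARC spot
#' counts, irregular OCT visit schedules over follow-up, and subretinal
#' fluid (SRF) lesions whose onset is probabilistically linked to planted
#' "angiogenic" spots. Defaults emulate the study cohort structure: 29
#' eyes, 36 months of follow-up in 6-month intervals, ~2.1 OCT scans per
#' eye per interval (the study range was 1.70-2.59), 50 B-scans per
#' volume, and roughly a third of eyes SRF-positive at baseline.
#'
#' @param n_eyes number of eyes
#' @param months_followup total follow-up in months; must be a multiple of
#'   `interval_length`
#' @param interval_length analysis window length in months
#' @param visits_per_interval_mean Poisson mean of OCT visits per interval
#'   (each interval gets at least one visit)
#' @param slices_per_volume B-scans per OCT volume
#' @param spot_count_mean Poisson mean of planted angiogenic DARC spots
#'   per eye
#' @param nuisance_spot_mean Poisson mean of nuisance (non-angiogenic)
#'   DARC spots per eye
#' @param autofluorescent_spot_mean Poisson mean of baseline
#'   autofluorescent spots per eye (visible pre- and post-injection)
#' @param association_strength probability in [0, 1] that an angiogenic
#'   spot seeds an SRF lesion at its location at the eye's activity onset
#' @param spontaneous_lesion_mean Poisson mean of spot-independent SRF
#'   lesions per eye (uniform location and onset interval)
#' @param baseline_srf_fraction probability an eye carries SRF at baseline
#' @param image_size en-face image side length in pixels (square)
#' @param spot_amplitude,spot_sigma rendered spot peak intensity and
#'   Gaussian radius (px)
#' @param background_level,background_noise_sd background intensity mean
#'   and Gaussian noise SD
#' @param lesion_ax,lesion_ay initial lesion ellipse semi-axes in fundus px
#' @param lesion_growth per-interval fractional growth of lesion semi-axes
#'   after onset
#' @param lesion_thickness axial thickness (mask rows) of rasterized SRF
#' @param regression if TRUE lesions clear after `lesion_duration`
#'   intervals (allows recurrence scenarios); default FALSE (fluid
#'   persists and grows)
#' @param lesion_duration intervals a lesion persists when `regression`
#' @param seed integer RNG seed; the dataset is fully determined by
#'   config + seed
#' @return a validated `cohort_config` list
#' @export
cohort_config <- function(n_eyes = 29,
                          months_followup = 36,
                          interval_length = 6,
                          visits_per_interval_mean = 2.1,
                          slices_per_volume = 50,
                          spot_count_mean = 5,
                          nuisance_spot_mean = 2,
                          autofluorescent_spot_mean = 2,
                          association_strength = 0.05,
                          spontaneous_lesion_mean = 0.15,
                          baseline_srf_fraction = 0.34,
                          image_size = 256,
                          spot_amplitude = 100,
                          spot_sigma = 2,
                          background_level = 20,
                          background_noise_sd = 10,
                          lesion_ax = 18,
                          lesion_ay = 12,
                          lesion_growth = 0.25,
                          lesion_thickness = 4,
                          regression = FALSE,
                          lesion_duration = 2,
                          seed = 1L) {
  cfg <- as.list(environment())
  num_fields <- c("n_eyes", "months_followup", "interval_length",
                  "visits_per_interval_mean", "slices_per_volume",
                  "spot_count_mean", "nuisance_spot_mean",
                  "autofluorescent_spot_mean", "spontaneous_lesion_mean",
                  "baseline_srf_fraction", "image_size", "spot_amplitude",
                  "spot_sigma", "background_noise_sd", "lesion_ax",
                  "lesion_ay", "lesion_growth", "lesion_thickness",
                  "lesion_duration")
  for (f in num_fields)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0)
      stop(sprintf("invalid config value for '%s': must be a non-negative number", f))
  if (cfg$association_strength < 0 || cfg$association_strength > 1)
    stop("invalid config value for 'association_strength': must lie in [0, 1]")
  if (cfg$baseline_srf_fraction > 1)
    stop("invalid config value for 'baseline_srf_fraction': must lie in [0, 1]")
  if (cfg$months_followup %% cfg$interval_length != 0)
    stop("invalid config: 'interval_length' must divide 'months_followup'")
  if (cfg$interval_length <= 0)
    stop("invalid config value for 'interval_length': must be positive")
  cfg$n_intervals <- as.integer(cfg$months_followup / cfg$interval_length)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cohort_config")
}

#' Default OCT geometry for a synthetic eye
#'
#' The volume's fundus footprint spans the image minus a margin; slices
#' are evenly spaced rows, columns map 1:1 to fundus x.
#'
#' @param config a [cohort_config()]
#' @param margin footprint margin in pixels
#' @return an [oct_geometry()]
#' @export
synth_geometry <- function(config, margin = 16) {
  n <- config$slices_per_volume
  oct_geometry(n_slices = n, y0 = margin,
               dy = (config$image_size - 2 * margin) / (n - 1),
               x0 = 0, sx = 1, n_cols = config$image_size,
               depth = 32)
}

runif_int <- function(n, lo, hi) as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))

# draw spot coordinates uniformly inside the OCT footprint (with a small
# inner margin so rendered blobs and seeded lesions stay in bounds)
draw_positions <- function(n, config, geom, pad = 24) {
  data.frame(
    x = stats::runif(n, pad, config$image_size - 1 - pad),
    y = stats::runif(n, geom$y0, geom$y0 + (geom$n_slices - 1) * geom$dy)
  )
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Each eye receives Poisson numbers of angiogenic, nuisance and baseline
#' autofluorescent spots at uniform fundus positions; an activity-onset
#' interval is drawn per eye, and each angiogenic spot seeds an SRF lesion
#' centred on it (onset at the eye's activity interval, always at least
#' one interval after the baseline spot imaging) with probability
#' `association_strength`. Spot-independent "spontaneous" lesions with
#' their own uniform onset model background conversion. Baseline-positive
#' eyes carry a lesion already present at month 0. Visit schedules are
#' Poisson counts per 6-month interval (minimum one) at uniform dates,
#' plus a baseline visit.
#'
#' @param config a [cohort_config()]
#' @return list with `visits` (eye_id, visit_date in months, interval),
#'   `spots` (eye_id, x, y, label in angiogenic/nuisance/autofluorescent),
#'   `geometry` ([oct_geometry()]), `config`, and `truth` (per-eye list:
#'   spots, lesions with onset/centre/axes, baseline_srf, activity onset,
#'   true conversion interval)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  set.seed(config$seed)
  geom <- synth_geometry(config)
  nI <- config$n_intervals
  eyes <- vector("list", config$n_eyes)
  visits <- list(); spots <- list()
  for (e in seq_len(config$n_eyes)) {
    eid <- sprintf("eye%03d", e)
    n_ang <- stats::rpois(1, config$spot_count_mean)
    n_nui <- stats::rpois(1, config$nuisance_spot_mean)
    n_af  <- stats::rpois(1, config$autofluorescent_spot_mean)
    pos <- draw_positions(n_ang + n_nui + n_af, config, geom)
    lab <- rep(c("angiogenic", "nuisance", "autofluorescent"),
               c(n_ang, n_nui, n_af))
    eye_spots <- cbind(pos, label = lab, stringsAsFactors = FALSE)
    baseline_srf <- stats::runif(1) < config$baseline_srf_fraction
    # per-eye neovascular activity onset: >= 1 interval after the baseline
    # DARC imaging (spots mark pre-leakage endothelial activity)
    activity_onset <- if (nI >= 2) runif_int(1, 1L, nI - 1L) else NA_integer_
    lesions <- list()
    if (n_ang > 0 && !is.na(activity_onset)) {
      seeded <- stats::runif(n_ang) < config$association_strength
      for (k in which(seeded)) {
        lesions[[length(lesions) + 1]] <- list(
          cx = eye_spots$x[k], cy = eye_spots$y[k],
          ax = config$lesion_ax, ay = config$lesion_ay,
          onset = activity_onset, seeded_by = k, kind = "seeded")
      }
    }
    n_spont <- stats::rpois(1, config$spontaneous_lesion_mean)
    if (n_spont > 0) {
      cpos <- draw_positions(n_spont, config, geom)
      onsets <- runif_int(n_spont, 0L, nI - 1L)
      for (k in seq_len(n_spont)) {
        lesions[[length(lesions) + 1]] <- list(
          cx = cpos$x[k], cy = cpos$y[k],
          ax = config$lesion_ax, ay = config$lesion_ay,
          onset = onsets[k], seeded_by = NA_integer_, kind = "spontaneous")
      }
    }
    if (baseline_srf) {
      cpos <- draw_positions(1, config, geom)
      lesions[[length(lesions) + 1]] <- list(
        cx = cpos$x, cy = cpos$y,
        ax = config$lesion_ax, ay = config$lesion_ay,
        onset = -1L, seeded_by = NA_integer_, kind = "baseline")
    }
    # visit schedule: baseline + >=1 uniformly dated visit per interval
    n_vis <- pmax(1, stats::rpois(nI, config$visits_per_interval_mean))
    dates <- sort(unlist(lapply(seq_len(nI), function(i) {
      stats::runif(n_vis[i], (i - 1) * config$interval_length,
                   i * config$interval_length)
    })))
    dates <- c(0, dates)
    visits[[e]] <- data.frame(
      eye_id = eid, visit_date = dates,
      interval = visit_interval(dates, config$interval_length),
      n_slices = config$slices_per_volume, stringsAsFactors = FALSE)
    if (nrow(eye_spots) > 0)
      spots[[e]] <- cbind(eye_id = eid, eye_spots, stringsAsFactors = FALSE)
    post_onsets <- vapply(lesions, function(l) l$onset, integer(1))
    post_onsets <- post_onsets[post_onsets >= 0]
    eyes[[e]] <- list(
      eye_id = eid, spots = eye_spots, lesions = lesions,
      baseline_srf = baseline_srf, activity_onset = activity_onset,
      conversion_interval = if (!baseline_srf && length(post_onsets) > 0)
        min(post_onsets) else NA_integer_)
  }
  if (config$n_eyes > 0)
    names(eyes) <- vapply(eyes, `[[`, character(1), "eye_id")
  visits <- if (length(visits) > 0) do.call(rbind, visits) else
    data.frame(eye_id = character(0), visit_date = numeric(0),
               interval = integer(0), n_slices = integer(0))
  spots <- if (length(spots) > 0) do.call(rbind, spots) else
    data.frame(eye_id = character(0), x = numeric(0), y = numeric(0),
               label = character(0))
  rownames(visits) <- rownames(spots) <- NULL
  list(visits = visits, spots = spots, geometry = geom, config = config,
       truth = eyes)
}

# interval index of a visit date: half-open [L*k, L*(k+1)); baseline
# (month 0) is interval -1 by convention here, handled by caller as baseline
visit_interval <- function(date, interval_length) {
  i <- as.integer(floor(date / interval_length))
  i[date == 0] <- -1L
  i
}

#' Render a synthetic en-face fundus image from a spot table
#'
#' Additive composition: a flat background plus i.i.d. Gaussian noise plus
#' one isotropic Gaussian blob (peak `spot_amplitude`, radius
#' `spot_sigma`) per spot.
#'
#' @param spots data.frame with x, y columns (0-based pixel coordinates,
#'   inside the image)
#' @param config a [cohort_config()]
#' @return image matrix `image_size` x `image_size` (rows = y)
#' @export
render_fundus_image <- function(spots, config) {
  n <- config$image_size
  img <- matrix(config$background_level, n, n)
  if (config$background_noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, config$background_noise_sd), n, n)
  if (nrow(spots) > 0) {
    bad <- spots$x < 0 | spots$x > n - 1 | spots$y < 0 | spots$y > n - 1
    if (any(bad))
      stop(sprintf("spot out of image bounds: (%g, %g)",
                   spots$x[which(bad)[1]], spots$y[which(bad)[1]]))
    r <- ceiling(4 * config$spot_sigma)
    for (k in seq_len(nrow(spots))) {
      x0 <- spots$x[k]; y0 <- spots$y[k]
      cs <- max(0, floor(x0 - r)):min(n - 1, ceiling(x0 + r))
      rs <- max(0, floor(y0 - r)):min(n - 1, ceiling(y0 + r))
      blob <- config$spot_amplitude *
        exp(-(outer((rs - y0)^2, (cs - x0)^2, "+")) / (2 * config$spot_sigma^2))
      img[rs + 1, cs + 1] <- img[rs + 1, cs + 1] + blob
    }
  }
  img
}

# lesion semi-axes at a given interval (growth after onset; optional clearing)
lesion_axes_at <- function(lesion, interval, config) {
  if (interval < lesion$onset) return(NULL)
  if (isTRUE(config$regression) && lesion$onset >= 0 &&
      interval >= lesion$onset + config$lesion_duration) return(NULL)
  k <- if (lesion$onset < 0) interval + 1 else interval - lesion$onset
  g <- 1 + config$lesion_growth * k
  list(ax = lesion$ax * g, ay = lesion$ay * g)
}

# rasterize one lesion at one interval onto the OCT grid: per-slice column
# runs. Returns data.frame(slice, col_lo, col_hi) (0-based, inclusive).
lesion_runs <- function(lesion, interval, geom, config) {
  axes <- lesion_axes_at(lesion, interval, config)
  empty <- data.frame(slice = integer(0), col_lo = integer(0), col_hi = integer(0))
  if (is.null(axes)) return(empty)
  slices <- 0:(geom$n_slices - 1)
  ys <- geom$y0 + slices * geom$dy
  rel <- (ys - lesion$cy) / axes$ay
  hit <- abs(rel) <= 1
  if (!any(hit)) return(empty)
  half <- axes$ax * sqrt(pmax(0, 1 - rel[hit]^2))
  col_lo <- pmax(0L, as.integer(ceiling((lesion$cx - half - geom$x0) / geom$sx)))
  col_hi <- pmin(geom$n_cols - 1L, as.integer(floor((lesion$cx + half - geom$x0) / geom$sx)))
  out <- data.frame(slice = slices[hit], col_lo = col_lo, col_hi = col_hi)
  out[out$col_hi >= out$col_lo, , drop = FALSE]
}

# all SRF column-runs for one eye at one interval (union over lesions is
# left to consumers; runs may overlap)
eye_srf_runs <- function(eye_truth, interval, geom, config) {
  runs <- lapply(eye_truth$lesions, lesion_runs, interval = interval,
                 geom = geom, config = config)
  do.call(rbind, c(runs, list(data.frame(slice = integer(0), col_lo = integer(0),
                                         col_hi = integer(0)))))
}

# per-slice column occupancy (logical vector list) from runs
runs_occupancy <- function(runs, geom) {
  occ <- vector("list", geom$n_slices)
  for (s in seq_len(geom$n_slices)) occ[[s]] <- logical(geom$n_cols)
  if (nrow(runs) > 0)
    for (k in seq_len(nrow(runs)))
      occ[[runs$slice[k] + 1]][(runs$col_lo[k]:runs$col_hi[k]) + 1] <- TRUE
  occ
}

# SRF pixel count of one volume scan from runs (occupied columns x axial
# thickness)
runs_pixel_count <- function(runs, geom, config) {
  occ <- runs_occupancy(runs, geom)
  sum(vapply(occ, sum, numeric(1))) * config$lesion_thickness
}

#' Per-visit per-slice SRF masks for one synthetic eye
#'
#' Materialises the binary UNET-style segmentation masks implied by the
#' eye's ground-truth lesions: for each visit, `slices_per_volume`
#' depth-by-width matrices with the lesion's fundus-column extent filled
#' over a fixed axial band of `lesion_thickness` rows. Masks are empty
#' before a lesion's onset interval and non-decreasing afterwards (the
#' ellipse grows about a fixed centre) unless `regression` is set.
#'
#' @param eye_truth one element of `generate_cohort()$truth`
#' @param config the [cohort_config()]
#' @param visit_dates visit dates in months (default: one visit per
#'   interval midpoint plus baseline)
#' @param geom OCT geometry (default [synth_geometry()])
#' @return list of visits; each a list with `date`, `interval`, and
#'   `masks` (list of 0/1 matrices, one per slice)
#' @export
generate_srf_series <- function(eye_truth, config, visit_dates = NULL,
                                geom = synth_geometry(config)) {
  if (is.null(visit_dates))
    visit_dates <- c(0, (seq_len(config$n_intervals) - 0.5) * config$interval_length)
  lapply(visit_dates, function(d) {
    interval <- visit_interval(d, config$interval_length)
    runs <- eye_srf_runs(eye_truth, interval, geom, config)
    occ <- runs_occupancy(runs, geom)
    band <- axial_band(geom, config)
    masks <- lapply(occ, function(cols) {
      m <- matrix(0L, geom$depth, geom$n_cols)
      if (any(cols)) m[band, cols] <- 1L
      m
    })
    list(date = d, interval = interval, masks = masks)
  })
}

axial_band <- function(geom, config) {
  t <- min(config$lesion_thickness, geom$depth)
  start <- max(1, floor((geom$depth - t) / 2) + 1)
  start:(start + t - 1)
}
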