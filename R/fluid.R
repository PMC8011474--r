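#' SRF amount of a single OCT visit
#'
#' Sum of segmented SRF pixels over all B-scan masks of the visit; the
#' per-visit quantity that per-interval averaging normalises for uneven
#' scan schedules.
#'
#' @param masks list of binary (0/1 or logical) slice matrices, >= 1
#' @return total SRF pixel count
#' @export
visit_srf_amount <- function(masks) {
  if (length(masks) == 0) stop("visit has no masks")
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slice masks of a visit must share one shape")
  sum(vapply(masks, function(m) sum(m != 0), numeric(1)))
}

#' Accumulated SRF of a 6-month interval
#'
#' Total SRF pixels across all OCT scans in the window divided by the
#' number of scans — the scan-count average that makes uneven visit
#' schedules comparable between eyes and intervals.
#'
#' @param visit_amounts per-scan SRF pixel counts for the window (may be
#'   empty)
#' @return average SRF pixels per scan; NA for an empty window (no scans)
#' @export
interval_accumulated_srf <- function(visit_amounts) {
  if (length(visit_amounts) == 0) return(NA_real_)
  mean(visit_amounts)
}

#' SRF positivity of an interval
#'
#' @param accumulated_srf scan-averaged SRF pixels (NA = no scans)
#' @param min_pixels positivity threshold; the default 0 calls any
#'   detected SRF positive
#' @return TRUE/FALSE, or NA when the interval has no scans (caller
#'   carries the previous status forward)
#' @export
srf_positive <- function(accumulated_srf, min_pixels = 0) {
  ifelse(is.na(accumulated_srf), NA, accumulated_srf > min_pixels)
}

#' Build an eye's interval timeline from per-visit SRF amounts
#'
#' Groups visits into half-open 6-month windows `[Lk, L(k+1))` (the
#' baseline visit at month 0 stands apart and sets baseline SRF status),
#' computes accumulated SRF and positivity per interval, carries status
#' forward over scan-free intervals (flagged), and derives the new-SRF
#' flags and the conversion interval.
#'
#' @param eye_id eye identifier
#' @param visit_dates visit dates in months (month 0 = baseline)
#' @param visit_amounts per-visit SRF pixel counts, same length
#' @param n_intervals number of follow-up intervals
#' @param interval_length window length in months
#' @param min_pixels SRF positivity threshold (pixels per scan)
#' @param darc_count eye-level DARC count (carried for downstream use)
#' @return an `eye_timeline` list: eye_id, baseline_srf, darc_count,
#'   conversion_interval (NA if none), and `intervals` data.frame
#'   (interval, n_scans, accum_srf, carried (status imputed from previous
#'   interval), srf_pos, new_srf)
#' @export
build_timeline <- function(eye_id, visit_dates, visit_amounts, n_intervals,
                           interval_length = 6, min_pixels = 0,
                           darc_count = NA_integer_) {
  stopifnot(length(visit_dates) == length(visit_amounts))
  iv <- visit_interval(visit_dates, interval_length)
  base_idx <- which(iv == -1L)
  baseline_srf <- if (length(base_idx) > 0)
    isTRUE(srf_positive(mean(visit_amounts[base_idx]), min_pixels)) else FALSE
  intervals <- data.frame(interval = 0:(n_intervals - 1), n_scans = 0L,
                          accum_srf = NA_real_, carried = FALSE,
                          srf_pos = NA, new_srf = NA)
  for (k in 0:(n_intervals - 1)) {
    sel <- which(iv == k)
    intervals$n_scans[k + 1] <- length(sel)
    intervals$accum_srf[k + 1] <- interval_accumulated_srf(visit_amounts[sel])
    intervals$srf_pos[k + 1] <- srf_positive(intervals$accum_srf[k + 1], min_pixels)
  }
  # scan-free intervals: carry the previous status forward, flagged
  prev <- baseline_srf
  for (k in seq_len(n_intervals)) {
    if (is.na(intervals$srf_pos[k])) {
      intervals$srf_pos[k] <- prev
      intervals$carried[k] <- TRUE
    }
    prev <- intervals$srf_pos[k]
  }
  # new SRF: positive with an SRF-negative preceding period
  prev <- baseline_srf
  for (k in seq_len(n_intervals)) {
    intervals$new_srf[k] <- isTRUE(intervals$srf_pos[k]) && !isTRUE(prev)
    prev <- intervals$srf_pos[k]
  }
  structure(list(eye_id = eye_id, baseline_srf = baseline_srf,
                 darc_count = darc_count,
                 conversion_interval = conversion_from_flags(
                   baseline_srf, intervals$new_srf, intervals$interval),
                 intervals = intervals),
            class = "eye_timeline")
}

conversion_from_flags <- function(baseline_srf, new_srf, interval_idx) {
  if (isTRUE(baseline_srf)) return(NA_integer_)   # cannot newly convert
  hit <- which(new_srf)
  if (length(hit) == 0) NA_integer_ else as.integer(interval_idx[hit[1]])
}

#' Conversion interval of an eye timeline
#'
#' First interval that is SRF-positive after an SRF-negative preceding
#' period (baseline status for interval 0); first occurrence only. Eyes
#' SRF-positive at baseline return NA — they cannot newly convert.
#'
#' @param timeline an `eye_timeline` from [build_timeline()]
#' @return 0-based interval index, or NA
#' @export
detect_conversion <- function(timeline) {
  conversion_from_flags(timeline$baseline_srf, timeline$intervals$new_srf,
                        timeline$intervals$interval)
}

#' Cumulative conversion rate of a cohort
#'
#' 100 x (eyes converted at any interval <= k) / (at-risk eyes), where
#' at-risk eyes are SRF-negative at baseline with follow-up. Cumulative,
#' hence non-decreasing in k.
#'
#' @param timelines list of `eye_timeline`s
#' @param k interval index (0-based) up to which conversions count
#' @return percentage; NA (with a warning) if no eye is at risk
#' @export
conversion_rate <- function(timelines, k) {
  at_risk <- Filter(function(t) !isTRUE(t$baseline_srf), timelines)
  if (length(at_risk) == 0) {
    warning("conversion rate undefined: no at-risk eyes")
    return(NA_real_)
  }
  conv <- vapply(at_risk, function(t) {
    ci <- t$conversion_interval
    !is.na(ci) && ci <= k
  }, logical(1))
  100 * sum(conv) / length(at_risk)
}

#' Pixel-level precision-recall evaluation of SRF segmentation
#'
#' Pools pixel TP/FP/FN over all images at each threshold: precision =
#' TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R); the area under the
#' precision-recall curve is integrated by trapezoid over the recall axis.
#'
#' @param pred list of probability maps (or binary matrices), same shapes
#'   as `truth`
#' @param truth list of binary ground-truth masks
#' @param thresholds probability cutoffs defining the curve
#' @param operating_threshold cutoff at which the point metrics are
#'   reported
#' @return list with `curve` (data.frame threshold, precision, recall,
#'   f1), `precision`, `recall`, `f1`, `auc`; recall is NA (flagged) when
#'   the truth has no positive pixels
#' @export
precision_recall <- function(pred, truth, thresholds = seq(0.05, 0.95, by = 0.05),
                             operating_threshold = 0.5) {
  stopifnot(length(pred) == length(truth))
  for (i in seq_along(pred))
    if (!all(dim(pred[[i]]) == dim(truth[[i]])))
      stop("prediction and truth shapes differ")
  pos_truth <- sum(vapply(truth, function(m) sum(m != 0), numeric(1)))
  eval_at <- function(th) {
    tp <- fp <- fn <- 0
    for (i in seq_along(pred)) {
      p <- pred[[i]] >= th
      t <- truth[[i]] != 0
      tp <- tp + sum(p & t); fp <- fp + sum(p & !t); fn <- fn + sum(!p & t)
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    c(precision = prec, recall = rec)
  }
  thr <- sort(unique(c(thresholds, operating_threshold)))
  pts <- t(vapply(thr, eval_at, c(precision = 0, recall = 0)))
  curve <- data.frame(threshold = thr, precision = pts[, 1], recall = pts[, 2])
  curve$f1 <- f1_score(curve$precision, curve$recall)
  op <- curve[match(operating_threshold, curve$threshold), ]
  ok <- stats::complete.cases(curve[, c("precision", "recall")])
  auc <- if (sum(ok) >= 2) {
    cc <- curve[ok, ]
    cc <- cc[order(cc$recall), ]
    sum(diff(cc$recall) * (utils::head(cc$precision, -1) + utils::tail(cc$precision, -1)) / 2)
  } else NA_real_
  if (pos_truth == 0) warning("no positive truth pixels: recall undefined")
  list(curve = curve, precision = op$precision, recall = op$recall,
       f1 = op$f1, auc = auc)
}

#' F1 score from precision and recall
#'
#' Harmonic mean: 2PR / (P + R).
#' @param precision,recall proportions in [0, 1]
#' @return F1 (NA when either input is NA or both are 0)
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}
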