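#' Does a fundus spot overlie SRF in a visit's masks?
#'
#' Maps the spot through the OCT geometry to (slice, column) and reports
#' whether any SRF pixel lies within the tolerance window (+/- `tol_slices`
#' B-scans, +/- `tol_cols` columns). The tolerance absorbs registration
#' error; the window defaults mirror the anisotropy of the volume (slices
#' are far coarser than columns).
#'
#' @param spot point (x, y) in the registered fundus frame
#' @param masks list of per-slice binary masks (or NULL with `occupancy`)
#' @param geom an [oct_geometry()]
#' @param tol_slices,tol_cols tolerance window half-widths
#' @param occupancy optional precomputed per-slice column-occupancy
#'   (list of logical vectors) to avoid materialising masks
#' @return TRUE/FALSE; error if the spot falls outside the volume footprint
#' @export
spot_overlies_srf <- function(spot, masks = NULL, geom, tol_slices = 1,
                              tol_cols = 10, occupancy = NULL) {
  sc <- fundus_to_oct(spot, geom)
  if (is.null(occupancy)) {
    occupancy <- lapply(masks, function(m) colSums(m != 0) > 0)
  }
  s_lo <- max(0, sc$slice - tol_slices); s_hi <- min(geom$n_slices - 1, sc$slice + tol_slices)
  c_lo <- max(0, sc$col - tol_cols); c_hi <- min(geom$n_cols - 1, sc$col + tol_cols)
  for (s in s_lo:s_hi)
    if (any(occupancy[[s + 1]][(c_lo:c_hi) + 1])) return(TRUE)
  FALSE
}

#' Unique DARC spots per interval
#'
#' Applies the unique-spot rules: spots overlying SRF at baseline are
#' excluded outright; each remaining spot contributes once, at the first
#' follow-up interval where it overlies SRF (new at its location by
#' construction of the first-occurrence rule), and never again.
#'
#' @param spots data.frame of baseline-subtracted spots (x, y)
#' @param interval_occupancy list over intervals (0-based + 1) of
#'   per-slice column-occupancy lists (SRF present at any scan of the
#'   interval)
#' @param baseline_occupancy occupancy at the baseline visit
#' @param geom an [oct_geometry()]
#' @param tol_slices,tol_cols overlap tolerance window
#' @return data.frame (spot, interval) with one row per unique spot at its
#'   first-overlap interval; spots outside the volume footprint are
#'   dropped with a warning
#' @export
unique_spots <- function(spots, interval_occupancy, baseline_occupancy, geom,
                         tol_slices = 1, tol_cols = 10) {
  out <- data.frame(spot = integer(0), interval = integer(0))
  if (nrow(spots) == 0) return(out)
  n_int <- length(interval_occupancy)
  for (i in seq_len(nrow(spots))) {
    p <- c(spots$x[i], spots$y[i])
    ok <- tryCatch({ fundus_to_oct(p, geom); TRUE }, error = function(e) FALSE)
    if (!ok) {
      warning(sprintf("spot %d outside volume footprint; excluded", i))
      next
    }
    if (spot_overlies_srf(p, geom = geom, tol_slices = tol_slices,
                          tol_cols = tol_cols, occupancy = baseline_occupancy))
      next  # baseline-SRF overlap: excluded from prediction
    for (k in seq_len(n_int)) {
      if (spot_overlies_srf(p, geom = geom, tol_slices = tol_slices,
                            tol_cols = tol_cols,
                            occupancy = interval_occupancy[[k]])) {
        out <- rbind(out, data.frame(spot = i, interval = k - 1L))
        break  # first occurrence only
      }
    }
  }
  out
}

#' Classify an eye in one interval
#'
#' The eye-level decision rule: any unique DARC spot in the interval and
#' new SRF -> TP; new SRF without unique spots -> FN; unique spots without
#' new SRF -> FP; neither -> TN.
#'
#' @param unique_count unique DARC spots attributed to the interval
#' @param new_srf logical new-SRF flag of the interval
#' @return one of "TP", "FP", "FN", "TN"
#' @export
classify_eye_interval <- function(unique_count, new_srf) {
  if (is.na(unique_count) || is.na(new_srf)) stop("inputs must be defined")
  if (unique_count > 0 && new_srf) "TP"
  else if (unique_count == 0 && new_srf) "FN"
  else if (unique_count > 0 && !new_srf) "FP"
  else "TN"
}

#' Predictive metrics from a confusion matrix
#'
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). Zero denominators yield NA, never a silent
#' 0 or 1.
#'
#' @param tp,fp,fn,tn non-negative eye counts
#' @return list with ppv, npv, sensitivity, specificity
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("confusion counts must be non-negative")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
       sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp))
}

#' Per-interval confusion matrices from eye classifications
#'
#' @param labels data.frame with columns eye_id, interval, label
#'   ("TP"/"FP"/"FN"/"TN")
#' @return data.frame per interval: tp, fp, fn, tn, n, ppv, npv,
#'   sensitivity, specificity
#' @export
confusion_table <- function(labels) {
  out <- lapply(sort(unique(labels$interval)), function(k) {
    l <- labels$label[labels$interval == k]
    tp <- sum(l == "TP"); fp <- sum(l == "FP")
    fn <- sum(l == "FN"); tn <- sum(l == "TN")
    m <- confusion_metrics(tp, fp, fn, tn)
    data.frame(interval = k, tp = tp, fp = fp, fn = fn, tn = tn,
               n = length(l), ppv = m$ppv, npv = m$npv,
               sensitivity = m$sensitivity, specificity = m$specificity)
  })
  do.call(rbind, out)
}

#' SRF-free survival by DARC-count group
#'
#' For each interval and DARC-count group (> threshold vs <= threshold),
#' the proportion of the group's at-risk eyes (SRF-negative at baseline)
#' not yet converted by the end of that interval. Non-increasing within
#' each group by construction.
#'
#' @param timelines list of `eye_timeline`s with darc_count set
#' @param darc_threshold grouping cutoff (default 5, the study's split)
#' @return data.frame: interval, group ("high" = count > threshold),
#'   n_at_risk, surviving, proportion (NA rows flagged via n_at_risk = 0)
#' @export
srf_free_survival <- function(timelines, darc_threshold = 5) {
  at_risk <- Filter(function(t) !isTRUE(t$baseline_srf), timelines)
  if (length(at_risk) == 0) stop("no at-risk eyes")
  n_int <- nrow(at_risk[[1]]$intervals)
  grp <- vapply(at_risk, function(t) t$darc_count > darc_threshold, logical(1))
  conv <- vapply(at_risk, function(t) {
    ci <- t$conversion_interval
    if (is.na(ci)) Inf else ci
  }, numeric(1))
  out <- list()
  for (g in c(TRUE, FALSE)) {
    sel <- conv[grp == g]
    n <- length(sel)
    for (k in 0:(n_int - 1)) {
      surv <- if (n > 0) sum(sel > k) else NA_integer_
      out[[length(out) + 1]] <- data.frame(
        interval = k, group = if (g) "high" else "low",
        n_at_risk = n, surviving = surv,
        proportion = if (n > 0) surv / n else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  if (any(res$n_at_risk == 0)) warning("empty DARC-count group: curve missing")
  res
}

#' Compare SRF-free survival curves between DARC-count groups
#'
#' Wilcoxon signed-rank test on the paired per-interval surviving
#' proportions (exact for few intervals), plus per-group ordinary
#' least-squares regression of proportion on interval with a
#' slope-difference test. Identical curves give p = 1 (no nonzero paired
#' differences).
#'
#' @param survival output of [srf_free_survival()]
#' @return list with `wilcoxon` (W, p) and `regression`
#'   ([linreg_compare()] output)
#' @export
compare_groups <- function(survival) {
  hi <- survival[survival$group == "high", ]
  lo <- survival[survival$group == "low", ]
  if (nrow(hi) != nrow(lo)) stop("groups must share the interval grid")
  if (nrow(hi) < 2) stop("need at least 2 intervals")
  d <- hi$proportion - lo$proportion
  w <- wilcoxon_signed_rank(d)
  if (is.na(w$p) && all(d == 0, na.rm = TRUE)) w$p <- 1  # identical curves
  reg <- linreg_compare(hi$interval, hi$proportion, lo$interval, lo$proportion)
  list(wilcoxon = w, regression = reg)
}

#' Association between unique DARC spots and SRF magnitude
#'
#' Per interval: Spearman rank correlation between eyes' unique-spot
#' counts and accumulated SRF, and a Mann-Whitney comparison of counts
#' between 'high SRF' and 'low SRF' eyes split at `split_threshold`
#' (default 2000 px/scan, the study's split; its figure legend states
#' 3000 um^2 — the unit conflict is surfaced here as a parameter).
#'
#' @param df data.frame with columns interval, unique_count, accum_srf
#'   (one row per eye per interval; carried/no-scan intervals should be
#'   excluded by the caller)
#' @param split_threshold high/low SRF cutoff in pixels per scan
#' @return data.frame per interval: n, spearman_r, mw_U, mw_p, n_high,
#'   n_low (NA correlation when fewer than 3 eyes or all tied)
#' @export
spot_srf_association <- function(df, split_threshold = 2000) {
  out <- lapply(sort(unique(df$interval)), function(k) {
    d <- df[df$interval == k & !is.na(df$accum_srf), ]
    r <- if (nrow(d) >= 3) spearman_rho(d$unique_count, d$accum_srf) else NA_real_
    hi <- d$unique_count[d$accum_srf > split_threshold]
    lo <- d$unique_count[d$accum_srf <= split_threshold]
    mw <- if (length(hi) > 0 && length(lo) > 0) mann_whitney(hi, lo)
    else list(U = NA_real_, p = NA_real_)
    data.frame(interval = k, n = nrow(d), spearman_r = r,
               mw_U = mw$U, mw_p = mw$p,
               n_high = length(hi), n_low = length(lo))
  })
  do.call(rbind, out)
}
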