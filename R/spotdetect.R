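#' Spot detector configuration
#'
#' Settings for the classical matched-filter detector used to count DARC
#' spots on en-face cSLO frames: candidates are local maxima of the
#' normalized cross-correlation with a Gaussian template, thresholded and
#' de-duplicated by greedy non-maximum suppression.
#'
#' @param template_sigma Gaussian template sigma in pixels
#' @param threshold detection threshold on the normalized correlation,
#'   in (-1, 1)
#' @param nms_radius non-maximum-suppression radius in pixels (> 0)
#' @param baseline_radius match radius (px) used when subtracting baseline
#'   autofluorescent spots
#' @return a `detector_config` list
#' @export
detector_config <- function(template_sigma = 2, threshold = 0.5,
                            nms_radius = 5, baseline_radius = 4) {
  stopifnot(nms_radius > 0, threshold > -1, threshold < 1,
            template_sigma > 0, baseline_radius > 0)
  structure(list(template_sigma = template_sigma, threshold = threshold,
                 nms_radius = nms_radius, baseline_radius = baseline_radius),
            class = "detector_config")
}

# 2D convolution (same size, zero-padded) via FFT
conv2_fft <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  PH <- H + kh - 1; PW <- W + kw - 1
  A <- matrix(0, PH, PW); A[1:H, 1:W] <- img
  K <- matrix(0, PH, PW); K[1:kh, 1:kw] <- kernel
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (PH * PW)
  r0 <- (kh - 1) %/% 2; c0 <- (kw - 1) %/% 2
  full[(r0 + 1):(r0 + H), (c0 + 1):(c0 + W)]
}

gaussian_template <- function(sigma) {
  r <- max(2, ceiling(3 * sigma))
  g <- outer(-r:r, -r:r, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g
}

# normalized cross-correlation of image with a zero-mean template
ncc_map <- function(img, template) {
  tz <- template - mean(template)
  tn <- sqrt(sum(tz^2))
  npix <- length(template)
  ones <- matrix(1, nrow(template), ncol(template))
  num <- conv2_fft(img, tz[rev(seq_len(nrow(tz))), rev(seq_len(ncol(tz)))])
  s1 <- conv2_fft(img, ones[, , drop = FALSE])
  s2 <- conv2_fft(img^2, ones)
  lvar <- pmax(s2 - s1^2 / npix, 0)
  den <- sqrt(lvar) * tn
  out <- num / den
  out[den < 1e-8] <- 0
  out
}

# local maxima (strictly >= all 8 neighbours, > at least one) above threshold
local_maxima <- function(score, threshold) {
  H <- nrow(score); W <- ncol(score)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- score
  ismax <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
    ismax <- ismax & (score >= nb)
  }
  idx <- which(ismax & score > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1,
             score = score[idx])
}

#' Greedy non-maximum suppression
#'
#' Keeps candidates in descending score order, suppressing any candidate
#' within `radius` of an already accepted one. Score ties are broken by
#' (y, x) lexicographic order for determinism.
#'
#' @param spots data.frame with columns x, y, score
#' @param radius suppression radius in pixels
#' @return the input rows with an `accepted` logical column
#' @export
nms <- function(spots, radius) {
  n <- nrow(spots)
  if (n == 0) return(cbind(spots, accepted = logical(0)))
  ord <- order(-spots$score, spots$y, spots$x)
  accepted <- logical(n)
  ax <- numeric(0); ay <- numeric(0)
  for (i in ord) {
    if (length(ax) == 0 ||
        all((spots$x[i] - ax)^2 + (spots$y[i] - ay)^2 >= radius^2)) {
      accepted[i] <- TRUE
      ax <- c(ax, spots$x[i]); ay <- c(ay, spots$y[i])
    }
  }
  cbind(spots, accepted = accepted)
}

#' Detect spots in an en-face intensity image
#'
#' Matched-filter detection: normalized cross-correlation with a Gaussian
#' template, local maxima above the correlation threshold, then greedy
#' non-maximum suppression. A classical stand-in for CNN-based spot
#' classification; the accepted-spot count is the DARC count input.
#'
#' @param img 2D intensity matrix (rows = y, cols = x)
#' @param cfg a [detector_config()]
#' @return a `spotset` data.frame: x, y (0-based pixel coordinates),
#'   score, accepted
#' @export
detect_spots <- function(img, cfg = detector_config()) {
  if (!is.matrix(img) || !is.numeric(img)) stop("image must be a 2D numeric matrix")
  tpl <- gaussian_template(cfg$template_sigma)
  score <- ncc_map(img, tpl)
  cand <- local_maxima(score, cfg$threshold)
  out <- nms(cand, cfg$nms_radius)
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spotset", "data.frame")
  out
}

accepted_xy <- function(s) {
  if (is.null(s$accepted)) as.matrix(s[, c("x", "y"), drop = FALSE])
  else as.matrix(s[s$accepted, c("x", "y"), drop = FALSE])
}

#' Greedy nearest-neighbour spot matching
#'
#' One-to-one matching of two spot sets: candidate pairs within `radius`
#' are accepted greedily by increasing distance, each spot used at most
#' once.
#'
#' @param a,b spot data.frames with x, y columns (and optionally an
#'   `accepted` flag, in which case only accepted spots are matched)
#' @param radius maximum pairing distance in pixels (> 0)
#' @return list with `pairs` (data.frame ia, ib, dist: row indices into
#'   the accepted spots of a and b), `unmatched_a`, `unmatched_b`
#' @export
match_spots <- function(a, b, radius) {
  if (radius <= 0) stop("radius must be positive")
  pa <- accepted_xy(a); pb <- accepted_xy(b)
  na <- nrow(pa); nb <- nrow(pb)
  if (na == 0 || nb == 0)
    return(list(pairs = data.frame(ia = integer(0), ib = integer(0), dist = numeric(0)),
                unmatched_a = seq_len(na), unmatched_b = seq_len(nb)))
  d <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  cand <- which(d <= radius, arr.ind = TRUE)
  pairs <- data.frame(ia = integer(0), ib = integer(0), dist = numeric(0))
  if (nrow(cand) > 0) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_a <- logical(na); used_b <- logical(nb)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pairs <- rbind(pairs, data.frame(ia = i, ib = j, dist = d[i, j]))
      }
    }
  }
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(na), pairs$ia),
       unmatched_b = setdiff(seq_len(nb), pairs$ib))
}

#' Subtract baseline autofluorescent spots from a DARC spot set
#'
#' Spots already visible on the pre-injection autofluorescence image are
#' not injected-probe signal; any DARC spot within `radius` of a baseline
#' autofluorescent spot is removed.
#'
#' @param darc spot data.frame (x, y, ... ; accepted flag honoured)
#' @param autofluorescent baseline spot data.frame
#' @param radius exclusion radius in pixels
#' @return the DARC spots with baseline-matched spots removed
#' @export
subtract_baseline <- function(darc, autofluorescent, radius) {
  keep_rows <- if (is.null(darc$accepted)) seq_len(nrow(darc)) else which(darc$accepted)
  d <- darc[keep_rows, , drop = FALSE]
  pb <- accepted_xy(autofluorescent)
  if (nrow(pb) == 0 || nrow(d) == 0) { rownames(d) <- NULL; return(d) }
  dm <- sqrt(outer(d$x, pb[, 1], "-")^2 + outer(d$y, pb[, 2], "-")^2)
  keep <- apply(dm, 1, function(r) all(r > radius))
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DARC count of a spot set
#'
#' Number of accepted spots (after baseline autofluorescence subtraction);
#' the eye-level biomarker thresholded at > 5 in the survival analysis.
#'
#' @param s spot data.frame
#' @return integer count
#' @export
darc_count <- function(s) {
  if (is.null(s) || nrow(s) == 0) return(0L)
  if (is.null(s$accepted)) nrow(s) else sum(s$accepted)
}
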