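#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between two binary raters (e.g. clinical
#' grading of subretinal fluid vs automated OCT segmentation).
#' kappa = (po - pe) / (1 - pe), where po is the observed agreement
#' proportion and pe the agreement expected from the marginal rates.
#'
#' @param a count with both raters positive
#' @param b count with rater 1 positive only
#' @param c count with rater 2 positive only
#' @param d count with both raters negative
#' @return a list with `kappa` (NA when pe = 1, i.e. degenerate margins),
#'   `po`, `pe` and `n`
#' @examples
#' cohens_kappa(8, 3, 2, 16)  # ~0.627
#' @export
cohens_kappa <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("agreement counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop("agreement table is empty")
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_ else (po - pe) / (1 - pe)
  list(kappa = kappa, po = po, pe = pe, n = n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param x,y numeric vectors of equal length, n >= 3
#' @return correlation coefficient, or NA when either variable has zero
#'   rank variance (all values tied)
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For groups of at most `exact_max` observations
#' each the p-value is computed by full enumeration of all assignments of
#' the pooled mid-ranks to the two groups (exact even under ties); larger
#' samples use the normal approximation with tie correction.
#'
#' @param x,y numeric vectors (non-empty)
#' @param exact_max per-group size limit for the enumeration branch
#' @return list with `U` (for the first group), `p` (two-sided) and
#'   `method` ("exact" or "normal")
#' @export
mann_whitney <- function(x, y, exact_max = 10) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    # enumerate all choose(n1+n2, n1) assignments of ranks to group 1
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  nt <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
  sigma2 <- n1 * n2 / 12 * (nt + 1 - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  # continuity-corrected normal deviate (U is lattice-valued)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped. For at most `exact_max` nonzero pairs the
#' two-sided p-value is exact, enumerating all 2^m sign patterns of the
#' ranked absolute differences (so m uniformly signed pairs give
#' p = 2 / 2^m); larger samples use the normal approximation with tie
#' correction.
#'
#' @param d numeric vector of paired differences
#' @param exact_max nonzero-pair limit for the enumeration branch
#' @return list with `W` (positive-rank sum), `n` (nonzero pairs), `p`
#'   (two-sided; NA when every difference is zero) and `method`
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 12) {
  d <- d[is.finite(d)]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(list(W = NA_real_, n = 0L, p = NA_real_, method = "degenerate"))
  r <- rank(abs(d), ties.method = "average")
  W <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  if (m <= exact_max) {
    # all 2^m sign patterns; distribution of the positive-rank sum
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    w_all <- as.vector(signs %*% r)
    p <- mean(abs(w_all - mu) >= abs(W - mu) - 1e-9)
    return(list(W = W, n = m, p = p, method = "exact"))
  }
  ties <- table(abs(d))
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  list(W = W, n = m, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

# closed-form simple OLS: returns intercept, slope, R2, residual SS
ols_fit <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points per series")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("degenerate x variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ssr <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  list(intercept = intercept, slope = slope, r2 = r2, ssr = ssr, n = length(x))
}

#' Compare regression slopes of two series
#'
#' Fits ordinary least squares to each (x, y) series and tests whether the
#' slopes differ, via the group-by-x interaction term of the pooled
#' two-line model (t test on the interaction coefficient).
#'
#' @param x1,y1 first series (>= 3 points)
#' @param x2,y2 second series (>= 3 points)
#' @return list with per-series `slope`, `intercept`, `r2`, the slope
#'   difference, its standard error, t statistic, df and two-sided `p`
#' @export
linreg_compare <- function(x1, y1, x2, y2) {
  f1 <- ols_fit(x1, y1)
  f2 <- ols_fit(x2, y2)
  n1 <- f1$n; n2 <- f2$n
  df <- n1 + n2 - 4
  s2 <- (f1$ssr + f2$ssr) / df            # pooled residual variance
  se <- sqrt(s2 * (1 / sum((x1 - mean(x1))^2) + 1 / sum((x2 - mean(x2))^2)))
  diff <- f1$slope - f2$slope
  tstat <- if (se > 0) diff / se else ifelse(diff == 0, 0, Inf)
  p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df) else 0
  list(
    slope1 = f1$slope, intercept1 = f1$intercept, r2_1 = f1$r2,
    slope2 = f2$slope, intercept2 = f2$intercept, r2_2 = f2$r2,
    slope_diff = diff, se = se, t = tstat, df = df, p = p
  )
}
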