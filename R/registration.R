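#' Fit a 2D affine transform from fiducial point pairs
#'
#' Least-squares fit of the 2x3 matrix `[A | t]` mapping source fiducials
#' onto target fiducials, as used to bring en-face cSLO frames and the OCT
#' reflectance image into a common coordinate system. With exactly three
#' non-collinear pairs the fit is exact (zero residual).
#'
#' @param src,dst n x 2 matrices (columns x, y; 0-based pixel centres) of
#'   corresponding points, n >= 3
#' @return an `affine2d` object: 2 x 3 matrix, row i giving the
#'   coefficients of output coordinate i in (x, y, 1)
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst) || ncol(src) != 2 || ncol(dst) != 2)
    stop("src and dst must be n x 2 matrices of equal row count")
  n <- nrow(src)
  if (n < 3) stop("degenerate configuration: need at least 3 fiducial pairs")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3) stop("degenerate configuration: source fiducials are collinear")
  # normal equations; rank already checked
  coef <- solve(crossprod(X), crossprod(X, dst))  # 3 x 2
  m <- t(coef)                                    # 2 x 3, rows = (x', y')
  structure(m, class = "affine2d")
}

#' Apply a 2D affine transform to points
#'
#' @param t an `affine2d` 2 x 3 matrix
#' @param p point(s): length-2 vector or n x 2 matrix (x, y)
#' @return transformed points, same shape as input
#' @export
apply_affine <- function(t, p) {
  vec <- is.null(dim(p))
  p <- rbind2cols(p)
  out <- cbind(p, 1) %*% t(unclass(t))
  colnames(out) <- c("x", "y")
  if (vec) drop(out) else out
}

rbind2cols <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
}

#' Invert a 2D affine transform
#'
#' @param t an `affine2d` 2 x 3 matrix with non-singular linear part
#' @return the inverse `affine2d`
#' @export
invert_affine <- function(t) {
  A <- unclass(t)[, 1:2, drop = FALSE]
  b <- unclass(t)[, 3]
  if (abs(det(A)) <= 1e-12) stop("affine transform is singular")
  Ai <- solve(A)
  structure(cbind(Ai, -Ai %*% b), class = "affine2d")
}

#' OCT volume geometry descriptor
#'
#' Describes how the en-face fundus footprint of an OCT volume maps to
#' (slice index, B-scan column). Slices are parallel horizontal B-scans:
#' slice s sits on fundus row `y0 + s * dy`; within a slice, fundus x maps
#' to B-scan column `(x - x0) / sx`.
#'
#' @param n_slices number of B-scans in the volume (>= 1)
#' @param y0 fundus row (px) of slice 0
#' @param dy inter-slice spacing in fundus pixels (> 0)
#' @param x0 fundus x of B-scan column 0
#' @param sx fundus pixels per B-scan column (> 0)
#' @param n_cols number of columns per B-scan
#' @param depth number of axial rows per B-scan image
#' @return an `oct_geometry` list
#' @export
oct_geometry <- function(n_slices, y0, dy, x0 = 0, sx = 1, n_cols = 512, depth = 32) {
  stopifnot(n_slices >= 1, dy > 0, sx > 0, n_cols >= 1, depth >= 1)
  structure(list(n_slices = as.integer(n_slices), y0 = y0, dy = dy,
                 x0 = x0, sx = sx, n_cols = as.integer(n_cols),
                 depth = as.integer(depth)),
            class = "oct_geometry")
}

#' Map a registered fundus point to OCT (slice, column)
#'
#' Nearest-slice lookup with ties broken toward the lower slice index;
#' column by per-slice scale, rounded to the nearest integer (half away
#' from zero would be ambiguous, so ties also resolve downward).
#'
#' @param p point (x, y) in the registered fundus frame, or n x 2 matrix
#' @param g an [oct_geometry()]
#' @return data.frame with integer columns `slice` and `col` (0-based)
#' @export
fundus_to_oct <- function(p, g) {
  p <- rbind2cols(p)
  x <- p[, 1]; y <- p[, 2]
  s_real <- (y - g$y0) / g$dy
  slice <- floor(s_real + 0.5)
  # tie exactly halfway between slices -> lower index
  tie <- abs(s_real - (floor(s_real) + 0.5)) < 1e-9
  slice[tie] <- floor(s_real[tie])
  c_real <- (x - g$x0) / g$sx
  col <- floor(c_real + 0.5)
  ctie <- abs(c_real - (floor(c_real) + 0.5)) < 1e-9
  col[ctie] <- floor(c_real[ctie])
  bad <- slice < 0 | slice >= g$n_slices | col < 0 | col >= g$n_cols
  if (any(bad))
    stop(sprintf("point outside OCT volume footprint: (%g, %g)",
                 x[which(bad)[1]], y[which(bad)[1]]))
  data.frame(slice = as.integer(slice), col = as.integer(col))
}

#' Serialize / deserialize an affine transform as JSON
#'
#' Row-major 2 x 3 coefficient list.
#' @param t an `affine2d`
#' @param path file path
#' @export
write_affine_json <- function(t, path) {
  jsonlite::write_json(list(matrix = as.vector(t(unclass(t)))), path,
                       auto_unbox = TRUE, digits = NA)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)$matrix
  structure(matrix(m, nrow = 2, byrow = TRUE), class = "affine2d")
}
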