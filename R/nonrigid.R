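# Cubic B-spline kernel (support [-2, 2], partition of unity on a uniform grid)
bspline3 <- function(t) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at < 1
  i2 <- at >= 1 & at < 2
  w[i1] <- (4 - 6 * at[i1]^2 + 3 * at[i1]^3) / 6
  w[i2] <- (2 - at[i2])^3 / 6
  w
}

# basis matrix mapping control-point values (spacing h, padded grid) to
# sample positions pos (0-based pixel coordinates along one axis)
bspline_basis <- function(pos, n_px, h) {
  # control points at -h, 0, h, ..., covering [0, n_px-1] with one pad each side
  k0 <- -1L
  k1 <- as.integer(ceiling((n_px - 1) / h)) + 1L
  ks <- k0:k1
  B <- outer(pos, ks * h, function(p, c) bspline3((p - c) / h))
  B
}

# bilinear sampling of image `img` at (row, col) positions (0-based, matrices
# same shape); out-of-bounds clamped to the border
bilinear_sample <- function(img, rr, cc) {
  H <- nrow(img); W <- ncol(img)
  rr <- pmin(pmax(rr, 0), H - 1)
  cc <- pmin(pmax(cc, 0), W - 1)
  r0 <- pmin(floor(rr), H - 2); r1 <- r0 + 1
  c0 <- pmin(floor(cc), W - 2); c1 <- c0 + 1
  fr <- rr - r0; fc <- cc - c0
  i00 <- r0 + 1 + H * c0; i10 <- r1 + 1 + H * c0
  i01 <- r0 + 1 + H * c1; i11 <- r1 + 1 + H * c1
  v <- img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
  matrix(v, nrow = H)
}

# central-difference gradients of an image (rows = y, cols = x)
image_gradients <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gy <- img; gx <- img
  gy[2:(H - 1), ] <- (img[3:H, ] - img[1:(H - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]; gy[H, ] <- img[H, ] - img[H - 1, ]
  gx[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]; gx[, W] <- img[, W] - img[, W - 1]
  list(gx = gx, gy = gy)
}

# 2x block-mean downsampling (odd trailing row/col dropped)
downsample2 <- function(img) {
  H <- 2 * (nrow(img) %/% 2); W <- 2 * (ncol(img) %/% 2)
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  (img[seq(1, H, 2), seq(1, W, 2)] + img[seq(2, H, 2), seq(1, W, 2)] +
     img[seq(1, H, 2), seq(2, W, 2)] + img[seq(2, H, 2), seq(2, W, 2)]) / 4
}

# warp the moving image by displacement fields (ux, uy in pixels):
# sampled at x + u(x)
warp_by_field <- function(moving, ux, uy) {
  H <- nrow(moving); W <- ncol(moving)
  cc <- matrix(rep(0:(W - 1), each = H), nrow = H)
  rr <- matrix(rep(0:(H - 1), W), nrow = H)
  bilinear_sample(moving, rr + uy, cc + ux)
}

mse <- function(a, b) mean((a - b)^2)

# single-resolution B-spline gradient descent on the MSE; returns control
# offsets (list tx, ty) and convergence flag
refine_level <- function(fixed, moving, h, theta_x, theta_y, max_iter, tol) {
  H <- nrow(fixed); W <- ncol(fixed)
  Br <- bspline_basis(0:(H - 1), H, h)   # H  x Kr
  Bc <- bspline_basis(0:(W - 1), W, h)   # W  x Kc
  field <- function(tx, ty) list(ux = Br %*% tx %*% t(Bc), uy = Br %*% ty %*% t(Bc))
  objective <- function(tx, ty) {
    f <- field(tx, ty)
    mse(warp_by_field(moving, f$ux, f$uy), fixed)
  }
  cur <- objective(theta_x, theta_y)
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f <- field(theta_x, theta_y)
    warped <- warp_by_field(moving, f$ux, f$uy)
    resid <- warped - fixed
    g <- image_gradients(warped)
    # dL/dtheta = (2/N) * Br' (resid * grad) Bc
    gx_t <- 2 / (H * W) * crossprod(Br, (resid * g$gx)) %*% Bc
    gy_t <- 2 / (H * W) * crossprod(Br, (resid * g$gy)) %*% Bc
    gn <- sqrt(sum(gx_t^2) + sum(gy_t^2))
    if (gn < 1e-12) { converged <- TRUE; break }
    # backtracking line search: accept only improving steps, so the
    # objective never rises above its initialization
    improved <- FALSE
    s <- step
    for (ls in 1:20) {
      nx <- theta_x - s / gn * gx_t
      ny <- theta_y - s / gn * gy_t
      val <- objective(nx, ny)
      if (val < cur - 1e-15) {
        theta_x <- nx; theta_y <- ny
        if (cur - val < tol * max(cur, 1e-12)) converged <- TRUE
        cur <- val
        step <- s * 2
        improved <- TRUE
        break
      }
      s <- s / 2
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  list(tx = theta_x, ty = theta_y, mse = cur, converged = converged)
}

#' Non-rigid B-spline refinement of an affine pre-alignment
#'
#' Multi-resolution (3 levels: 4x, 2x, 1x downsampling) free-form
#' deformation: a dense displacement field is parameterised as the cubic
#' B-spline interpolation of offsets on a uniform control-point grid and
#' optimised by gradient descent with a backtracking line search on the
#' mean squared intensity difference. Only improving steps are taken, so
#' the final objective never exceeds the affine-initialised one.
#'
#' @param fixed,moving 2D intensity matrices of identical shape; `moving`
#'   is expected to already be resampled through the affine transform
#' @param grid_spacing control-point spacing in pixels at full resolution
#' @param max_iter gradient-descent iteration cap per resolution level
#' @param tol relative objective-decrease convergence tolerance
#' @return a `displacement_field` list: `ux`, `uy` (pixel offsets, same
#'   shape as the images), `mse_before`, `mse_after`, and `converged`
#'   (FALSE means the iteration cap was hit; the best-so-far field is
#'   still returned)
#' @export
nonrigid_refine <- function(fixed, moving, grid_spacing = 16, max_iter = 60,
                            tol = 1e-6) {
  if (!is.matrix(fixed) || !is.matrix(moving)) stop("images must be 2D matrices")
  if (!all(dim(fixed) == dim(moving))) stop("images must have the same shape")
  mse0 <- mse(moving, fixed)
  levels <- list()
  f <- fixed; m <- moving
  scales <- c(1, 2, 4)
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (i in 2:3) { pyr_f[[i]] <- downsample2(pyr_f[[i - 1]]); pyr_m[[i]] <- downsample2(pyr_m[[i - 1]]) }
  theta_x <- theta_y <- NULL
  converged <- TRUE
  for (lev in 3:1) {
    fl <- pyr_f[[lev]]; ml <- pyr_m[[lev]]
    h <- max(grid_spacing / scales[lev], 2)
    Kr <- length(seq.int(-1L, as.integer(ceiling((nrow(fl) - 1) / h)) + 1L))
    Kc <- length(seq.int(-1L, as.integer(ceiling((ncol(fl) - 1) / h)) + 1L))
    if (is.null(theta_x)) {
      tx <- matrix(0, Kr, Kc); ty <- matrix(0, Kr, Kc)
    } else {
      # resample previous level's control offsets onto this level's grid
      tx <- resize_theta(theta_x * 2, Kr, Kc)
      ty <- resize_theta(theta_y * 2, Kr, Kc)
    }
    res <- refine_level(fl, ml, h, tx, ty, max_iter, tol)
    theta_x <- res$tx; theta_y <- res$ty
    converged <- converged && res$converged
  }
  H <- nrow(fixed); W <- ncol(fixed)
  h <- max(grid_spacing, 2)
  Br <- bspline_basis(0:(H - 1), H, h)
  Bc <- bspline_basis(0:(W - 1), W, h)
  ux <- Br %*% theta_x %*% t(Bc)
  uy <- Br %*% theta_y %*% t(Bc)
  mse1 <- mse(warp_by_field(moving, ux, uy), fixed)
  if (mse1 > mse0) {  # safety net: never worse than initialization
    ux <- matrix(0, H, W); uy <- matrix(0, H, W); mse1 <- mse0
  }
  if (!converged) warning("nonrigid_refine: iteration cap reached; returning best-so-far field")
  structure(list(ux = ux, uy = uy, mse_before = mse0, mse_after = mse1,
                 converged = converged),
            class = "displacement_field")
}

# bilinear resize of a control-offset matrix to a new grid size
resize_theta <- function(th, Kr, Kc) {
  if (nrow(th) == Kr && ncol(th) == Kc) return(th)
  rr <- seq(0, nrow(th) - 1, length.out = Kr)
  cc <- seq(0, ncol(th) - 1, length.out = Kc)
  bilinear_sample(th, matrix(rep(rr, Kc), nrow = Kr),
                  matrix(rep(cc, each = Kr), nrow = Kr))
}
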