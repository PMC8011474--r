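# independent brute-force oracles used to check pipeline results

# brute-force nearest-slice search: exhaustively scan all slice rows
brute_nearest_slice <- function(y, geom) {
  rows <- geom$y0 + (0:(geom$n_slices - 1)) * geom$dy
  d <- abs(rows - y)
  which(d <= min(d) + 1e-12)[1] - 1L  # tie -> lower index
}

# O(n^2) baseline-subtraction filter
brute_subtract <- function(darc, af, radius) {
  keep <- rep(TRUE, nrow(darc))
  for (i in seq_len(nrow(darc)))
    for (j in seq_len(nrow(af)))
      if (sqrt((darc$x[i] - af$x[j])^2 + (darc$y[i] - af$y[j])^2) <= radius)
        keep[i] <- FALSE
  darc[keep, , drop = FALSE]
}

# exhaustive optimal one-to-one assignment (minimum total distance) for
# small point sets; returns number of pairs within radius and the pairing
brute_assignment <- function(a, b, radius) {
  na <- nrow(a); nb <- nrow(b)
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
  d[d > radius] <- Inf
  n <- min(na, nb)
  best <- list(npairs = -1, cost = Inf, map = NULL)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  if (na <= nb) {
    for (p in perms(seq_len(nb))) {
      sel <- d[cbind(seq_len(na), p[seq_len(na)])]
      k <- sum(is.finite(sel)); cost <- sum(sel[is.finite(sel)])
      if (k > best$npairs || (k == best$npairs && cost < best$cost))
        best <- list(npairs = k, cost = cost, map = p[seq_len(na)])
    }
  } else {
    for (p in perms(seq_len(na))) {
      sel <- d[cbind(p[seq_len(nb)], seq_len(nb))]
      k <- sum(is.finite(sel)); cost <- sum(sel[is.finite(sel)])
      if (k > best$npairs || (k == best$npairs && cost < best$cost))
        best <- list(npairs = k, cost = cost, map = p[seq_len(nb)])
    }
  }
  best
}

# brute-force spot-over-SRF check: scan every mask pixel
brute_overlies <- function(spot, masks, geom, tol_slices, tol_cols) {
  sc <- fundus_to_oct(spot, geom)
  for (s in seq_along(masks)) {
    if (abs((s - 1) - sc$slice) > tol_slices) next
    idx <- which(masks[[s]] != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    if (any(abs((idx[, 2] - 1) - sc$col) <= tol_cols)) return(TRUE)
  }
  FALSE
}

# ---- null-association Monte-Carlo oracle -----------------------------------
# Independent re-implementation of the documented generative model and
# unique-spot classification, with direct per-spot/per-lesion geometry
# (no occupancy grids), used to compute the chance-level PPV when spots
# and lesions are unlinked (association_strength = 0).
null_ppv_oracle <- function(cfg, n_sims, tol_slices = 1, tol_cols = 10,
                            baseline_radius = 4) {
  nI <- cfg$n_intervals
  margin <- 16
  y0 <- margin
  dy <- (cfg$image_size - 2 * margin) / (cfg$slices_per_volume - 1)
  pad <- 24
  # continuous chord of a lesion on slice s at interval k (NULL if absent)
  chord <- function(les, k, s) {
    if (k < les$onset) return(NULL)
    g <- 1 + cfg$lesion_growth * (if (les$onset < 0) k + 1 else k - les$onset)
    ys <- y0 + s * dy
    rel <- (ys - les$cy) / (cfg$lesion_ay * g)
    if (abs(rel) > 1) return(NULL)
    half <- cfg$lesion_ax * g * sqrt(1 - rel^2)
    c(ceiling(les$cx - half), floor(les$cx + half))
  }
  overlaps <- function(x, y, lesions, k) {
    sl <- round((y - y0) / dy)
    col <- round(x)
    for (les in lesions) {
      for (s in max(0, sl - tol_slices):min(cfg$slices_per_volume - 1, sl + tol_slices)) {
        ch <- chord(les, k, s)
        if (!is.null(ch) && ch[1] <= col + tol_cols && ch[2] >= col - tol_cols)
          return(TRUE)
      }
    }
    FALSE
  }
  ppvs <- numeric(0)
  for (sim in seq_len(n_sims)) {
    tp <- 0; fp <- 0
    for (e in seq_len(cfg$n_eyes)) {
      n_sp <- stats::rpois(1, cfg$spot_count_mean) + stats::rpois(1, cfg$nuisance_spot_mean)
      n_af <- stats::rpois(1, cfg$autofluorescent_spot_mean)
      sx <- stats::runif(n_sp, pad, cfg$image_size - 1 - pad)
      sy <- stats::runif(n_sp, y0, y0 + (cfg$slices_per_volume - 1) * dy)
      ax <- stats::runif(n_af, pad, cfg$image_size - 1 - pad)
      ay <- stats::runif(n_af, y0, y0 + (cfg$slices_per_volume - 1) * dy)
      if (n_sp > 0 && n_af > 0) {
        keep <- vapply(seq_len(n_sp), function(i)
          all(sqrt((sx[i] - ax)^2 + (sy[i] - ay)^2) > baseline_radius), logical(1))
        sx <- sx[keep]; sy <- sy[keep]
      }
      lesions <- list()
      base <- stats::runif(1) < cfg$baseline_srf_fraction
      n_les <- stats::rpois(1, cfg$spontaneous_lesion_mean)
      if (n_les > 0) for (k in seq_len(n_les))
        lesions[[length(lesions) + 1]] <- list(
          cx = stats::runif(1, pad, cfg$image_size - 1 - pad),
          cy = stats::runif(1, y0, y0 + (cfg$slices_per_volume - 1) * dy),
          onset = sample(0:(nI - 1), 1))
      if (base)
        lesions[[length(lesions) + 1]] <- list(
          cx = stats::runif(1, pad, cfg$image_size - 1 - pad),
          cy = stats::runif(1, y0, y0 + (cfg$slices_per_volume - 1) * dy),
          onset = -1L)
      onsets <- vapply(lesions, function(l) l$onset, numeric(1))
      pos <- vapply(0:(nI - 1), function(k) any(onsets <= k), logical(1))
      new_srf <- logical(nI); prev <- base
      for (k in seq_len(nI)) { new_srf[k] <- pos[k] && !prev; prev <- pos[k] }
      # per-spot first-overlap interval (baseline overlap -> excluded)
      first <- rep(NA_integer_, length(sx))
      for (i in seq_along(sx)) {
        if (base && overlaps(sx[i], sy[i], lesions[onsets < 0], -1L)) next
        for (k in 0:(nI - 1)) {
          if (overlaps(sx[i], sy[i], lesions, k)) { first[i] <- k; break }
        }
      }
      for (k in 0:(nI - 1)) {
        uc <- sum(first == k, na.rm = TRUE)
        if (uc > 0 && new_srf[k + 1]) tp <- tp + 1
        else if (uc > 0 && !new_srf[k + 1]) fp <- fp + 1
      }
    }
    if (tp + fp > 0) ppvs <- c(ppvs, tp / (tp + fp))
  }
  list(mean = mean(ppvs), se = stats::sd(ppvs) / sqrt(length(ppvs)),
       n = length(ppvs))
}
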