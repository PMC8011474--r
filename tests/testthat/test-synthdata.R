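test_that("config validation names the offending field", {
  expect_error(cohort_config(spot_count_mean = -1), "spot_count_mean")
  expect_error(cohort_config(association_strength = 1.5), "association_strength")
  expect_error(cohort_config(months_followup = 35), "interval_length")
})

test_that("empty cohorts and seed determinism behave as contracts", {
  empty <- generate_cohort(cohort_config(n_eyes = 0, seed = 1))
  expect_equal(nrow(empty$visits), 0)
  expect_equal(nrow(empty$spots), 0)
  expect_equal(length(empty$truth), 0)
  c1 <- generate_cohort(small_cohort(99))
  c2 <- generate_cohort(small_cohort(99))
  expect_identical(c1, c2)
  c3 <- generate_cohort(small_cohort(100))
  expect_false(identical(c1$spots, c3$spots))
})

test_that("planted spot labels conserve the per-class counts", {
  co <- generate_cohort(small_cohort(41))
  for (e in co$truth) {
    tab <- table(factor(e$spots$label,
                        c("angiogenic", "nuisance", "autofluorescent")))
    expect_equal(nrow(e$spots), sum(tab))
  }
  expect_equal(nrow(co$spots),
               sum(vapply(co$truth, function(e) nrow(e$spots), numeric(1))))
})

test_that("full association plants a spot inside every future lesion footprint", {
  cfg <- small_cohort(42, association_strength = 1, nuisance_spot_mean = 0,
                      baseline_srf_fraction = 0, spontaneous_lesion_mean = 0)
  co <- generate_cohort(cfg)
  geom <- co$geometry
  converters <- Filter(function(e) !is.na(e$conversion_interval), co$truth)
  expect_gt(length(converters), 0)
  for (e in converters) {
    k <- e$conversion_interval
    occ <- darcsrf:::runs_occupancy(darcsrf:::eye_srf_runs(e, k, geom, cfg), geom)
    inside <- vapply(seq_len(nrow(e$spots)), function(i) {
      sc <- fundus_to_oct(c(e$spots$x[i], e$spots$y[i]), geom)
      occ[[sc$slice + 1]][sc$col + 1]
    }, logical(1))
    expect_true(any(inside))
  }
})

test_that("rendered images have the stated background and spot closed forms", {
  cfg <- cohort_config(image_size = 64, background_level = 20,
                       background_noise_sd = 8, seed = 1)
  set.seed(43)
  bg <- render_fundus_image(data.frame(x = numeric(0), y = numeric(0)), cfg)
  se <- 8 / sqrt(length(bg))
  expect_lt(abs(mean(bg) - 20), 3 * se)
  cfg0 <- cohort_config(image_size = 64, background_level = 20,
                        background_noise_sd = 0, spot_amplitude = 100,
                        seed = 1)
  one <- render_fundus_image(data.frame(x = 30, y = 22), cfg0)
  expect_equal(which(one == max(one), arr.ind = TRUE)[1, ],
               c(row = 23, col = 31))
  expect_equal(max(one), 120)  # amplitude + background at the centre
  expect_error(render_fundus_image(data.frame(x = 99, y = 5), cfg0), "bounds")
})

test_that("planted spots at SNR 10 are recovered by the detector", {
  cfg <- cohort_config(image_size = 128, spot_amplitude = 100,
                       background_noise_sd = 10, seed = 1)
  set.seed(44)
  pts <- plant_min_sep(20, 8, 119, 12)
  img <- render_fundus_image(as.data.frame(pts), cfg)
  det <- detect_spots(img)
  m <- match_spots(as.data.frame(pts), det, radius = 1)
  expect_gte(nrow(m$pairs), 18)
})

test_that("SRF mask series respect onset, growth and planted footprints", {
  cfg <- cohort_config(image_size = 128, slices_per_volume = 25, seed = 1)
  geom <- synth_geometry(cfg)
  none <- list(eye_id = "e", spots = data.frame(), lesions = list(),
               baseline_srf = FALSE)
  for (v in generate_srf_series(none, cfg))
    expect_equal(sum(vapply(v$masks, sum, numeric(1))), 0)
  # onset at interval 3: empty strictly before, nonempty from 3
  les <- list(cx = 64, cy = 64, ax = 15, ay = 10, onset = 3L, kind = "seeded")
  eye <- list(eye_id = "e", lesions = list(les), baseline_srf = FALSE)
  series <- generate_srf_series(eye, cfg)
  sums <- vapply(series, function(v) sum(vapply(v$masks, sum, numeric(1))),
                 numeric(1))
  iv <- vapply(series, `[[`, numeric(1), "interval")
  expect_true(all(sums[iv < 3] == 0))
  expect_true(all(sums[iv >= 3] > 0))
  expect_true(all(diff(sums[iv >= 3]) >= 0))  # growth: non-decreasing
  # planted 500-px footprint in one slice: thin lesion centred on a slice row
  g <- synth_geometry(cfg)
  cy <- g$y0 + 10 * g$dy
  thin <- list(cx = 64, cy = cy, ax = 62.2, ay = g$dy / 4, onset = 0L)
  eye2 <- list(eye_id = "e", lesions = list(thin), baseline_srf = FALSE)
  cfg0 <- cohort_config(image_size = 128, slices_per_volume = 25,
                        lesion_growth = 0, lesion_thickness = 4, seed = 1)
  v0 <- generate_srf_series(eye2, cfg0, visit_dates = 3)[[1]]
  per_slice <- vapply(v0$masks, sum, numeric(1))
  expect_equal(sum(per_slice > 0), 1)       # a single slice intersected
  expect_equal(per_slice[11], 125 * 4)      # 125 columns x 4 axial rows = 500
})

test_that("at zero association, spot-over-lesion overlap sits at chance level", {
  # fraction of converting eyes with an angiogenic spot inside their lesion
  # footprint at conversion, vs an independent Monte-Carlo chance oracle
  cfg <- small_cohort(45, n_eyes = 200, association_strength = 0,
                      spontaneous_lesion_mean = 1, baseline_srf_fraction = 0,
                      nuisance_spot_mean = 0, autofluorescent_spot_mean = 0)
  co <- generate_cohort(cfg)
  geom <- co$geometry
  conv <- Filter(function(e) !is.na(e$conversion_interval) && nrow(e$spots) > 0,
                 co$truth)
  hit <- vapply(conv, function(e) {
    occ <- darcsrf:::runs_occupancy(
      darcsrf:::eye_srf_runs(e, e$conversion_interval, geom, cfg), geom)
    any(vapply(seq_len(nrow(e$spots)), function(i) {
      sc <- fundus_to_oct(c(e$spots$x[i], e$spots$y[i]), geom)
      occ[[sc$slice + 1]][sc$col + 1]
    }, logical(1)))
  }, logical(1))
  frac <- mean(hit)
  # chance oracle: uniform spots vs uniform lesions present at the eye's
  # first onset, slice/column discretization done directly
  set.seed(46)
  nsim <- 2000
  pad <- 24
  ys <- geom$y0 + (0:(geom$n_slices - 1)) * geom$dy
  spot_in_lesion <- function(sx, sy, cx, cy) {
    sl <- round((sy - geom$y0) / geom$dy)
    col <- round(sx)
    rel <- (ys[sl + 1] - cy) / cfg$lesion_ay
    if (abs(rel) > 1) return(FALSE)
    half <- cfg$lesion_ax * sqrt(1 - rel^2)
    col >= ceiling(cx - half) && col <= floor(cx + half)
  }
  hits <- vapply(seq_len(nsim), function(s) {
    n_sp <- stats::rpois(1, cfg$spot_count_mean)
    m <- stats::rpois(1, cfg$spontaneous_lesion_mean)
    if (n_sp == 0 || m == 0) return(NA)  # condition: converting eye with spots
    sx <- stats::runif(n_sp, pad, cfg$image_size - 1 - pad)
    sy <- stats::runif(n_sp, geom$y0, geom$y0 + (geom$n_slices - 1) * geom$dy)
    onsets <- sample(0:(cfg$n_intervals - 1), m, replace = TRUE)
    present <- which(onsets == min(onsets))  # lesions alive at conversion
    cx <- stats::runif(m, pad, cfg$image_size - 1 - pad)
    cy <- stats::runif(m, geom$y0, geom$y0 + (geom$n_slices - 1) * geom$dy)
    any(vapply(seq_along(sx), function(i)
      any(vapply(present, function(l)
        spot_in_lesion(sx[i], sy[i], cx[l], cy[l]), logical(1))), logical(1)))
  }, NA)
  chance <- mean(hits, na.rm = TRUE)
  se <- sqrt(frac * (1 - frac) / length(hit) +
               chance * (1 - chance) / sum(!is.na(hits)))
  expect_lt(abs(frac - chance), 3 * se)
})
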