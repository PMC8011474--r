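test_that("spot-over-SRF check matches the brute-force window search", {
  g <- oct_geometry(n_slices = 20, y0 = 10, dy = 5, n_cols = 128, depth = 16)
  masks <- replicate(20, matrix(0L, 16, 128), simplify = FALSE)
  expect_false(spot_overlies_srf(c(64, 50), masks, g))  # all empty
  masks[[9]][5:8, 60:70] <- 1L  # slice 8, columns 59-69 (0-based)
  expect_true(spot_overlies_srf(c(64, 10 + 8 * 5), masks, g, 0, 0))
  set.seed(61)
  for (i in 1:100) {
    p <- c(stats::runif(1, 0, 127), stats::runif(1, 10, 10 + 19 * 5))
    expect_equal(spot_overlies_srf(p, masks, g, 1, 10),
                 brute_overlies(p, masks, g, 1, 10))
  }
})

test_that("unique spots follow baseline-exclusion and first-occurrence rules", {
  g <- oct_geometry(n_slices = 10, y0 = 0, dy = 10, n_cols = 100, depth = 8)
  occ_at <- function(cols_by_slice) {
    occ <- replicate(10, logical(100), simplify = FALSE)
    for (s in names(cols_by_slice)) occ[[as.integer(s)]][cols_by_slice[[s]]] <- TRUE
    occ
  }
  empty <- occ_at(list())
  # spot A over baseline SRF; spot B overlaps at intervals 2 and 3 only
  spots <- data.frame(x = c(20, 70), y = c(30, 50))
  base_occ <- occ_at(list(`4` = 15:25))               # covers spot A
  occ2 <- occ_at(list(`6` = 65:75))                   # covers spot B
  us <- unique_spots(spots, list(empty, empty, occ2, occ2), base_occ, g,
                     tol_slices = 1, tol_cols = 5)
  expect_equal(us, data.frame(spot = 2L, interval = 2L))
  # construction: 3 spots seeding one lesion appearing at interval 1
  cfg <- cohort_config(image_size = 128, slices_per_volume = 25, seed = 1)
  geom <- synth_geometry(cfg)
  sp <- data.frame(x = c(60, 64, 68), y = rep(geom$y0 + 12 * geom$dy, 3))
  les <- list(cx = 64, cy = geom$y0 + 12 * geom$dy, ax = 15, ay = 10, onset = 1L)
  eye <- list(eye_id = "e", lesions = list(les), baseline_srf = FALSE)
  occ <- lapply(0:5, function(k) darcsrf:::runs_occupancy(
    darcsrf:::eye_srf_runs(eye, k, geom, cfg), geom))
  b0 <- darcsrf:::runs_occupancy(darcsrf:::eye_srf_runs(eye, -1L, geom, cfg), geom)
  us2 <- unique_spots(sp, occ, b0, geom)
  expect_equal(nrow(us2), 3)
  expect_true(all(us2$interval == 1))
})

test_that("eye-interval classification follows the decision rule exactly", {
  expect_equal(classify_eye_interval(2, TRUE), "TP")
  expect_equal(classify_eye_interval(0, TRUE), "FN")
  expect_equal(classify_eye_interval(3, FALSE), "FP")
  expect_equal(classify_eye_interval(0, FALSE), "TN")
  expect_error(classify_eye_interval(NA, TRUE), "defined")
})

test_that("predictive metrics match brute-force recounts and flag undefined", {
  # recount: 27 labelled eyes -> PPV 0.714, sens 0.833, spec 0.905, NPV 0.950
  labels <- rep(c("TP", "FP", "FN", "TN"), c(5, 2, 1, 19))
  m <- confusion_metrics(sum(labels == "TP"), sum(labels == "FP"),
                         sum(labels == "FN"), sum(labels == "TN"))
  expect_equal(round(m$ppv, 3), 0.714)
  expect_equal(round(m$sensitivity, 3), 0.833)
  expect_equal(round(m$specificity, 3), 0.905)
  expect_equal(round(m$npv, 3), 0.950)
  allTN <- confusion_metrics(0, 0, 0, 10)
  expect_equal(allTN$specificity, 1)
  expect_true(is.na(allTN$sensitivity))
  oneTP <- confusion_metrics(1, 0, 0, 0)
  expect_equal(oneTP$ppv, 1)
  expect_equal(oneTP$sensitivity, 1)
  expect_true(is.na(oneTP$specificity))
  expect_true(is.na(oneTP$npv))
  expect_error(confusion_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("survival curves count at-risk eyes per DARC group, hand-checked", {
  mk <- function(id, darc, baseline, conv, n_int = 4) {
    amounts <- c(if (baseline) 100 else 0,
                 ifelse(seq_len(n_int) - 1 >= conv, 100, 0))
    build_timeline(id, c(0, (seq_len(n_int) - 0.5) * 6), amounts, n_int,
                   darc_count = darc)
  }
  # 4 high-count eyes with conversions at intervals 1 and 3
  tls <- list(mk("a", 9, FALSE, 1), mk("b", 8, FALSE, 3),
              mk("c", 7, FALSE, Inf), mk("d", 10, FALSE, Inf),
              mk("e", 2, FALSE, Inf), mk("f", 3, FALSE, Inf))
  s <- srf_free_survival(tls, darc_threshold = 5)
  hi <- s$proportion[s$group == "high"]
  expect_equal(hi, c(1, 0.75, 0.75, 0.5))
  lo <- s$proportion[s$group == "low"]
  expect_equal(lo, rep(1, 4))
  expect_true(all(diff(hi) <= 0))
  # no conversions anywhere -> both curves constant 1
  none <- list(mk("a", 9, FALSE, Inf), mk("b", 2, FALSE, Inf))
  s0 <- srf_free_survival(none)
  expect_true(all(s0$proportion == 1))
  # baseline-positive eyes are excluded from the at-risk sets
  tls2 <- c(tls, list(mk("g", 9, TRUE, Inf)))
  expect_equal(srf_free_survival(tls2)$n_at_risk,
               s$n_at_risk)
})

test_that("group comparison tests behave on identical and separated curves", {
  surv <- data.frame(interval = rep(0:3, 2),
                     group = rep(c("high", "low"), each = 4),
                     proportion = rep(c(1, 0.8, 0.6, 0.5), 2))
  same <- compare_groups(surv)
  expect_equal(same$wilcoxon$p, 1)
  expect_equal(same$regression$slope_diff, 0)
  surv2 <- data.frame(interval = rep(0:2, 2),
                      group = rep(c("high", "low"), each = 3),
                      proportion = c(1, 0.5, 0.25, 1, 1, 1))
  sep <- compare_groups(surv2)
  expect_lt(sep$regression$slope1, 0)
  expect_equal(sep$regression$slope2, 0)
  # exact signed-rank p vs base R oracle on small curves
  set.seed(62)
  hi <- c(0.99, 0.9, 0.7, 0.5, 0.4, 0.3)
  lo <- c(1, 0.95, 0.9, 0.88, 0.85, 0.8)
  surv3 <- data.frame(interval = rep(0:5, 2),
                      group = rep(c("high", "low"), each = 6),
                      proportion = c(hi, lo))
  res <- compare_groups(surv3)
  ref <- stats::wilcox.test(hi, lo, paired = TRUE, exact = TRUE)
  expect_equal(res$wilcoxon$p, unname(ref$p.value))
})

test_that("spot-SRF association recovers monotone links and splits groups", {
  df <- data.frame(interval = 0, unique_count = 1:8,
                   accum_srf = c(100, 300, 800, 1500, 2500, 3000, 4000, 5000))
  a <- spot_srf_association(df, split_threshold = 2000)
  expect_equal(a$spearman_r, 1)
  expect_equal(a$n_high, 4)
  expect_equal(a$n_low, 4)
  expect_lt(a$mw_p, 0.05)
  df$unique_count <- 8:1
  expect_equal(spot_srf_association(df)$spearman_r, -1)
  # n = 8 toy pair vs the rank formula computed directly
  set.seed(63)
  df2 <- data.frame(interval = 0, unique_count = sample(0:5, 8, replace = TRUE),
                    accum_srf = stats::runif(8, 0, 4000))
  r <- spot_srf_association(df2)$spearman_r
  expect_equal(r, suppressWarnings(
    stats::cor(df2$unique_count, df2$accum_srf, method = "spearman")))
  # all-tied counts -> undefined correlation, flagged as NA
  df3 <- data.frame(interval = 0, unique_count = rep(2, 5),
                    accum_srf = stats::runif(5))
  expect_true(is.na(spot_srf_association(df3)$spearman_r))
})
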