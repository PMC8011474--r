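test_that("visit SRF amount is the pixel sum over slices", {
  empty <- replicate(3, matrix(0L, 12, 60), simplify = FALSE)
  expect_equal(visit_srf_amount(empty), 0)
  m <- empty
  m[[1]][1:10, 1:10] <- 1L
  m[[2]][1, 1:50] <- 1L
  expect_equal(visit_srf_amount(m), 150)
  set.seed(51)
  rnd <- replicate(4, matrix(stats::rbinom(128, 1, 0.3), 8, 16), simplify = FALSE)
  loop_count <- 0
  for (s in rnd) for (i in seq_len(nrow(s))) for (j in seq_len(ncol(s)))
    loop_count <- loop_count + (s[i, j] != 0)
  expect_equal(visit_srf_amount(rnd), loop_count)
  expect_error(visit_srf_amount(list()), "no masks")
  bad <- list(matrix(0, 4, 4), matrix(0, 5, 4))
  expect_error(visit_srf_amount(bad), "shape")
})

test_that("accumulated SRF is the per-scan average, stable under duplication", {
  expect_equal(interval_accumulated_srf(c(100, 50, 0)), 50)
  expect_equal(interval_accumulated_srf(rep(c(100, 50, 0), 2)), 50)
  expect_true(is.na(interval_accumulated_srf(numeric(0))))
  # uneven visits: scans of 200, 180 and 60 px -> (200+180+60)/3
  expect_equal(interval_accumulated_srf(c(200, 180, 60)), 440 / 3)
})

test_that("SRF positivity obeys the threshold and the sweep is monotone", {
  expect_false(srf_positive(0, 0))
  expect_true(srf_positive(1, 0))
  expect_true(is.na(srf_positive(NA_real_)))
  set.seed(52)
  vals <- stats::rpois(40, 500)
  counts <- vapply(seq(0, 2000, by = 100), function(th)
    sum(vapply(vals, srf_positive, logical(1), min_pixels = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("conversion is the first newly positive interval, once only", {
  mk <- function(baseline, statuses) {
    # statuses as per-interval amounts: 0 = negative, 100 = positive
    amounts <- c(if (baseline) 100 else 0, ifelse(statuses, 100, 0))
    dates <- c(0, (seq_along(statuses) - 0.5) * 6)
    build_timeline("e", dates, amounts, length(statuses))
  }
  expect_equal(detect_conversion(mk(FALSE, c(FALSE, FALSE, TRUE, TRUE))), 2L)
  expect_true(is.na(detect_conversion(mk(TRUE, c(TRUE, TRUE, TRUE, TRUE)))))
  # clears and recurs: first time only
  expect_equal(detect_conversion(mk(FALSE, c(FALSE, TRUE, FALSE, TRUE))), 1L)
  tl <- mk(FALSE, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(tl$intervals$new_srf, c(FALSE, TRUE, FALSE, TRUE))
  expect_true(all(tl$intervals$srf_pos[tl$intervals$new_srf]))  # new => positive
})

test_that("scan-free intervals carry the previous status forward, flagged", {
  # visits only at baseline and intervals 0 and 3; 1-2 have no scans
  tl <- build_timeline("e", c(0, 3, 21), c(0, 150, 0), 4)
  expect_equal(tl$intervals$n_scans, c(1L, 0L, 0L, 1L))
  expect_equal(tl$intervals$carried, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(tl$intervals$srf_pos, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(detect_conversion(tl), 0L)
})

test_that("cumulative conversion rate counts at-risk eyes and is monotone", {
  mk <- function(baseline, conv, n_int = 6) {
    amounts <- c(if (baseline) 100 else 0,
                 ifelse(seq_len(n_int) - 1 >= conv, 100, 0))
    build_timeline("e", c(0, (seq_len(n_int) - 0.5) * 6), amounts, n_int)
  }
  none <- lapply(1:5, function(i) mk(FALSE, Inf))
  expect_equal(conversion_rate(none, 5), 0)
  # 8 converters among 24 at-risk eyes -> 33.3%
  tls <- c(lapply(1:8, function(i) mk(FALSE, 2)),
           lapply(1:16, function(i) mk(FALSE, Inf)),
           lapply(1:5, function(i) mk(TRUE, Inf)))  # baseline-positive excluded
  expect_equal(round(conversion_rate(tls, 5), 1), 33.3)
  rates <- vapply(0:5, function(k) conversion_rate(tls, k), numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_warning(conversion_rate(lapply(1:3, function(i) mk(TRUE, Inf)), 5),
                 "at-risk")
})

test_that("precision-recall pools pixels and reports the curve identities", {
  t1 <- matrix(0, 3, 3); t1[1, 1:2] <- 1
  p_perfect <- list(t1)
  pr <- precision_recall(list(t1 * 1.0), list(t1))
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  expect_equal(pr$f1, 1)
  # 3x3 toy: truth 2 px, prediction 3 px with 2 overlapping
  p1 <- matrix(0, 3, 3); p1[1, 1:2] <- 1; p1[3, 3] <- 1
  pr2 <- precision_recall(list(p1), list(t1))
  expect_equal(pr2$precision, 2 / 3)
  expect_equal(pr2$recall, 1)
  # F1 identity at every operating point
  set.seed(53)
  prob <- matrix(stats::runif(400), 20, 20)
  tru <- matrix(stats::rbinom(400, 1, 0.3), 20, 20)
  pr3 <- precision_recall(list(prob), list(tru))
  ok <- stats::complete.cases(pr3$curve)
  expect_equal(pr3$curve$f1[ok],
               2 * pr3$curve$precision[ok] * pr3$curve$recall[ok] /
                 (pr3$curve$precision[ok] + pr3$curve$recall[ok]))
  expect_true(pr3$auc >= 0 && pr3$auc <= 1)
  expect_warning(precision_recall(list(p1), list(matrix(0, 3, 3))),
                 "no positive truth")
  expect_error(precision_recall(list(matrix(0, 2, 2)), list(t1)), "shapes")
})

test_that("the printed precision/recall pair gives F1 0.80", {
  expect_equal(round(f1_score(0.89, 0.72), 2), 0.80)
  expect_true(is.na(f1_score(0, 0)))
})
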