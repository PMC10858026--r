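test_that("thresholding is inclusive and validates its input", {
  plane <- rbind(c(1, 5), c(3, 9))
  expect_identical(apply_threshold(plane, 4), rbind(c(FALSE, TRUE),
                                                    c(FALSE, TRUE)))
  expect_true(all(apply_threshold(plane, 0)))          # counts are >= 0
  expect_false(any(apply_threshold(matrix(0, 3, 3), 1)))
  expect_identical(apply_threshold(plane, 5)[1L, 2L], TRUE)   # inclusive
  expect_identical(apply_threshold(plane, 5, inclusive = FALSE)[1L, 2L],
                   FALSE)
  expect_error(apply_threshold(plane, -1), "non-negative")
})

test_that("automatic thresholds match quantile and exhaustive-Otsu oracles", {
  set.seed(21)
  roi <- matrix(TRUE, 10L, 10L)

  # 90% zeros / 10% high: quantile(0.95) sits at the high mode and calls
  # exactly the planted 10% positive
  plane <- matrix(0, 10L, 10L)
  plane[sample(100L, 10L)] <- 100
  t_q <- auto_threshold(plane, roi, "quantile", q = 0.95)
  expect_gt(t_q, 0)
  expect_identical(sum(apply_threshold(plane, t_q)), 10L)

  # bimodal 0/1000: Otsu separates the classes exactly
  bim <- matrix(0, 10L, 10L)
  bim[sample(100L, 30L)] <- 1000
  t_o <- auto_threshold(bim, roi, "otsu")
  expect_identical(unname(apply_threshold(bim, t_o)), bim == 1000)

  # random planes: histogram Otsu equals the exhaustive-search oracle
  for (rep in 1:20) {
    v <- matrix(sample(0:30, 64L, replace = TRUE), 8L, 8L)
    r <- matrix(sample(c(TRUE, FALSE), 64L, TRUE, prob = c(.8, .2)), 8L, 8L)
    if (length(unique(v[r])) < 2L) next
    expect_equal(auto_threshold(v, r, "otsu"), oracle_otsu(v[r]))
  }

  # constant plane falls back to max + 1 with a warning
  expect_warning(t_c <- auto_threshold(matrix(7, 5L, 5L), matrix(TRUE, 5, 5)),
                 "constant")
  expect_identical(t_c, 8)
  expect_false(any(apply_threshold(matrix(7, 5L, 5L), t_c)))
  expect_error(auto_threshold(plane, matrix(FALSE, 10, 10)), "empty")
})

test_that("ROI metrics match a brute-force per-pixel oracle exactly", {
  panel <- small_panel()
  ts <- threshold_set(rep("*", 3L), panel$marker_name, c(20, 10, 25))
  set.seed(33)
  for (rep in 1:5) {
    st <- random_stack(panel, 64L, 64L)
    roi <- matrix(runif(64 * 64) > 0.3, 64L, 64L)
    got <- roi_metrics(st, roi, ts)
    for (i in 1:3) {
      want <- oracle_plane_metrics(st$pixels[, , i], roi,
                                   get_threshold(ts, "s1",
                                                 panel$marker_name[i]))
      expect_identical(got$positive_fraction[i], want$positive_fraction)
      expect_identical(got$mean_intensity[i], want$mean_intensity)
      expect_identical(got$positive_mean_intensity[i],
                       want$positive_mean_intensity)
    }
  }
})

test_that("ROI metrics handle the degenerate positive sets", {
  panel <- small_panel()
  st <- channel_stack(array(5L, dim = c(5L, 5L, 3L)), panel)
  roi <- matrix(TRUE, 5L, 5L)
  roi[1L, 1L] <- FALSE  # 24-pixel ROI

  all_pos <- roi_metrics(st, roi, threshold_set(rep("*", 3L),
                                                panel$marker_name,
                                                rep(0, 3L)))
  expect_identical(all_pos$positive_fraction, rep(100, 3L))
  expect_identical(all_pos$positive_mean_intensity, all_pos$mean_intensity)

  none <- roi_metrics(st, roi, threshold_set(rep("*", 3L),
                                             panel$marker_name,
                                             rep(6, 3L)))
  expect_identical(none$positive_fraction, rep(0, 3L))
  expect_true(all(is.na(none$positive_mean_intensity)))

  expect_error(roi_metrics(st, matrix(FALSE, 5L, 5L),
                           threshold_set("*", "MarkerA", 1)), "empty")

  # 6 of 25 pixels at/above threshold -> 24%
  px <- array(0L, dim = c(5L, 5L, 3L))
  px[1:6] <- 9L
  st2 <- channel_stack(px, panel)
  m <- roi_metrics(st2, matrix(TRUE, 5L, 5L),
                   threshold_set(rep("*", 3L), panel$marker_name,
                                 c(9, 9, 9)))
  expect_identical(m$positive_fraction[1L], 24)
})

test_that("positive fraction is monotone in the threshold", {
  set.seed(55)
  plane <- matrix(sample(0:40, 400L, replace = TRUE), 20L, 20L)
  roi <- matrix(TRUE, 20L, 20L)
  fr <- vapply(0:42, function(t) 100 * sum(plane[roi] >= t) / sum(roi),
               numeric(1L))
  expect_true(all(diff(fr) <= 0))
  expect_identical(fr[1L], 100)
  expect_identical(fr[length(fr)], 0)
})

test_that("metrics on a union of disjoint ROIs are the area-weighted mean", {
  panel <- small_panel()
  set.seed(77)
  st <- random_stack(panel, 32L, 32L)
  ts <- threshold_set(rep("*", 3L), panel$marker_name, c(10, 20, 30))
  a <- matrix(FALSE, 32L, 32L); a[, 1:10] <- TRUE
  b <- matrix(FALSE, 32L, 32L); b[, 20:32] <- TRUE
  ma <- roi_metrics(st, a, ts); mb <- roi_metrics(st, b, ts)
  mu <- roi_metrics(st, a | b, ts)
  wa <- mask_area(a); wb <- mask_area(b)
  expect_equal(mu$positive_fraction,
               (wa * ma$positive_fraction + wb * mb$positive_fraction) /
                 (wa + wb))
  expect_equal(mu$mean_intensity,
               (wa * ma$mean_intensity + wb * mb$mean_intensity) /
                 (wa + wb))
})

test_that("object density normalizes by ROI area in mm^2", {
  roi <- matrix(TRUE, 500L, 1000L)  # 5e5 um^2
  expect_identical(object_density(50L, roi), 100)
  expect_identical(object_density(0L, roi), 0)
  half <- roi; half[, 501:1000] <- FALSE
  expect_identical(object_density(50L, half), 200)
  expect_error(object_density(1L, matrix(FALSE, 2L, 2L)), "empty")
  expect_error(object_density(-1L, roi), ">= 0")
})

test_that("threshold tables resolve per sample with wildcard fallback", {
  ts <- rbind(threshold_set("s1", "MarkerA", 5),
              threshold_set("*", "MarkerA", 9),
              threshold_set("*", "MarkerB", 2))
  expect_identical(get_threshold(ts, "s1", "MarkerA"), 5)
  expect_identical(get_threshold(ts, "s2", "MarkerA"), 9)
  expect_identical(get_threshold(ts, "s1", "MarkerB"), 2)
  expect_error(get_threshold(ts, "s1", "MarkerC"), "no threshold")
  expect_error(threshold_set("s1", "MarkerA", -1), ">= 0")
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = "s1", marker_name = "MarkerA",
                       threshold = 4), f, row.names = FALSE)
  rt <- read_thresholds(f)
  expect_identical(rt$provenance, "manual")
  expect_identical(get_threshold(rt, "s1", "MarkerA"), 4)
})
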