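test_that("a clean fiber lattice is segmented to its known geometry", {
  lat <- generate_lattice_section(noise = FALSE)
  fib <- segment_fibers(lat$laminin, lat$roi)
  expect_identical(fib$n_fibers, 16L)
  areas <- tabulate(fib$labels[fib$labels > 0L])
  expect_true(all(abs(areas - 1600) <= 160))  # within 10% of 40x40 um^2
  # all labels away from the frame border (margin + exclude_border)
  expect_false(any(fib$labels[c(1L, nrow(fib$labels)), ] > 0L))
})

test_that("segmentation is deterministic and labels are raster-ordered", {
  lat <- generate_lattice_section(seed = 3)
  f1 <- segment_fibers(lat$laminin, lat$roi)
  f2 <- segment_fibers(lat$laminin, lat$roi)
  expect_identical(f1$labels, f2$labels)
  first_px <- vapply(seq_len(f1$n_fibers),
                     function(id) which(f1$labels == id)[1L], integer(1L))
  expect_true(all(diff(first_px) > 0L))
})

test_that("an all-zero laminin channel yields no fibers", {
  roi <- matrix(TRUE, 60L, 60L)
  fib <- suppressWarnings(segment_fibers(matrix(0L, 60L, 60L), roi))
  expect_identical(fib$n_fibers, 0L)
  expect_identical(stroma_mask(roi, fib), roi)
})

test_that("fiber and stroma pixels partition the ROI exactly", {
  lat <- generate_lattice_section(seed = 5)
  roi <- lat$roi
  fib <- segment_fibers(lat$laminin, roi)
  st <- stroma_mask(roi, fib)
  expect_identical(mask_area(st) + mask_area((fib$labels > 0L) & roi),
                   mask_area(roi))
  expect_false(any(st & fib$labels > 0L))
})

test_that("fiber recovery degrades monotonically with noise amplitude", {
  rates <- vapply(c(0.2, 60, 110), function(bg) {
    lat <- generate_lattice_section(signal = 150, background = bg, seed = 9)
    fib <- suppressWarnings(segment_fibers(lat$laminin, lat$roi))
    recovery_stats(lat$labels, fib$labels)$match_rate
  }, numeric(1L))
  expect_true(all(diff(rates) <= 0))
  expect_identical(rates[1L], 1)
})

test_that("cell detection applies size and nucleus gates", {
  mk <- matrix(FALSE, 40L, 40L); nuc <- matrix(FALSE, 40L, 40L)
  centers <- list(c(8L, 8L), c(8L, 30L), c(30L, 8L))
  for (ct in centers) {  # 5x5 squares under 2x2 nuclei
    mk[ct[1L] + (-2:2), ct[2L] + (-2:2)] <- TRUE
    nuc[ct[1L] + 0:1, ct[2L] + 0:1] <- TRUE
  }
  p <- segmentation_params(cell_min_area_um2 = 10, cell_max_area_um2 = 100)
  cells <- detect_cells(mk, nuc, p)
  expect_identical(nrow(cells), 3L)
  expect_true(all(cells$area_um2 == 25))
  expect_equal(sort(cells$centroid_x), sort(vapply(centers, `[`, 0L, 2L)) - 0.5)

  # no nuclei -> nothing counted, rejects logged
  none <- detect_cells(mk, matrix(FALSE, 40L, 40L), p)
  expect_identical(nrow(none), 0L)
  expect_identical(attr(none, "rejected")$reason, rep("no_nucleus", 3L))

  # an oversized smear is rejected as diffuse signal
  smear <- matrix(FALSE, 120L, 120L)
  smear[10:110, 10:110] <- TRUE
  nuc2 <- matrix(FALSE, 120L, 120L); nuc2[50L, 50L] <- TRUE
  big <- detect_cells(smear, nuc2, segmentation_params())
  expect_identical(nrow(big), 0L)
  expect_identical(attr(big, "rejected")$reason, "diffuse_signal")

  expect_identical(nrow(detect_cells(matrix(FALSE, 5L, 5L),
                                     matrix(FALSE, 5L, 5L), p)), 0L)
})

test_that("macrophages split into M2 and non-M2 by CD206 overlap", {
  mk <- matrix(FALSE, 20L, 100L); nuc <- matrix(FALSE, 20L, 100L)
  for (k in 0:4) {
    mk[8:12, (k * 20 + 5):(k * 20 + 9)] <- TRUE
    nuc[10L, k * 20 + 7L] <- TRUE
  }
  p <- segmentation_params(cell_min_area_um2 = 10)
  cd68 <- detect_cells(mk, nuc, p)
  expect_identical(nrow(cd68), 5L)
  cd206 <- matrix(FALSE, 20L, 100L)
  cd206[, 1:30] <- TRUE  # covers the first two cells
  res <- classify_macrophages(cd68, cd206, p)
  expect_identical(res$m2, 2L)
  expect_identical(res$non_m2, 3L)
  expect_identical(classify_macrophages(cd68, matrix(FALSE, 20L, 100L),
                                        p)$non_m2, 5L)
  expect_identical(classify_macrophages(cd68, matrix(TRUE, 20L, 100L),
                                        p)$non_m2, 0L)
})

test_that("CD31 components partition into capillaries and large vessels", {
  m <- matrix(FALSE, 60L, 200L)
  for (k in 0:9) m[10:14, (k * 18 + 5):(k * 18 + 10)] <- TRUE  # 30 um^2
  caps <- detect_capillaries(m, segmentation_params())
  expect_identical(nrow(caps), 10L)
  expect_true(all(caps$kind == "capillary"))

  m[30:55, 10:190] <- TRUE  # ~4700 um^2 vessel
  both <- detect_capillaries(m, segmentation_params())
  expect_identical(sum(both$kind == "large_vessel"), 1L)
  expect_identical(sum(both$kind == "capillary"), 10L)

  # sub-minimum specks are discarded
  sp <- matrix(FALSE, 10L, 10L); sp[5L, 5L] <- TRUE
  expect_identical(nrow(detect_capillaries(sp, segmentation_params())), 0L)
})

test_that("nearest-vessel distances match the all-pairs oracle", {
  cells <- data.frame(centroid_x = 0, centroid_y = 0)
  vessels <- data.frame(centroid_x = c(3, 10), centroid_y = c(4, 0))
  expect_identical(nearest_structure_distance(cells, vessels), 5)
  expect_identical(
    nearest_structure_distance(data.frame(centroid_x = 3, centroid_y = 4),
                               vessels), 0)
  expect_error(nearest_structure_distance(cells,
                                          vessels[0L, ]), "undefined")
  set.seed(13)
  for (rep in 1:10) {
    cl <- data.frame(centroid_x = runif(7, 0, 50),
                     centroid_y = runif(7, 0, 50))
    vs <- data.frame(centroid_x = runif(5, 0, 50),
                     centroid_y = runif(5, 0, 50))
    got <- nearest_structure_distance(cl, vs)
    want <- vapply(seq_len(7L), function(i) {
      min(sqrt((cl$centroid_x[i] - vs$centroid_x)^2 +
                 (cl$centroid_y[i] - vs$centroid_y)^2))
    }, numeric(1L))
    expect_equal(got, want)
  }
})
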