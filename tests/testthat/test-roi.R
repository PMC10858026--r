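test_that("GeoJSON import handles polygons, kinds, skips and failures", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  f <- write_geojson(list(geo_polygon_feature(sq, "r1")),
                     tempfile(fileext = ".json"))
  rs <- import_rois(f)
  expect_length(rs, 1L)
  expect_identical(rs[[1L]]$kind, "whole_section")
  expect_identical(nrow(rs[[1L]]$vertices), 4L)  # closing vertex dropped

  # kind read from the QuPath classification property
  f2 <- write_geojson(list(
    geo_polygon_feature(sq, "r1", classification = "Fibrotic focus"),
    geo_polygon_feature(sq + 20, "r2", classification = "Non-fibrotic")),
    tempfile(fileext = ".json"))
  rs2 <- import_rois(f2)
  expect_identical(vapply(rs2, function(r) r$kind, character(1L)),
                   c("fibrotic_focus", "nonfibrotic_area"))

  # point features are skipped with a warning
  pt <- list(type = "Feature", properties = list(name = "p"),
             geometry = list(type = "Point", coordinates = c(1, 1)))
  f3 <- write_geojson(list(pt, geo_polygon_feature(sq, "r1")),
                      tempfile(fileext = ".json"))
  expect_warning(rs3 <- import_rois(f3), "non-polygon")
  expect_length(rs3, 1L)

  # malformed JSON names the file
  f4 <- tempfile(fileext = ".json")
  writeLines("{not json", f4)
  expect_error(import_rois(f4), basename(f4))

  f5 <- write_geojson(list(), tempfile(fileext = ".json"))
  expect_error(import_rois(f5), "zero features")

  # MultiPolygon features split into suffixed ROIs
  mp <- list(type = "Feature", properties = list(name = "m"),
             geometry = list(
               type = "MultiPolygon",
               coordinates = list(
                 list(lapply(seq_len(nrow(sq)), function(i) sq[i, ])),
                 list(lapply(seq_len(nrow(sq)), function(i) sq[i, ] + 30)))))
  f6 <- write_geojson(list(mp), tempfile(fileext = ".json"))
  rs6 <- import_rois(f6)
  expect_identical(vapply(rs6, function(r) r$roi_id, character(1L)),
                   c("m_1", "m_2"))
})

test_that("polygon construction enforces ring validity", {
  expect_error(roi_polygon(rbind(c(0, 0), c(1, 1))), "3 distinct")
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(roi_polygon(bow), "self-intersecting")
})

test_that("rasterization follows the pixel-center convention", {
  # axis-aligned square with corners (0,0)-(2,2) on a 4x4 frame: the four
  # centers (0.5,0.5)..(1.5,1.5) are inside
  sq <- roi_polygon(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  m <- rasterize_roi(sq, c(4L, 4L))
  expect_identical(mask_area(m), 4L)
  expect_true(all(m[1:2, 1:2]))

  # polygon covering the whole frame
  big <- roi_polygon(rbind(c(-1, -1), c(5, -1), c(5, 5), c(-1, 5)))
  expect_identical(mask_area(rasterize_roi(big, c(4L, 4L))), 16L)

  # triangle (0,0),(1,0),(0,1): no center strictly inside -> empty mask
  tri <- roi_polygon(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_identical(mask_area(rasterize_roi(tri, c(4L, 4L))), 0L)

  # fully outside the frame is an error
  far <- roi_polygon(rbind(c(100, 100), c(110, 100), c(110, 110)))
  expect_error(rasterize_roi(far, c(4L, 4L)), "outside")

  # holes are subtracted
  ring <- roi_polygon(rbind(c(0, 0), c(6, 0), c(6, 6), c(0, 6)),
                      holes = list(rbind(c(2, 2), c(4, 2), c(4, 4),
                                         c(2, 4))))
  mh <- rasterize_roi(ring, c(6L, 6L))
  expect_identical(mask_area(mh), 36L - 4L)
  expect_false(mh[3L, 3L])
})

test_that("rasterization agrees with a winding-number oracle", {
  set.seed(101)
  for (rep in 1:40) {
    frame <- c(sample(8:64, 1L), sample(8:64, 1L))
    v <- random_convex_polygon(frame)
    roi <- tryCatch(roi_polygon(v), error = function(e) NULL)
    if (is.null(roi)) next
    m <- tryCatch(rasterize_roi(roi, frame), error = function(e) NULL)
    if (is.null(m)) next
    rs <- rep(seq_len(frame[1L]), times = frame[2L])
    cs <- rep(seq_len(frame[2L]), each = frame[1L])
    expected <- oracle_point_in_polygon(cs - 0.5, rs - 0.5, v)
    expect_identical(as.vector(m[cbind(rs, cs)]), expected)
  }
})

test_that("rasterized area of a rectangle is within a perimeter of truth", {
  set.seed(7)
  for (rep in 1:25) {
    x0 <- runif(1, 0, 20); y0 <- runif(1, 0, 20)
    wid <- runif(1, 10, 40); hei <- runif(1, 10, 40)
    rect <- roi_polygon(rbind(c(x0, y0), c(x0 + wid, y0),
                              c(x0 + wid, y0 + hei), c(x0, y0 + hei)))
    m <- rasterize_roi(rect, c(64L, 64L))
    expect_lte(abs(mask_area(m) - wid * hei), 2 * (wid + hei))
  }
})

test_that("mask algebra obeys set identities exactly", {
  set.seed(11)
  a <- matrix(runif(64) > 0.5, 8L, 8L)
  b <- matrix(runif(64) > 0.5, 8L, 8L)
  expect_identical(mask_subtract(a, a), matrix(FALSE, 8L, 8L))
  expect_identical(mask_subtract(a, matrix(FALSE, 8L, 8L)), a)
  expect_identical(mask_area(mask_subtract(a, b)) + mask_area(a & b),
                   mask_area(a))
  # De Morgan
  expect_identical(!(a | b), (!a) & (!b))
  expect_identical(mask_subtract(mask_subtract(a, b), b),
                   mask_subtract(a, b))  # idempotence
  expect_error(mask_subtract(a, matrix(FALSE, 4L, 4L)), "shapes differ")
})

test_that("margin erosion removes the mask rim", {
  m <- matrix(TRUE, 20L, 20L)
  e <- erode_margin(m, 3)
  expect_lt(mask_area(e), mask_area(m))
  expect_false(any(e[1:2, ]))
  expect_identical(erode_margin(m, 0), m)
})
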