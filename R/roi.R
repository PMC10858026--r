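#' Regions of interest: polygons, masks and mask algebra
#'
#' ROIs are drawn in an annotation tool (QuPath-style GeoJSON export) as
#' polygons in pixel coordinates (1 px = 1 um, x = column, y = row, origin at
#' the image's top-left corner) and rasterized to boolean masks for all
#' pixel-level metrics. A pixel belongs to a mask when its center lies
#' strictly inside the polygon under the even-odd rule; centers falling
#' exactly on an edge are resolved by the half-open crossing rule and are in
#' practice excluded. Holes (inner rings) are subtracted.
#'
#' @name roi_geometry
NULL

.roi_kinds <- c("whole_section", "fibrotic_focus", "nonfibrotic_area")

#' Construct a polygon ROI
#'
#' @param vertices n x 2 matrix (columns x, y) of ring vertices in pixel
#'   coordinates; a closing duplicate of the first vertex is dropped.
#' @param roi_id Identifier.
#' @param kind One of `whole_section`, `fibrotic_focus`, `nonfibrotic_area`.
#' @param holes Optional list of inner-ring vertex matrices to subtract.
#' @return An `roi_polygon`.
#' @export
roi_polygon <- function(vertices, roi_id = "roi", kind = "whole_section",
                        holes = list()) {
  kind <- match.arg(kind, .roi_kinds)
  norm <- function(v) {
    v <- as.matrix(v)
    stopifnot(ncol(v) == 2L)
    n <- nrow(v)
    if (n >= 2L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
    if (nrow(v) < 3L) stop("ROI ring needs at least 3 distinct vertices",
                           call. = FALSE)
    storage.mode(v) <- "double"
    colnames(v) <- c("x", "y")
    v
  }
  vertices <- norm(vertices)
  if (.ring_self_intersects(vertices)) {
    stop("ROI '", roi_id, "' ring is self-intersecting", call. = FALSE)
  }
  structure(list(roi_id = roi_id, kind = kind, vertices = vertices,
                 holes = lapply(holes, norm)),
            class = "roi_polygon")
}

# O(n^2) proper-intersection test between non-adjacent edges
.ring_self_intersects <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip adjacent (wrap) edge
    if (!length(js)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], a[i, 1], a[i, 2])
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], b[i, 1], b[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Import ROIs from a GeoJSON feature collection
#'
#' Reads a QuPath-dialect GeoJSON export: one `roi_polygon` per `Polygon`
#' feature, the kind taken from `properties.classification.name` (or a plain
#' `properties.kind`), defaulting to `whole_section`. `MultiPolygon`
#' features are split into one ROI per part, the id suffixed `_1`, `_2`, ...
#' Non-polygon geometries are skipped with a warning.
#'
#' @param path Path to a `.json`/`.geojson` file.
#' @return An `roi_set`: list of `roi_polygon`.
#' @export
import_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file does not exist: ", path,
                               call. = FALSE)
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) {
                   stop("failed to parse GeoJSON file ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else stop("not a GeoJSON Feature(Collection): ", path,
                     call. = FALSE)
  if (!length(feats)) stop("ROI file contains zero features: ", path,
                           call. = FALSE)
  rois <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    id <- f$properties$name
    if (is.null(id)) id <- f$id
    if (is.null(id)) id <- paste0("roi_", i)
    kind <- .feature_kind(f)
    if (identical(geom$type, "Polygon")) {
      rois[[length(rois) + 1L]] <- .rings_to_roi(geom$coordinates, id, kind)
    } else if (identical(geom$type, "MultiPolygon")) {
      for (j in seq_along(geom$coordinates)) {
        rois[[length(rois) + 1L]] <-
          .rings_to_roi(geom$coordinates[[j]], paste0(id, "_", j), kind)
      }
    } else {
      warning("skipping feature ", i, " with non-polygon geometry '",
              geom$type, "'", call. = FALSE)
    }
  }
  if (!length(rois)) stop("no polygon features in ", path, call. = FALSE)
  structure(rois, class = "roi_set")
}

.feature_kind <- function(f) {
  nm <- f$properties$classification$name
  if (is.null(nm)) nm <- f$properties$kind
  if (is.null(nm)) return("whole_section")
  key <- gsub("[^a-z]+", "_", tolower(nm))
  if (grepl("fibrotic_focus|^fibrotic$", key)) return("fibrotic_focus")
  if (grepl("non_?fibrotic", key)) return("nonfibrotic_area")
  "whole_section"
}

.rings_to_roi <- function(rings, id, kind) {
  mat <- function(ring) {
    do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
  }
  outer <- mat(rings[[1L]])
  holes <- lapply(rings[-1L], mat)
  roi_polygon(outer, roi_id = id, kind = kind, holes = holes)
}

# Even-odd crossing test for points (px, py) against ring v (n x 2).
# Half-open edge rule: an edge spans y in [min, max); crossings strictly to
# the right of the point are counted. Returns logical vector.
.points_in_ring <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  x1 <- v[, 1L]; y1 <- v[, 2L]
  x2 <- v[c(2:n, 1L), 1L]; y2 <- v[c(2:n, 1L), 2L]
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) next
    spans <- (py >= pmin(y1[e], y2[e])) & (py < pmax(y1[e], y2[e]))
    if (!any(spans)) next
    xi <- x1[e] + (py[spans] - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
    hit <- xi > px[spans]
    idx <- which(spans)[hit]
    inside[idx] <- !inside[idx]
  }
  inside
}

#' Rasterize a polygon ROI to a boolean mask
#'
#' Pixel `(r, c)` (1-based) is true iff its center `(c - 0.5, r - 0.5)` lies
#' inside the outer ring (even-odd rule) and outside every hole ring.
#'
#' @param roi An `roi_polygon`.
#' @param shape `c(H, W)` of the target frame in pixels.
#' @return An H x W logical matrix.
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
  v <- roi$vertices
  if (min(v[, 1L]) >= W || max(v[, 1L]) <= 0 ||
      min(v[, 2L]) >= H || max(v[, 2L]) <= 0) {
    stop("ROI '", roi$roi_id, "' lies outside the ", H, "x", W, " frame ",
         "(empty mask)", call. = FALSE)
  }
  # restrict to the bounding box to keep the test cheap on large frames
  c0 <- max(1L, floor(min(v[, 1L]) + 0.5))
  c1 <- min(W, ceiling(max(v[, 1L]) + 0.5))
  r0 <- max(1L, floor(min(v[, 2L]) + 0.5))
  r1 <- min(H, ceiling(max(v[, 2L]) + 0.5))
  mask <- matrix(FALSE, H, W)
  if (c0 <= c1 && r0 <= r1) {
    rs <- rep(r0:r1, times = c1 - c0 + 1L)
    cs <- rep(c0:c1, each = r1 - r0 + 1L)
    px <- cs - 0.5; py <- rs - 0.5
    inside <- .points_in_ring(px, py, v)
    for (h in roi$holes) inside <- inside & !.points_in_ring(px, py, h)
    mask[cbind(rs, cs)] <- inside
  }
  # a polygon that intersects the frame but captures no pixel center (e.g.
  # thinner than a pixel) rasterizes to a valid empty mask
  mask
}

#' Mask area in square micrometres
#'
#' At 1 px = 1 um^2 the area is the count of true pixels.
#' @param mask Logical matrix.
#' @export
mask_area <- function(mask) sum(mask)

#' Mask difference
#'
#' True exactly where `a` is true and `b` is false (e.g. stroma = ROI minus
#' fiber mask).
#' @param a,b Logical matrices of equal shape.
#' @export
mask_subtract <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  a & !b
}

#' Morphological erosion of a mask by a margin
#'
#' Removes `margin_um` from the mask boundary (disc structuring element);
#' used to emulate the annotator's edge exclusion on synthetic runs.
#' @param mask Logical matrix.
#' @param margin_um Margin in micrometres (pixels).
#' @export
erode_margin <- function(mask, margin_um) {
  if (margin_um <= 0) return(mask)
  k <- as.integer(ceiling(margin_um))
  kern <- EBImage::makeBrush(2L * k + 1L, shape = "disc")
  # pad with background so the frame edge erodes too
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2L * k, W + 2L * k)
  pad[(k + 1L):(k + H), (k + 1L):(k + W)] <- mask * 1
  er <- EBImage::erode(pad, kern) > 0.5
  er[(k + 1L):(k + H), (k + 1L):(k + W)]
}

#' Export a mask as a single-page 8-bit TIFF for visual inspection
#' @param mask Logical matrix.
#' @param path Output path.
#' @export
export_mask <- function(mask, path) {
  tiff::writeTIFF((mask * 1), path, bits.per.sample = 8L)
  invisible(path)
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set with", length(x), "polygon(s):\n")
  for (r in x) {
    cat(sprintf("  %s [%s], %d vertices, %d hole(s)\n", r$roi_id, r$kind,
                nrow(r$vertices), length(r$holes)))
  }
  invisible(x)
}
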