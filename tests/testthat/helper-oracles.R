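# Independent oracles and small fixtures, written deliberately differently
# from the package implementations.

# winding-number point-in-polygon (the package uses even-odd crossing
# counts); points exactly on an edge are avoided by the tests that use this
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  vapply(seq_along(px), function(i) {
    ang <- 0
    for (e in seq_len(n)) {
      a <- c(v[e, 1L] - px[i], v[e, 2L] - py[i])
      bidx <- if (e == n) 1L else e + 1L
      b <- c(v[bidx, 1L] - px[i], v[bidx, 2L] - py[i])
      ang <- ang + atan2(a[1L] * b[2L] - a[2L] * b[1L], sum(a * b))
    }
    abs(ang) > pi
  }, logical(1L))
}

# brute-force per-pixel ROI metrics for one plane
oracle_plane_metrics <- function(plane, roi, t) {
  vals <- c()
  pos <- c()
  for (r in seq_len(nrow(plane))) {
    for (c in seq_len(ncol(plane))) {
      if (roi[r, c]) {
        vals <- c(vals, plane[r, c])
        pos <- c(pos, plane[r, c] >= t)
      }
    }
  }
  list(positive_fraction = 100 * sum(pos) / length(vals),
       mean_intensity = mean(vals),
       positive_mean_intensity = if (any(pos)) mean(vals[pos]) else NA_real_)
}

# exhaustive-search Otsu over all candidate split values
oracle_otsu <- function(v) {
  cand <- sort(unique(v))[-1L]
  best <- -Inf; best_t <- cand[1L]
  for (t in cand) {
    lo <- v[v < t]; hi <- v[v >= t]
    bcv <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

# two-sample KS statistic as a sup over the pooled support
oracle_ks_D <- function(a, b) {
  sup <- sort(unique(c(a, b)))
  max(abs(vapply(sup, function(x) mean(a <= x) - mean(b <= x), numeric(1L))))
}

# per-label positive-fraction by explicit pixel loops
oracle_fiber_fractions <- function(labels, plane, t) {
  ids <- sort(unique(labels[labels > 0L]))
  out <- numeric(length(ids))
  for (k in seq_along(ids)) {
    sel <- labels == ids[k]
    out[k] <- sum(plane[sel] >= t) / sum(sel)
  }
  names(out) <- ids
  out
}

# 3-channel test panel (marker A, marker B, nuclei)
small_panel <- function() {
  as_panel(data.frame(
    marker_name = c("MarkerA", "MarkerB", "DNA"),
    metal_tag = c("141Pr", "169Tm", "191Ir"),
    channel_index = 0:2,
    target_class = c("ecm", "cell_marker", "nuclei"),
    stringsAsFactors = FALSE))
}

random_stack <- function(panel, H = 16L, W = 16L, max_count = 50L,
                         sample_id = "s1") {
  px <- array(sample(0:max_count, H * W * nrow(panel), replace = TRUE),
              dim = c(H, W, nrow(panel)))
  channel_stack(px, panel, sample_id)
}

# convex polygon from the hull of random points (always simple)
random_convex_polygon <- function(frame, n_pts = 8L) {
  x <- runif(n_pts, 0, frame[2L])
  y <- runif(n_pts, 0, frame[1L])
  h <- grDevices::chull(x, y)
  cbind(x = x[h], y = y[h])
}

write_geojson <- function(features, path) {
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  path
}

geo_polygon_feature <- function(coords, name = "roi", classification = NULL) {
  props <- list(name = name)
  if (!is.null(classification)) {
    props$classification <- list(name = classification)
  }
  list(type = "Feature", properties = props,
       geometry = list(type = "Polygon",
                       coordinates = list(lapply(seq_len(nrow(coords)),
                                                 function(i) coords[i, ]))))
}
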