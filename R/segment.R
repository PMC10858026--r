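#' Fiber segmentation and object detection
#'
#' Muscle fibers are segmented from the laminin channel with a classical,
#' fully deterministic pipeline: Gaussian smoothing, boundary thresholding
#' (Otsu within the ROI by default), connected components of the sub-boundary
#' interior as seeds, and a seeded watershed on the smoothed laminin
#' landscape restricted to sub-threshold ROI pixels. Supra-threshold laminin
#' wall pixels are never assigned to a fiber: they remain part of the stroma
#' compartment, so fiber labels estimate the fiber interior (the
#' cross-section enclosed by the laminin sheath) and the fiber/stroma
#' partition of the ROI is exact by construction.
#'
#' Cells and capillaries are detected as connected components of thresholded
#' marker masks with size gates; counted cells must additionally overlap the
#' nuclei mask.
#'
#' @name segmentation
NULL

#' Segmentation parameters
#'
#' All areas in um^2 (= pixels), lengths in um (= pixels).
#'
#' @param smooth_sigma_um Gaussian smoothing sigma for the laminin channel.
#' @param boundary_threshold `"auto"` (Otsu within the ROI) or a raw-count
#'   value applied to the smoothed laminin.
#' @param min_fiber_area_um2 Fibers below this area are dropped.
#' @param max_fiber_area_um2 Candidates above this area are returned to the
#'   background: laminin-negative stroma expanses are not fibers.
#' @param min_solidity Minimum solidity (area / convex-hull area) of a
#'   fiber candidate; myofiber cross-sections are near-convex, while
#'   laminin-negative stroma pockets are amoeboid and fall below this.
#' @param exclude_border Drop fibers touching the ROI boundary (or frame
#'   edge).
#' @param cell_min_area_um2,cell_max_area_um2 Size gate for counted cells.
#' @param capillary_min_area_um2,capillary_max_area_um2 Size range for
#'   capillaries; components above the range are classed `large_vessel`,
#'   below it discarded as noise.
#' @param nucleus_overlap_min_px Minimum overlap (pixels) between a cell
#'   component and the nuclei mask for the cell to be counted; also the
#'   overlap rule for CD206 co-positivity of macrophages.
#' @return A `seg_params` list.
#' @export
segmentation_params <- function(smooth_sigma_um = 1,
                                boundary_threshold = "auto",
                                min_fiber_area_um2 = 100,
                                max_fiber_area_um2 = 8000,
                                min_solidity = 0.8,
                                exclude_border = TRUE,
                                cell_min_area_um2 = 25,
                                cell_max_area_um2 = 500,
                                capillary_min_area_um2 = 10,
                                capillary_max_area_um2 = 300,
                                nucleus_overlap_min_px = 1) {
  stopifnot(smooth_sigma_um > 0, min_fiber_area_um2 > 0,
            max_fiber_area_um2 > min_fiber_area_um2,
            min_solidity >= 0, min_solidity <= 1,
            cell_min_area_um2 > 0, cell_min_area_um2 < cell_max_area_um2,
            capillary_min_area_um2 > 0,
            capillary_min_area_um2 < capillary_max_area_um2,
            nucleus_overlap_min_px >= 1)
  structure(list(smooth_sigma_um = smooth_sigma_um,
                 boundary_threshold = boundary_threshold,
                 min_fiber_area_um2 = min_fiber_area_um2,
                 max_fiber_area_um2 = max_fiber_area_um2,
                 min_solidity = min_solidity,
                 exclude_border = exclude_border,
                 cell_min_area_um2 = cell_min_area_um2,
                 cell_max_area_um2 = cell_max_area_um2,
                 capillary_min_area_um2 = capillary_min_area_um2,
                 capillary_max_area_um2 = capillary_max_area_um2,
                 nucleus_overlap_min_px = nucleus_overlap_min_px),
            class = "seg_params")
}

# pixels of `mask` adjacent (4-neighbourhood) to a non-mask pixel or the
# frame edge
.mask_border <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  interior <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  mask & !interior
}

# per-label area/centroid table; centroids in um with pixel (r, c) centered
# at (c - 0.5, r - 0.5)
.label_features <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx)) {
    return(data.frame(label = integer(), area_um2 = numeric(),
                      centroid_x = numeric(), centroid_y = numeric()))
  }
  H <- nrow(labels)
  lab <- labels[idx]
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  area <- as.numeric(tabulate(lab))
  keep <- which(area > 0)
  sx <- rowsum(c - 0.5, lab)[, 1L]
  sy <- rowsum(r - 0.5, lab)[, 1L]
  data.frame(label = keep, area_um2 = area[keep],
             centroid_x = as.numeric(sx) / area[keep],
             centroid_y = as.numeric(sy) / area[keep])
}

# per-label solidity: pixel count / convex hull area of pixel centers
# (shoelace), capped at 1; hull area of a digital region slightly
# underestimates, so near-convex regions score ~1
.label_solidity <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(numeric())
  H <- nrow(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  x <- (idx - 1L) %/% H + 0.5
  y <- (idx - 1L) %% H + 0.5
  out <- vapply(ids, function(id) {
    sel <- lab == id
    xs <- x[sel]; ys <- y[sel]
    if (length(xs) < 3L) return(1)
    h <- grDevices::chull(xs, ys)
    hx <- xs[h]; hy <- ys[h]
    hull <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
    if (hull <= 0) 1 else min(1, length(xs) / hull)
  }, numeric(1L))
  names(out) <- ids
  out
}

# relabel positive labels 1..n in order of first occurrence in R's
# column-major raster scan
.relabel_raster <- function(labels) {
  pos <- which(labels > 0L)
  if (!length(pos)) return(list(labels = labels, n = 0L))
  ord <- unique(labels[pos])  # first occurrence in column-major raster scan
  map <- integer(max(ord))
  map[ord] <- seq_along(ord)
  out <- labels
  out[pos] <- map[labels[pos]]
  list(labels = out, n = length(ord))
}

#' Segment muscle fibers from the laminin channel
#'
#' Deterministic pipeline: (1) Gaussian smoothing at `smooth_sigma_um`;
#' (2) boundary mask = smoothed laminin `>=` `boundary_threshold` (Otsu
#' within the ROI when `"auto"`); (3) seeds = connected components of
#' ROI minus boundary with area `>= min_fiber_area_um2`; (4) seeded
#' watershed ([EBImage::propagate()]) on the smoothed landscape over the
#' sub-threshold ROI pixels, re-absorbing pixels freed by the seed filter;
#' (5) drop fibers below `min_fiber_area_um2`; (6) optionally drop fibers
#' touching the ROI border; labels are renumbered 1..n in raster order.
#'
#' @param laminin H x W matrix: the panel's laminin channel.
#' @param roi Non-empty logical mask.
#' @param params A `seg_params` list.
#' @return A `label_map`: list with `labels` (H x W integer matrix, 0 =
#'   background/stroma), `n_fibers`, `boundary_threshold` (the value used)
#'   and `params`.
#' @export
segment_fibers <- function(laminin, roi, params = segmentation_params()) {
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  stopifnot(identical(dim(laminin), dim(roi)))
  sm <- EBImage::gblur(laminin, sigma = params$smooth_sigma_um,
                       boundary = "replicate")
  t <- params$boundary_threshold
  if (identical(t, "auto")) {
    v <- sm[roi]
    t <- if (length(unique(round(v, 6))) == 1L) max(v) + 1 else {
      # quantize to 256 bins for a stable histogram Otsu on continuous values
      b <- .otsu_counts(findInterval(v, seq(min(v), max(v),
                                            length.out = 257L)[-257L]))
      seq(min(v), max(v), length.out = 257L)[b]
    }
  }
  boundary <- roi & (sm >= t)
  interior <- roi & !boundary
  seeds <- EBImage::bwlabel(interior)
  areas <- tabulate(seeds[seeds > 0L])
  small <- which(areas < params$min_fiber_area_um2)
  if (length(small)) seeds[seeds %in% small] <- 0L
  if (!any(seeds > 0L)) {
    warning("no fibers found (boundary mask covers the ROI or all ",
            "components below min_fiber_area_um2)", call. = FALSE)
    return(structure(list(labels = matrix(0L, nrow(roi), ncol(roi)),
                          n_fibers = 0L, boundary_threshold = t,
                          params = params), class = "label_map"))
  }
  lab <- EBImage::propagate(sm, seeds = seeds, mask = interior)
  lab <- matrix(as.integer(round(lab)), nrow(roi), ncol(roi))
  # The boundary threshold is chosen low enough to keep the laminin wall
  # network connected, which bites a skirt of sub-plateau pixels off every
  # fiber. Recover the true outline by growing each label through the
  # skirt up to the wall's half-maximum contour (FWHM edge); seeded
  # propagation cannot merge labels, so wall gaps do not fuse fibers.
  if (any(boundary)) {
    t_edge <- stats::quantile(sm[boundary], 0.9, names = FALSE) / 2
    if (is.finite(t_edge) && t_edge > t) {
      grown <- EBImage::propagate(sm, seeds = lab, mask = roi & (sm < t_edge))
      lab <- matrix(as.integer(round(grown)), nrow(roi), ncol(roi))
    }
  }
  # size and shape gates after watershed: too-small fragments, oversized
  # laminin-negative expanses and amoeboid (non-convex) candidates are all
  # returned to the stroma compartment
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < params$min_fiber_area_um2 |
                  areas > params$max_fiber_area_um2)
  if (length(drop)) lab[lab %in% drop] <- 0L
  if (params$min_solidity > 0 && any(lab > 0L)) {
    sol <- .label_solidity(lab)
    bad <- as.integer(names(sol)[sol < params$min_solidity])
    if (length(bad)) lab[lab %in% bad] <- 0L
  }
  if (isTRUE(params$exclude_border)) {
    border_ids <- unique(lab[.mask_border(roi) & lab > 0L])
    if (length(border_ids)) lab[lab %in% border_ids] <- 0L
  }
  rl <- .relabel_raster(lab)
  structure(list(labels = rl$labels, n_fibers = rl$n, boundary_threshold = t,
                 params = params),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("Fiber label map:", x$n_fibers, "fibers, frame",
      paste(dim(x$labels), collapse = "x"), "px\n")
  invisible(x)
}

#' Stroma mask: the ROI minus the fiber labels
#'
#' Fiber and stroma pixels partition the ROI exactly.
#'
#' @param roi Logical mask.
#' @param fibers A `label_map` from [segment_fibers()].
#' @return Logical mask.
#' @export
stroma_mask <- function(roi, fibers) {
  mask_subtract(roi, fibers$labels > 0L)
}

#' Detect and count cells from a marker mask
#'
#' Cells are connected components (4-neighbourhood) of the thresholded
#' marker mask whose area lies within the cell size gate and which overlap
#' the nuclei mask in at least `nucleus_overlap_min_px` pixels. Components
#' failing a gate are returned in the `"rejected"` attribute (with the
#' failed gate named) for review; oversized components are flagged
#' `diffuse_signal`.
#'
#' @param marker_mask Thresholded cell-marker mask (e.g. CD56, CD68, CD206).
#' @param nuclei_mask Thresholded nuclei (DNA intercalator) mask.
#' @param params A `seg_params` list.
#' @return A `cell_set` data.frame (one row per counted cell: `cell_id`,
#'   `centroid_x`, `centroid_y`, `area_um2`, `has_nucleus`) with attributes
#'   `labels` (component matrix restricted to counted cells) and `rejected`.
#' @export
detect_cells <- function(marker_mask, nuclei_mask,
                         params = segmentation_params()) {
  stopifnot(identical(dim(marker_mask), dim(nuclei_mask)))
  comp <- EBImage::bwlabel(marker_mask)
  comp <- matrix(as.integer(comp), nrow(marker_mask))
  feats <- .label_features(comp)
  if (!nrow(feats)) {
    out <- data.frame(cell_id = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), area_um2 = numeric(),
                      has_nucleus = logical())
    attr(out, "labels") <- comp
    attr(out, "rejected") <- cbind(feats, reason = character())
    class(out) <- c("cell_set", "data.frame")
    return(out)
  }
  nuc_overlap <- rowsum(as.numeric(nuclei_mask[comp > 0L]), comp[comp > 0L])
  feats$nucleus_overlap_px <- as.numeric(nuc_overlap[as.character(feats$label), 1L])
  too_small <- feats$area_um2 < params$cell_min_area_um2
  too_big <- feats$area_um2 > params$cell_max_area_um2
  no_nuc <- feats$nucleus_overlap_px < params$nucleus_overlap_min_px
  keep <- !too_small & !too_big & !no_nuc
  reason <- ifelse(too_big, "diffuse_signal",
                   ifelse(too_small, "below_min_area", "no_nucleus"))
  rejected <- cbind(feats[!keep, , drop = FALSE],
                    reason = reason[!keep])
  kept <- feats[keep, , drop = FALSE]
  labels <- comp
  labels[!(labels %in% kept$label)] <- 0L
  out <- data.frame(cell_id = seq_len(nrow(kept)),
                    centroid_x = kept$centroid_x,
                    centroid_y = kept$centroid_y,
                    area_um2 = kept$area_um2,
                    has_nucleus = rep_len(TRUE, nrow(kept)))
  # renumber the kept components to match cell_id
  if (nrow(kept)) {
    map <- integer(max(comp))
    map[kept$label] <- seq_len(nrow(kept))
    labels[labels > 0L] <- map[labels[labels > 0L]]
  }
  attr(out, "labels") <- labels
  attr(out, "rejected") <- rejected
  class(out) <- c("cell_set", "data.frame")
  out
}

#' Classify macrophages into M2 and non-M2
#'
#' A CD68+ cell is classed M2 when its pixels overlap the thresholded CD206
#' mask in at least `nucleus_overlap_min_px` pixels, else non-M2
#' (CD68+CD206-). The independent CD206+ cell count (from [detect_cells()]
#' on the CD206 channel) is the M2 total reported by the pipeline summaries;
#' this function resolves the CD68+ subset only.
#'
#' @param cd68_cells A `cell_set` from [detect_cells()] on CD68.
#' @param cd206_mask Thresholded CD206 mask.
#' @param params A `seg_params` list.
#' @return List with integer counts `m2` and `non_m2` and logical vector
#'   `is_m2` aligned with `cd68_cells`.
#' @export
classify_macrophages <- function(cd68_cells, cd206_mask,
                                 params = segmentation_params()) {
  labels <- attr(cd68_cells, "labels")
  stopifnot(!is.null(labels), identical(dim(labels), dim(cd206_mask)))
  n <- nrow(cd68_cells)
  if (n == 0L) return(list(m2 = 0L, non_m2 = 0L, is_m2 = logical()))
  ov <- rep(0, n)
  sel <- labels > 0L
  if (any(sel)) {
    o <- rowsum(as.numeric(cd206_mask[sel]), labels[sel])
    ov[as.integer(rownames(o))] <- o[, 1L]
  }
  is_m2 <- ov >= params$nucleus_overlap_min_px
  list(m2 = sum(is_m2), non_m2 = sum(!is_m2), is_m2 = is_m2)
}

#' Detect capillaries and larger vessels from the CD31 mask
#'
#' Connected components of the thresholded CD31 mask are partitioned by
#' area: `capillary` within the capillary range, `large_vessel` above it;
#' components below the range are discarded as noise.
#'
#' @param cd31_mask Thresholded CD31 mask.
#' @param params A `seg_params` list.
#' @return Data.frame, one row per vessel: `vessel_id`, `centroid_x`,
#'   `centroid_y`, `area_um2`, `kind`.
#' @export
detect_capillaries <- function(cd31_mask, params = segmentation_params()) {
  comp <- EBImage::bwlabel(cd31_mask)
  comp <- matrix(as.integer(comp), nrow(cd31_mask))
  feats <- .label_features(comp)
  feats <- feats[feats$area_um2 >= params$capillary_min_area_um2, ,
                 drop = FALSE]
  kind <- ifelse(feats$area_um2 <= params$capillary_max_area_um2,
                 "capillary", "large_vessel")
  data.frame(vessel_id = seq_len(nrow(feats)),
             centroid_x = feats$centroid_x, centroid_y = feats$centroid_y,
             area_um2 = feats$area_um2,
             kind = if (nrow(feats)) kind else character())
}

#' Distance from each cell to its nearest vessel
#'
#' Euclidean centroid-to-centroid distance in um.
#'
#' @param cells Data.frame with `centroid_x`, `centroid_y` (e.g. a
#'   `cell_set`).
#' @param vessels Data.frame with `centroid_x`, `centroid_y` (e.g. from
#'   [detect_capillaries()]); must be non-empty.
#' @return Numeric vector, one distance per cell.
#' @export
nearest_structure_distance <- function(cells, vessels) {
  if (is.null(vessels) || nrow(vessels) == 0L) {
    stop("no vessels available; report the distance as undefined",
         call. = FALSE)
  }
  if (nrow(cells) == 0L) return(numeric())
  dx <- outer(cells$centroid_x, vessels$centroid_x, "-")
  dy <- outer(cells$centroid_y, vessels$centroid_y, "-")
  apply(sqrt(dx^2 + dy^2), 1L, min)
}
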