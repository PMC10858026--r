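#' Synthetic muscle-section generator
#'
#' Generates IMC-like pseudoimages of transverse muscle sections with full
#' ground truth, so that every pipeline stage has a recoverable target.
#' Fibers are a Voronoi mosaic carved by laminin-positive boundaries; a
#' reserved stroma region carries ECM (collagens, TE-7, PDGFRa) and
#' cytokine signal; capillaries (CD31 rings), one large vessel (CD31 +
#' aSMA), perilipin-coated fat vacuoles and nucleated marker-positive cells
#' are planted at known positions. Per-channel expected counts are
#' `background + signal * mask` and pixels are independent Poisson draws
#' (IMC pixels are ion counts), clipped to the 16-bit range at export.
#'
#' Disease-stage presets order the generated sections the way dystrophic
#' muscle progresses: stroma fraction strictly increases, capillary and
#' satellite-cell counts strictly decrease, M2 (CD206+) cell counts strictly
#' increase, and perilipin-positive area is near zero except in the
#' fat-replacement stage. The magnitudes are the generator's own choices.
#'
#' @name synthetic_data
NULL

#' Synthetic-section parameters
#'
#' @param frame `c(H, W)` in pixels (1 px = 1 um).
#' @param fiber_csa_lognormal `c(median_um2, sigma)` of the target fiber CSA
#'   distribution; the Voronoi seed density is derived from its mean.
#' @param boundary_width_um Laminin wall width between fibers.
#' @param stroma_fraction Target fraction of the frame occupied by the
#'   interstitial (non-fiber) compartment, in `[0, 1)`. The interstitium is
#'   an endomysial wall network of width `boundary_width_um` widened
#'   patchily until the target is met; values below the bare wall network's
#'   own fraction leave just the walls.
#' @param stroma_patchiness Log-scale SD of the smooth field that modulates
#'   local interstitium width (0 = uniform widening).
#' @param fat_focus List `count`, `radius_um`, `near_large_vessel`.
#' @param n_capillaries,n_satellite_cells,n_cd68_cells,n_cd206_cells Planted
#'   object counts.
#' @param large_vessel Plant one large vessel (CD31 + aSMA ring).
#' @param cell_near_vessel_prob Probability that a planted cell is placed
#'   within `near_vessel_radius_um` of a capillary rather than uniformly.
#' @param near_vessel_radius_um Radius defining "near a vessel".
#' @param myh3_fiber_frac,cd56_extra_fiber_frac Fractions of fibers painted
#'   MYH3+ (regenerating; all MYH3+ fibers are also CD56+) and additionally
#'   CD56+ only.
#' @param signal Named per-marker signal levels (expected counts on the true
#'   mask); names must match the default panel.
#' @param background Expected background counts per pixel.
#' @param seed RNG seed; identical parameters give bit-identical output.
#' @return A `synth_params` list.
#' @export
synth_params <- function(frame = c(300L, 300L),
                         fiber_csa_lognormal = c(1500, 0.35),
                         boundary_width_um = 3,
                         stroma_fraction = 0.15,
                         stroma_patchiness = 1,
                         fat_focus = list(count = 0, radius_um = 8,
                                          near_large_vessel = TRUE),
                         n_capillaries = 20,
                         n_satellite_cells = 8,
                         n_cd68_cells = 5,
                         n_cd206_cells = 5,
                         large_vessel = TRUE,
                         cell_near_vessel_prob = 0.5,
                         near_vessel_radius_um = 15,
                         myh3_fiber_frac = 0.05,
                         cd56_extra_fiber_frac = 0.05,
                         signal = NULL,
                         background = 0.2,
                         seed = 1L) {
  if (stroma_fraction < 0 || stroma_fraction >= 1) {
    stop("stroma_fraction must be in [0, 1)", call. = FALSE)
  }
  stopifnot(all(frame >= 64), boundary_width_um > 0,
            fiber_csa_lognormal[1L] > 0, fiber_csa_lognormal[2L] >= 0,
            n_capillaries >= 0, n_satellite_cells >= 0, n_cd68_cells >= 0,
            n_cd206_cells >= 0, fat_focus$count >= 0,
            cell_near_vessel_prob >= 0, cell_near_vessel_prob <= 1,
            background >= 0)
  default_signal <- c("Laminin" = 150, "Collagen I" = 120,
                      "Collagen III" = 100, "Collagen VI" = 80,
                      "TE-7" = 60, "PDGFRa" = 60, "CTGF" = 40, "PDGFA" = 40,
                      "TGFb" = 40, "Perilipin" = 100, "CD31" = 120,
                      "aSMA" = 100, "CD68" = 80, "CD206" = 80, "CD56" = 80,
                      "MYH3" = 60, "DNA" = 100)
  if (!is.null(signal)) default_signal[names(signal)] <- signal
  if (any(default_signal <= background)) {
    stop("every signal level must exceed the background", call. = FALSE)
  }
  structure(list(frame = as.integer(frame),
                 fiber_csa_lognormal = fiber_csa_lognormal,
                 boundary_width_um = boundary_width_um,
                 stroma_fraction = stroma_fraction,
                 stroma_patchiness = stroma_patchiness,
                 fat_focus = fat_focus,
                 n_capillaries = n_capillaries,
                 n_satellite_cells = n_satellite_cells,
                 n_cd68_cells = n_cd68_cells,
                 n_cd206_cells = n_cd206_cells,
                 large_vessel = isTRUE(large_vessel),
                 cell_near_vessel_prob = cell_near_vessel_prob,
                 near_vessel_radius_um = near_vessel_radius_um,
                 myh3_fiber_frac = myh3_fiber_frac,
                 cd56_extra_fiber_frac = cd56_extra_fiber_frac,
                 signal = default_signal, background = background,
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Disease-stage presets
#'
#' Presets for `control`, `mild`, `moderate`, `advanced_fibrosis` and
#' `advanced_fat`, ordered so that the true stroma fraction strictly
#' increases, capillary and satellite-cell counts strictly decrease, CD206+
#' (M2) cell counts strictly increase, and perilipin-positive area is
#' non-zero only in `advanced_fat`. In the control preset cells sit near
#' vessels with probability 0.8; in dystrophic presets 0.3.
#'
#' @param name Stage name.
#' @param frame Frame size passed through to [synth_params()].
#' @param seed RNG seed passed through.
#' @return A `synth_params` list.
#' @export
stage_preset <- function(name, frame = c(300L, 300L), seed = 1L) {
  presets <- list(
    control = list(stroma_fraction = 0.12, n_capillaries = 30,
                   n_satellite_cells = 12, n_cd68_cells = 2,
                   n_cd206_cells = 1, fat_count = 0,
                   cell_near_vessel_prob = 0.8, myh3_fiber_frac = 0.02),
    mild = list(stroma_fraction = 0.22, n_capillaries = 24,
                n_satellite_cells = 9, n_cd68_cells = 4, n_cd206_cells = 4,
                fat_count = 0, cell_near_vessel_prob = 0.3,
                myh3_fiber_frac = 0.06),
    moderate = list(stroma_fraction = 0.33, n_capillaries = 18,
                    n_satellite_cells = 7, n_cd68_cells = 6,
                    n_cd206_cells = 8, fat_count = 0,
                    cell_near_vessel_prob = 0.3, myh3_fiber_frac = 0.10),
    advanced_fibrosis = list(stroma_fraction = 0.45, n_capillaries = 12,
                             n_satellite_cells = 5, n_cd68_cells = 8,
                             n_cd206_cells = 13, fat_count = 0,
                             cell_near_vessel_prob = 0.3,
                             myh3_fiber_frac = 0.12),
    advanced_fat = list(stroma_fraction = 0.55, n_capillaries = 8,
                        n_satellite_cells = 3, n_cd68_cells = 8,
                        n_cd206_cells = 18, fat_count = 6,
                        cell_near_vessel_prob = 0.3,
                        myh3_fiber_frac = 0.12))
  if (!name %in% names(presets)) {
    stop("unknown stage '", name, "'; options: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  # planted counts are defined per 300 x 300 um^2 of section and scale
  # with the requested frame area
  ratio <- prod(frame) / (300 * 300)
  synth_params(frame = frame,
               stroma_fraction = p$stroma_fraction,
               n_capillaries = round(p$n_capillaries * ratio),
               n_satellite_cells = round(p$n_satellite_cells * ratio),
               n_cd68_cells = round(p$n_cd68_cells * ratio),
               n_cd206_cells = round(p$n_cd206_cells * ratio),
               fat_focus = list(count = round(p$fat_count * ratio),
                                radius_um = 8,
                                near_large_vessel = TRUE),
               cell_near_vessel_prob = p$cell_near_vessel_prob,
               myh3_fiber_frac = p$myh3_fiber_frac,
               seed = seed)
}

# -- geometry helpers --------------------------------------------------------

# paint TRUE on pixels whose center lies within [r_in, r_out] of (cx, cy);
# bounded-box implementation so many small objects stay cheap
.paint_annulus <- function(mask, cx, cy, r_out, r_in = 0) {
  H <- nrow(mask); W <- ncol(mask)
  c0 <- max(1L, floor(cx - r_out)); c1 <- min(W, ceiling(cx + r_out + 1))
  r0 <- max(1L, floor(cy - r_out)); r1 <- min(H, ceiling(cy + r_out + 1))
  if (c0 > c1 || r0 > r1) return(mask)
  cc <- (c0:c1) - 0.5; rr <- (r0:r1) - 0.5
  d2 <- outer((rr - cy)^2, (cc - cx)^2, "+")
  hit <- d2 <= r_out^2 & d2 >= r_in^2
  mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | hit
  mask
}

# rejection-sample n centers from `domain` (logical) keeping min separation
# from each other and from `avoid` points; error when the retry cap is hit
.place_points <- function(n, domain, min_sep, avoid = NULL,
                          what = "objects") {
  if (n == 0L) return(cbind(x = numeric(), y = numeric()))
  idx <- which(domain)
  if (!length(idx)) stop("no room to place ", what, call. = FALSE)
  H <- nrow(domain)
  pts <- matrix(numeric(), 0L, 2L)
  all_pts <- if (is.null(avoid)) pts else avoid
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > 400L * n) {
      stop("could not place ", n, " ", what,
           " without overlap; use a larger frame", call. = FALSE)
    }
    i <- idx[sample.int(length(idx), 1L)]
    x <- (i - 1L) %/% H + 1L - 0.5
    y <- (i - 1L) %% H + 1L - 0.5
    if (nrow(all_pts) &&
        min((all_pts[, 1L] - x)^2 + (all_pts[, 2L] - y)^2) < min_sep^2) next
    pts <- rbind(pts, c(x, y))
    all_pts <- rbind(all_pts, c(x, y))
  }
  colnames(pts) <- c("x", "y")
  pts
}

# -- main generator ----------------------------------------------------------

#' Generate a synthetic muscle section with ground truth
#'
#' @param params A [synth_params()] list.
#' @param panel The marker panel to bind channels to (default: the shipped
#'   panel).
#' @param sample_id Sample identifier for the emitted stack.
#' @return List with `stack` (an `imc_stack`) and `truth`: fiber `labels`,
#'   `stroma_mask` (frame complement of the labels), per-channel true
#'   positive `masks`, planted `cells`/`capillaries`/`fat` tables, `csa`
#'   list, `stroma_fraction` (true), the MYH3+/CD56+ fiber id sets and the
#'   `params` used.
#' @export
generate_section <- function(params = synth_params(),
                             panel = load_panel(),
                             sample_id = "synthetic") {
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = .GlobalEnv))
  set.seed(params$seed)

  H <- params$frame[1L]; W <- params$frame[2L]
  w <- params$boundary_width_um
  sf <- params$stroma_fraction

  # (1) Voronoi mosaic of fiber territories. Seed density targets the CSA
  # mean after subtracting the stroma share and the basal-lamina rim
  # (expected cell perimeter 4/sqrt(lambda)): solve
  # s^2 (1 - sf) - 2 w s - M = 0 for the cell pitch s.
  med <- params$fiber_csa_lognormal[1L]
  sig <- params$fiber_csa_lognormal[2L]
  target_mean <- med * exp(sig^2 / 2)
  s <- (w + sqrt(w^2 + (1 - sf) * target_mean)) / (1 - sf)
  n_seeds <- max(2L, round(H * W / s^2))
  seeds <- .place_points(n_seeds, matrix(TRUE, H, W),
                         min_sep = sqrt(target_mean) / 2,
                         what = "fiber seeds")
  colc <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  rowc <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  d1 <- matrix(Inf, H, W); d2 <- matrix(Inf, H, W)
  for (k in seq_len(nrow(seeds))) {
    d <- (colc - seeds[k, 1L])^2 + (rowc - seeds[k, 2L])^2
    closer <- d < d1
    d2 <- ifelse(closer, d1, pmin(d2, d))
    d1 <- pmin(d1, d)
  }
  edge_gap <- sqrt(d2) - sqrt(d1)  # 2 x distance to the Voronoi edge

  # (2) stroma = the interstitial network around the Voronoi edges: a base
  # endomysial wall of width w everywhere, widened patchily (fibrosis) by
  # deflating the edge gap with a smooth lognormal width field until the
  # stroma_fraction quantile is met. The network stays connected to the
  # edge skeleton, so no laminin-enclosed stroma pocket can mimic a fiber.
  # ECM/cytokine signal lives in the widened interstitium beyond the base
  # wall; at stroma_fraction 0 the interstitium reduces to the walls and
  # the ECM channels stay at background.
  walls <- edge_gap < w
  if (sf > mean(walls)) {
    g <- EBImage::gblur(matrix(stats::rnorm(H * W), H, W), sigma = 12,
                        boundary = "replicate")
    wfield <- exp(params$stroma_patchiness * g / stats::sd(g))
    u <- edge_gap / wfield
    stroma_region <- walls | (u < stats::quantile(u, sf, names = FALSE))
  } else {
    stroma_region <- walls
  }
  ecm_region <- stroma_region & !walls
  fiber_region <- !stroma_region

  # (3) laminin = basal-lamina rim of each fiber territory (width w/2),
  # plus the frame edge where territories are cut; interiors = the rest
  dm <- EBImage::distmap(fiber_region * 1)
  laminin_mask <- fiber_region & (dm <= w / 2)
  interior <- fiber_region & !laminin_mask
  labels <- EBImage::bwlabel(interior)
  labels <- matrix(as.integer(labels), H, W)
  areas <- tabulate(labels[labels > 0L])
  tiny <- which(areas < 100)
  if (length(tiny)) labels[labels %in% tiny] <- 0L
  rl <- .relabel_raster(labels)
  labels <- rl$labels
  n_fib <- rl$n
  stroma_truth <- labels == 0L
  feats <- .label_features(labels)

  # (4) fiber-level positivity: MYH3+ regenerating fibers, all CD56+;
  # extra CD56+ fibers are MYH3- (chosen before cell placement so cells
  # can be kept clear of CD56-positive fibers)
  blank <- matrix(FALSE, H, W)
  myh3_mask <- blank; cd56_fiber <- blank
  myh3_ids <- integer(); cd56_ids <- integer()
  if (n_fib > 0L) {
    n_myh3 <- round(params$myh3_fiber_frac * n_fib)
    n_extra <- round(params$cd56_extra_fiber_frac * n_fib)
    perm <- sample.int(n_fib)
    myh3_ids <- sort(perm[seq_len(min(n_myh3, n_fib))])
    cd56_ids <- sort(perm[seq_len(min(n_myh3 + n_extra, n_fib))])
    if (length(myh3_ids)) {
      myh3_mask <- matrix(labels %in% myh3_ids, H, W)
    }
    if (length(cd56_ids)) {
      cd56_fiber <- matrix(labels %in% cd56_ids, H, W)
    }
  }

  # (5) planted structures; placement domain is the non-fiber compartment
  occupied <- matrix(numeric(), 0L, 2L)
  vessel_pts <- NULL
  masks <- list()
  cd31 <- blank; asma <- blank; peri <- blank
  fat_tab <- data.frame(x = numeric(), y = numeric())
  lv <- NULL
  if (params$large_vessel) {
    margin <- blank
    margin[30:(H - 30), 30:(W - 30)] <- TRUE
    lv <- .place_points(1L, stroma_truth & margin, min_sep = 0,
                        what = "large vessel")
    cd31 <- .paint_annulus(cd31, lv[1L], lv[2L], r_out = 20, r_in = 17)
    asma <- .paint_annulus(asma, lv[1L], lv[2L], r_out = 23, r_in = 20)
    occupied <- rbind(occupied, lv)
  }
  margin <- blank
  margin[6:(H - 6), 6:(W - 6)] <- TRUE
  caps <- .place_points(params$n_capillaries, stroma_truth & margin,
                        min_sep = 12,
                        avoid = if (is.null(lv)) NULL else
                          rbind(matrix(lv, 1L, 2L) + 0),
                        what = "capillaries")
  for (k in seq_len(nrow(caps))) {
    cd31 <- .paint_annulus(cd31, caps[k, 1L], caps[k, 2L],
                           r_out = 3, r_in = 1.3)
  }
  vessel_pts <- caps
  if (params$fat_focus$count > 0) {
    dom <- stroma_truth & margin
    if (isTRUE(params$fat_focus$near_large_vessel) && !is.null(lv)) {
      near <- .paint_annulus(blank, lv[1L], lv[2L],
                             r_out = 60, r_in = 22)
      if (any(dom & near)) dom <- dom & near
    }
    fat <- .place_points(params$fat_focus$count, dom,
                         min_sep = 2 * params$fat_focus$radius_um + 2,
                         avoid = rbind(occupied, caps), what = "fat vacuoles")
    for (k in seq_len(nrow(fat))) {
      peri <- .paint_annulus(peri, fat[k, 1L], fat[k, 2L],
                             r_out = params$fat_focus$radius_um,
                             r_in = params$fat_focus$radius_um - 2)
    }
    fat_tab <- as.data.frame(fat)
    occupied <- rbind(occupied, fat)
  }

  # cells: disks (r = 4) with a nucleus dot (r = 1.6); near a capillary with
  # probability cell_near_vessel_prob, else uniform in the stroma; cells
  # keep clear of CD56+/MYH3+ fibers so no thresholded cell-marker
  # component can merge with a marker-positive fiber
  cell_domain <- stroma_truth & margin
  if (length(cd56_ids)) {
    near_pos <- EBImage::dilate(cd56_fiber * 1,
                                EBImage::makeBrush(11L, "disc")) > 0.5
    if (any(cell_domain & !near_pos)) cell_domain <- cell_domain & !near_pos
  }
  place_cells <- function(n, class) {
    if (n == 0L) return(data.frame(x = numeric(), y = numeric(),
                                   class = character()))
    dom_all <- cell_domain
    pts <- matrix(numeric(), 0L, 2L)
    for (i in seq_len(n)) {
      near <- nrow(vessel_pts) > 0L &&
        stats::runif(1L) < params$cell_near_vessel_prob
      dom <- dom_all
      if (near) {
        v <- vessel_pts[sample.int(nrow(vessel_pts), 1L), ]
        nb <- .paint_annulus(blank, v[1L], v[2L],
                             r_out = params$near_vessel_radius_um, r_in = 4)
        if (any(dom_all & nb)) dom <- dom_all & nb
      }
      p <- tryCatch(.place_points(1L, dom, min_sep = 11,
                                  avoid = rbind(occupied, pts),
                                  what = "cells"),
                    error = function(e) NULL)
      if (is.null(p)) {
        # the chosen perivascular neighbourhood is full; fall back to a
        # uniform interstitial position
        p <- .place_points(1L, dom_all, min_sep = 11,
                           avoid = rbind(occupied, pts), what = "cells")
      }
      pts <- rbind(pts, p)
    }
    occupied <<- rbind(occupied, pts)
    data.frame(x = pts[, 1L], y = pts[, 2L], class = class,
               stringsAsFactors = FALSE)
  }
  sc <- place_cells(params$n_satellite_cells, "satellite_cell")
  cd68c <- place_cells(params$n_cd68_cells, "cd68_macrophage")
  cd206c <- place_cells(params$n_cd206_cells, "cd206_macrophage")
  cells <- rbind(sc, cd68c, cd206c)
  paint_cells <- function(mask, tab, r = 4) {
    for (k in seq_len(nrow(tab))) {
      mask <- .paint_annulus(mask, tab$x[k], tab$y[k], r_out = r)
    }
    mask
  }
  cd56 <- paint_cells(blank, sc)
  cd68m <- paint_cells(blank, rbind(cd68c, cd206c))
  cd206m <- paint_cells(blank, cd206c)
  dna <- paint_cells(blank, cells, r = 1.6)
  # scattered interstitial nuclei (not attached to any counted cell)
  extra_nuc <- .place_points(round(sum(stroma_truth) / 4000),
                             stroma_truth & margin, min_sep = 8,
                             avoid = occupied, what = "interstitial nuclei")
  dna <- paint_cells(dna, as.data.frame(extra_nuc), r = 1.6)

  masks <- list("Laminin" = laminin_mask,
                "Collagen I" = ecm_region, "Collagen III" = ecm_region,
                "Collagen VI" = ecm_region, "TE-7" = ecm_region,
                "PDGFRa" = ecm_region, "CTGF" = ecm_region,
                "PDGFA" = ecm_region, "TGFb" = ecm_region,
                "Perilipin" = peri, "CD31" = cd31, "aSMA" = asma,
                "CD68" = cd68m, "CD206" = cd206m,
                "CD56" = cd56 | cd56_fiber, "MYH3" = myh3_mask,
                "DNA" = dna)

  # (6) expected counts -> Poisson draws -> 16-bit clip
  pixels <- array(0L, dim = c(H, W, n_channels(panel)))
  for (i in seq_len(n_channels(panel))) {
    m <- panel$marker_name[i]
    mk <- masks[[m]]
    if (is.null(mk)) mk <- blank
    lambda <- params$background + params$signal[[m]] * mk
    draw <- stats::rpois(H * W, lambda)
    pixels[, , i] <- matrix(pmin(draw, 65535L), H, W)
  }
  stack <- channel_stack(pixels, panel, sample_id)

  truth <- list(labels = labels, n_fibers = n_fib,
                stroma_mask = stroma_truth,
                stroma_fraction = sum(stroma_truth) / (H * W),
                masks = masks, cells = cells,
                capillaries = as.data.frame(caps),
                large_vessel = if (is.null(lv)) NULL else
                  data.frame(x = lv[1L], y = lv[2L]),
                fat = fat_tab, csa = feats$area_um2,
                myh3_fiber_ids = myh3_ids, cd56_fiber_ids = cd56_ids,
                params = params)
  list(stack = stack, truth = truth)
}

#' Default thresholds for synthetic sections
#'
#' One threshold per marker (wildcard sample `"*"`): 10 raw counts, far
#' above the Poisson background (0.2 expected counts) and far below every
#' default signal level.
#'
#' @param panel The marker panel.
#' @param value Threshold applied to every marker.
#' @return A `threshold_set`.
#' @export
synth_thresholds <- function(panel = load_panel(), value = 10) {
  threshold_set(rep("*", n_channels(panel)), panel$marker_name,
                rep(value, n_channels(panel)), provenance = "manual")
}

#' Regular fiber lattice with known geometry
#'
#' An n x n grid of square fibers separated (and surrounded) by laminin
#' walls, embedded in a signal-free margin: the sharpest possible
#' segmentation target. With `noise = TRUE` pixel values are Poisson draws
#' around `background + signal * mask`; otherwise the expected counts are
#' rounded.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param fiber_um Side of each square fiber.
#' @param wall_um Laminin wall width.
#' @param margin_um Signal-free margin around the lattice.
#' @param signal,background Laminin expected counts on/off the wall.
#' @param noise Draw Poisson noise.
#' @param seed RNG seed (used when `noise`).
#' @return List with `laminin` (H x W counts), `labels` (true fiber label
#'   matrix), `roi` (all-true mask) and `wall_mask`.
#' @export
generate_lattice_section <- function(n_rows = 4L, n_cols = 4L, fiber_um = 40L,
                                     wall_um = 3L, margin_um = 10L,
                                     signal = 150, background = 0.2,
                                     noise = TRUE, seed = 1L) {
  block_h <- n_rows * fiber_um + (n_rows + 1L) * wall_um
  block_w <- n_cols * fiber_um + (n_cols + 1L) * wall_um
  H <- block_h + 2L * margin_um; W <- block_w + 2L * margin_um
  wall <- matrix(FALSE, H, W)
  labels <- matrix(0L, H, W)
  id <- 0L
  for (j in seq_len(n_cols)) {
    for (i in seq_len(n_rows)) {
      id <- id + 1L
      r0 <- margin_um + wall_um + (i - 1L) * (fiber_um + wall_um) + 1L
      c0 <- margin_um + wall_um + (j - 1L) * (fiber_um + wall_um) + 1L
      labels[r0:(r0 + fiber_um - 1L), c0:(c0 + fiber_um - 1L)] <- id
    }
  }
  block_r <- (margin_um + 1L):(margin_um + block_h)
  block_c <- (margin_um + 1L):(margin_um + block_w)
  wall[block_r, block_c] <- labels[block_r, block_c] == 0L
  lambda <- background + signal * wall
  if (noise) {
    old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = .GlobalEnv))
    set.seed(seed)
    laminin <- matrix(pmin(stats::rpois(H * W, lambda), 65535L), H, W)
  } else {
    laminin <- matrix(as.integer(round(lambda)), H, W)
  }
  list(laminin = laminin, labels = labels, roi = matrix(TRUE, H, W),
       wall_mask = wall)
}

#' Generate a cohort of synthetic sections across all stage presets
#'
#' Seeds are derived deterministically from `base_seed`, one distinct seed
#' per sample.
#'
#' @param n_per_group Samples per stage (the five-stage design with
#'   `n_per_group = 2` mirrors a 2/2/2/2/2 cohort).
#' @param base_seed Base RNG seed.
#' @param frame Frame size per sample.
#' @param panel Marker panel.
#' @return List of per-sample lists: `sample_id`, `group`, `stack`, `truth`.
#' @export
generate_cohort <- function(n_per_group = 2L, base_seed = 1L,
                            frame = c(300L, 300L), panel = load_panel()) {
  stopifnot(n_per_group >= 1L)
  stages <- .groups
  out <- list()
  k <- 0L
  for (g in seq_along(stages)) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      seed_k <- (as.integer(base_seed) + 104729L * k) %% 2147483647L
      p <- stage_preset(stages[g], frame = frame, seed = seed_k)
      sid <- sprintf("%s_%02d", stages[g], i)
      sec <- generate_section(p, panel = panel, sample_id = sid)
      out[[k]] <- list(sample_id = sid, group = stages[g],
                       stack = sec$stack, truth = sec$truth)
    }
  }
  out
}
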