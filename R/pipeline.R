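#' End-to-end pipeline orchestration
#'
#' `analyze_sample()` takes one stack + ROI through quantification,
#' segmentation, object detection and the fiber table;
#' `run_full_cohort()`/`run_full()` sequence a whole cohort into the tidy
#' result bundle (ROI metrics, fiber table, objects, per-sample summary,
#' CSA summary, correlations, region comparison, run log).
#'
#' Fiber/stroma areas are measured with border fibers retained (a fiber cut
#' by the ROI boundary still occupies area), while fiber counts and CSA
#' statistics use only fibers fully inside the ROI
#' ([exclude_border_fibers()]), the standard CSA convention.
#'
#' @name cli_pipeline
NULL

#' Drop fibers touching the ROI border from a label map
#'
#' @param fibers A `label_map`.
#' @param roi The analysis mask the map was segmented in.
#' @return A `label_map` with border-touching fibers removed and labels
#'   renumbered in raster order.
#' @export
exclude_border_fibers <- function(fibers, roi) {
  lab <- fibers$labels
  border_ids <- unique(lab[.mask_border(roi) & lab > 0L])
  if (length(border_ids)) lab[lab %in% border_ids] <- 0L
  rl <- .relabel_raster(lab)
  structure(list(labels = rl$labels, n_fibers = rl$n,
                 boundary_threshold = fibers$boundary_threshold,
                 params = fibers$params),
            class = "label_map")
}

#' Analyze one sample within one ROI
#'
#' Runs the per-marker ROI metrics, fiber segmentation (laminin channel),
#' stroma derivation, cell/capillary detection with nucleus and size gates,
#' macrophage classification, stroma-restricted marker metrics, and the
#' fiber table, and condenses them into one summary row.
#'
#' @param stack An `imc_stack`.
#' @param roi Logical analysis mask.
#' @param thresholds A `threshold_set`.
#' @param seg A `seg_params` list.
#' @param rules A [positivity_rules()] list.
#' @param group Stage label or `NA`.
#' @param roi_id Identifier for outputs.
#' @return List: `metrics`, `stroma_metrics`, `fibers` (full `label_map`),
#'   `fiber_table` (border-excluded), `cells` (tidy object table),
#'   `vessels`, `summary` (one-row data.frame).
#' @export
analyze_sample <- function(stack, roi, thresholds,
                           seg = segmentation_params(),
                           rules = positivity_rules(),
                           group = NA_character_, roi_id = "whole_section") {
  panel <- stack$panel
  metrics <- roi_metrics(stack, roi, thresholds, roi_id = roi_id)

  seg_area <- seg
  seg_area$exclude_border <- FALSE
  fibers <- segment_fibers(channel_plane(stack, "Laminin"), roi, seg_area)
  stroma <- stroma_mask(roi, fibers)
  roi_area <- mask_area(roi)
  stroma_pct <- 100 * mask_area(stroma) / roi_area

  fibers_complete <- exclude_border_fibers(fibers, roi)
  fiber_table <- build_fiber_table(fibers_complete, stack, thresholds,
                                   rules = rules, roi_id = roi_id,
                                   group = group)

  tmask <- function(marker) {
    t <- get_threshold(thresholds, stack$sample_id, marker)
    apply_threshold(channel_plane(stack, marker), t) & roi
  }
  nuclei <- tmask(nuclei_marker(panel))
  sc_cells <- detect_cells(tmask("CD56"), nuclei, seg)
  cd68_cells <- detect_cells(tmask("CD68"), nuclei, seg)
  cd206_cells <- detect_cells(tmask("CD206"), nuclei, seg)
  macs <- classify_macrophages(cd68_cells, tmask("CD206"), seg)
  vessels <- detect_capillaries(tmask("CD31"), seg)
  caps <- vessels[vessels$kind == "capillary", , drop = FALSE]

  sc_vessel_dist <- if (nrow(caps) && nrow(sc_cells)) {
    mean(nearest_structure_distance(sc_cells, caps))
  } else NA_real_

  stroma_metrics <- if (any(stroma)) {
    roi_metrics(stack, stroma, thresholds, roi_id = paste0(roi_id, "_stroma"))
  } else NULL
  pf <- function(marker) {
    metrics$positive_fraction[metrics$marker_name == marker]
  }

  tag <- function(det, marker, cls) {
    df <- as.data.frame(det)
    df$marker <- rep_len(marker, nrow(df))
    df$class <- as.character(cls)
    df
  }
  cells <- rbind(
    tag(sc_cells, "CD56", rep("satellite_cell", nrow(sc_cells))),
    tag(cd68_cells, "CD68",
        ifelse(macs$is_m2, "m2_macrophage", "non_m2_macrophage")),
    tag(cd206_cells, "CD206", rep("m2_macrophage", nrow(cd206_cells))))
  if (nrow(cells)) {
    cells <- data.frame(roi_id = roi_id, sample_id = stack$sample_id,
                        cells, stringsAsFactors = FALSE)
  }

  summary <- data.frame(
    sample_id = stack$sample_id, group = group, roi_id = roi_id,
    roi_area_um2 = roi_area,
    stroma_pct = stroma_pct, fiber_pct = 100 - stroma_pct,
    n_fibers = fibers_complete$n_fibers,
    fiber_density_mm2 = object_density(fibers_complete$n_fibers, roi),
    mean_csa_um2 = if (nrow(fiber_table)) mean(fiber_table$csa_um2)
                   else NA_real_,
    sd_csa_um2 = if (nrow(fiber_table) > 1L) stats::sd(fiber_table$csa_um2)
                 else NA_real_,
    n_capillaries = nrow(caps),
    capillary_density_mm2 = object_density(nrow(caps), roi),
    n_large_vessels = sum(vessels$kind == "large_vessel"),
    n_satellite_cells = nrow(sc_cells),
    n_cd68_cells = nrow(cd68_cells),
    n_m2 = nrow(cd206_cells),
    n_non_m2 = macs$non_m2,
    sc_vessel_dist_um = sc_vessel_dist,
    perilipin_pct = pf("Perilipin"),
    collagen1_pct = pf("Collagen I"),
    collagen3_pct = pf("Collagen III"),
    collagen6_pct = pf("Collagen VI"),
    te7_pct = pf("TE-7"),
    pdgfra_pct = pf("PDGFRa"),
    ctgf_pct = pf("CTGF"),
    pdgfa_pct = pf("PDGFA"),
    tgfb_pct = pf("TGFb"),
    stringsAsFactors = FALSE)

  list(metrics = metrics, stroma_metrics = stroma_metrics, fibers = fibers,
       fiber_table = fiber_table, cells = cells, vessels = vessels,
       summary = summary)
}

#' Default Spearman correlation family
#'
#' The quantity pairs correlated by default in a full run; the family size
#' (here 8) is the Bonferroni `m`.
#' @return List of character pairs.
#' @export
default_correlation_family <- function() {
  list(c("stroma_pct", "capillary_density_mm2"),
       c("stroma_pct", "fiber_density_mm2"),
       c("stroma_pct", "n_satellite_cells"),
       c("stroma_pct", "n_m2"),
       c("stroma_pct", "perilipin_pct"),
       c("stroma_pct", "mean_csa_um2"),
       c("capillary_density_mm2", "fiber_density_mm2"),
       c("collagen1_pct", "stroma_pct"))
}

# pick two disjoint sq x sq windows of the frame: the one richest and the
# one poorest in stroma (integral-image moving sum on a coarse stride) —
# stands in for the annotator's fibrotic-focus / non-fibrotic sub-ROIs on
# synthetic sections
.pick_subrois <- function(stroma, sq = 80L, stride = 20L) {
  H <- nrow(stroma); W <- ncol(stroma)
  # shrink the window on small frames so two disjoint windows fit
  sq <- min(sq, H, W, max(16L, floor(max(H, W) / 2)))
  S <- apply(apply(stroma, 2L, cumsum), 1L, cumsum)  # transposed integral
  win_sum <- function(r, c) {
    # sum over rows r..r+sq-1, cols c..c+sq-1 (S is transposed: S[c, r])
    a <- S[c + sq - 1L, r + sq - 1L]
    b <- if (r > 1L) S[c + sq - 1L, r - 1L] else 0
    d <- if (c > 1L) S[c - 1L, r + sq - 1L] else 0
    e <- if (r > 1L && c > 1L) S[c - 1L, r - 1L] else 0
    a - b - d + e
  }
  rs <- unique(c(seq(1L, H - sq + 1L, by = stride), H - sq + 1L))
  cs <- unique(c(seq(1L, W - sq + 1L, by = stride), W - sq + 1L))
  grid <- expand.grid(r = rs, c = cs)
  grid$s <- mapply(win_sum, grid$r, grid$c)
  hi <- grid[which.max(grid$s), ]
  disjoint <- abs(grid$r - hi$r) >= sq | abs(grid$c - hi$c) >= sq
  lo <- if (any(disjoint)) {
    grid[disjoint, ][which.min(grid$s[disjoint]), ]
  } else {
    far <- abs(grid$r - hi$r) + abs(grid$c - hi$c)
    grid[which.max(far), ]
  }
  mk <- function(g) {
    m <- matrix(FALSE, H, W)
    m[g$r:(g$r + sq - 1L), g$c:(g$c + sq - 1L)] <- TRUE
    m
  }
  list(fibrotic_focus = mk(hi), nonfibrotic_area = mk(lo))
}

#' Run the full pipeline over an in-memory cohort
#'
#' Sequences quantify -> segment -> objects -> fiber table -> sub-ROI
#' comparison -> summaries -> statistics over a list of samples (as
#' produced by [generate_cohort()], or any list with `sample_id`, `group`,
#' `stack`). Per-sample fibrotic-focus and non-fibrotic sub-ROIs are chosen
#' as the stroma-richest and stroma-poorest windows of the section.
#'
#' @param cohort List of samples (`sample_id`, `group`, `stack`).
#' @param thresholds A `threshold_set` (default: the synthetic-section
#'   thresholds).
#' @param seg,rules Segmentation parameters and positivity rules.
#' @param pairs Correlation family (list of column pairs).
#' @param subroi_um Side of the square sub-ROIs used for the
#'   fibrotic/non-fibrotic comparison.
#' @return A `pipeline_results` list: `roi_metrics`, `fibers`, `objects`,
#'   `sample_summary`, `csa_summary`, `correlations`, `region_comparison`,
#'   `ks_control_vs_dystrophic`, `log`.
#' @export
run_full_cohort <- function(cohort, thresholds = synth_thresholds(),
                            seg = segmentation_params(),
                            rules = positivity_rules(),
                            pairs = default_correlation_family(),
                            subroi_um = 80L) {
  t0 <- Sys.time()
  metrics <- list(); ftabs <- list(); objects <- list(); summaries <- list()
  region_rows <- list()
  for (s in cohort) {
    frame <- dim(s$stack)[1:2]
    roi <- matrix(TRUE, frame[1L], frame[2L])
    res <- analyze_sample(s$stack, roi, thresholds, seg = seg,
                          rules = rules, group = s$group,
                          roi_id = "whole_section")
    metrics[[length(metrics) + 1L]] <- cbind(sample_id = s$sample_id,
                                             res$metrics)
    ftabs[[length(ftabs) + 1L]] <- res$fiber_table
    if (nrow(res$cells)) objects[[length(objects) + 1L]] <- res$cells
    summaries[[length(summaries) + 1L]] <- res$summary
    # sub-ROI contrast windows from the measured stroma mask
    stroma <- stroma_mask(roi, res$fibers)
    sub <- .pick_subrois(stroma, sq = as.integer(subroi_um))
    for (kind in names(sub)) {
      r <- analyze_sample(s$stack, sub[[kind]], thresholds, seg = seg,
                          rules = rules, group = s$group, roi_id = kind)
      row <- r$summary
      row$roi_kind <- kind
      region_rows[[length(region_rows) + 1L]] <- row
    }
  }
  roi_metrics_tab <- do.call(rbind, metrics)
  fiber_tab <- do.call(rbind, ftabs)
  object_tab <- if (length(objects)) do.call(rbind, objects) else
    data.frame()
  summary_tab <- do.call(rbind, summaries)
  region_tab <- do.call(rbind, region_rows)

  csa <- csa_summary(fiber_tab)
  corr <- spearman_family(summary_tab, pairs)

  ctrl_csa <- fiber_tab$csa_um2[fiber_tab$group == "control"]
  dyst_csa <- fiber_tab$csa_um2[fiber_tab$group != "control"]
  ks <- if (length(ctrl_csa) && length(dyst_csa)) {
    ks_compare(ctrl_csa, dyst_csa)
  } else NULL

  region_cmp <- compare_regions(region_tab)

  log <- c(sprintf("imcmyo %s", as.character(utils::packageVersion("imcmyo"))),
           sprintf("samples: %d", length(cohort)),
           sprintf("thresholds: %s",
                   paste(unique(thresholds$provenance), collapse = ",")),
           sprintf("segmentation: sigma=%g min_fiber=%g",
                   seg$smooth_sigma_um, seg$min_fiber_area_um2),
           sprintf("positivity: default=%g overrides=%s", rules$default,
                   paste(names(rules$overrides), rules$overrides,
                         sep = "=", collapse = ",")),
           sprintf("correlation family m=%d", length(pairs)),
           sprintf("elapsed_s: %.1f",
                   as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  structure(list(roi_metrics = roi_metrics_tab, fibers = fiber_tab,
                 objects = object_tab, sample_summary = summary_tab,
                 csa_summary = csa, correlations = corr,
                 region_comparison = region_cmp,
                 ks_control_vs_dystrophic = ks, log = log),
            class = "pipeline_results")
}

#' Compare fibrotic and non-fibrotic regions
#'
#' Given per-region summary rows (one per sample x sub-ROI, with `group`
#' and `roi_kind` columns), computes the per-quantity mean and SD of the
#' three realized contrast groups (control non-fibrotic, dystrophic
#' non-fibrotic, dystrophic fibrotic) and all pairwise unpaired t-tests.
#' Contrasts with a group of fewer than 2 regions are skipped with a
#' warning.
#'
#' @param region_tab Data.frame of region summary rows.
#' @param quantities Summary columns to compare.
#' @param alpha Significance level.
#' @return List with `means` (group x quantity mean/SD table) and `tests`
#'   (pairwise t-test rows).
#' @export
compare_regions <- function(region_tab,
                            quantities = c("stroma_pct", "collagen1_pct",
                                           "collagen3_pct", "collagen6_pct",
                                           "te7_pct", "perilipin_pct",
                                           "pdgfra_pct", "ctgf_pct",
                                           "pdgfa_pct", "tgfb_pct",
                                           "n_satellite_cells", "n_fibers",
                                           "n_capillaries", "n_m2"),
                            alpha = 0.05) {
  stopifnot(all(c("group", "roi_kind") %in% names(region_tab)))
  region_tab$contrast <- ifelse(
    region_tab$group == "control", "control_nonfibrotic",
    ifelse(region_tab$roi_kind == "fibrotic_focus", "dystrophic_fibrotic",
           "dystrophic_nonfibrotic"))
  # a control section has no fibrotic focus by definition
  region_tab <- region_tab[!(region_tab$group == "control" &
                               region_tab$roi_kind == "fibrotic_focus"), ,
                           drop = FALSE]
  quantities <- intersect(quantities, names(region_tab))
  groups <- unique(region_tab$contrast)
  means <- do.call(rbind, lapply(groups, function(g) {
    sub <- region_tab[region_tab$contrast == g, , drop = FALSE]
    do.call(rbind, lapply(quantities, function(q) {
      data.frame(contrast = g, quantity = q, n = nrow(sub),
                 mean = mean(sub[[q]], na.rm = TRUE),
                 sd = stats::sd(sub[[q]]), stringsAsFactors = FALSE)
    }))
  }))
  combos <- utils::combn(groups, 2L, simplify = FALSE)
  tests <- list()
  for (cmb in combos) {
    a <- region_tab[region_tab$contrast == cmb[1L], , drop = FALSE]
    b <- region_tab[region_tab$contrast == cmb[2L], , drop = FALSE]
    if (nrow(a) < 2L || nrow(b) < 2L) {
      warning("contrast ", cmb[1L], " vs ", cmb[2L],
              " skipped: fewer than 2 regions in a group", call. = FALSE)
      next
    }
    for (q in quantities) {
      tt <- tryCatch(compare_groups(a[[q]], b[[q]], alpha = alpha),
                     error = function(e) NULL)
      if (is.null(tt)) next
      tests[[length(tests) + 1L]] <-
        data.frame(group_a = cmb[1L], group_b = cmb[2L], quantity = q,
                   mean_a = mean(a[[q]], na.rm = TRUE),
                   mean_b = mean(b[[q]], na.rm = TRUE),
                   t = tt$t, p = tt$p, significant = tt$significant,
                   stringsAsFactors = FALSE)
    }
  }
  list(means = means,
       tests = if (length(tests)) do.call(rbind, tests) else data.frame())
}

#' Write a results bundle to a directory
#'
#' Emits roi_metrics.csv, fibers.csv, objects.csv, sample_summary.csv,
#' csa_summary.csv, correlations.csv, region_comparison.csv and
#' run_log.txt.
#'
#' @param results A `pipeline_results` list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                        row.names = FALSE)
  wr(results$roi_metrics, "roi_metrics.csv")
  wr(results$fibers, "fibers.csv")
  wr(results$objects, "objects.csv")
  wr(results$sample_summary, "sample_summary.csv")
  wr(results$csa_summary$stats, "csa_summary.csv")
  wr(results$correlations, "correlations.csv")
  wr(results$region_comparison$tests, "region_comparison.csv")
  writeLines(results$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Load and validate a run configuration
#'
#' YAML (or JSON) with either a `synthetic:` block (`n_per_group`, `frame`,
#' `base_seed`) or a `samples:` list (`sample_id`, `group`, `stack` path,
#' optional `rois` path), plus optional `panel`, `thresholds` (CSV path or
#' `auto:otsu`/`auto:quantile`), `segmentation`, `positivity`,
#' `statistics`, `output_dir`, `seed`.
#'
#' @param path Path to the config file.
#' @return Validated config list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$synthetic) && is.null(cfg$samples)) {
    stop("config needs a 'synthetic' block or a 'samples' list",
         call. = FALSE)
  }
  if (!is.null(cfg$samples)) {
    for (s in cfg$samples) {
      if (!file.exists(s$stack)) stop("stack file missing: ", s$stack,
                                      call. = FALSE)
      if (!is.null(s$rois) && !file.exists(s$rois)) {
        stop("ROI file missing: ", s$rois, call. = FALSE)
      }
      if (!is.null(s$group) && !s$group %in% .groups) {
        stop("unknown group '", s$group, "'; expected one of ",
             paste(.groups, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (!is.null(cfg$panel) && !file.exists(cfg$panel)) {
    stop("panel file missing: ", cfg$panel, call. = FALSE)
  }
  alpha <- cfg$statistics$alpha
  if (!is.null(alpha) && (alpha <= 0 || alpha >= 1)) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  cfg
}

# resolve the cohort and thresholds a config describes
.config_cohort <- function(cfg) {
  panel <- if (is.null(cfg$panel)) load_panel() else load_panel(cfg$panel)
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    cohort <- generate_cohort(
      n_per_group = if (is.null(syn$n_per_group)) 2L else syn$n_per_group,
      base_seed = if (is.null(syn$base_seed)) {
        if (is.null(cfg$seed)) 1L else cfg$seed
      } else syn$base_seed,
      frame = if (is.null(syn$frame)) c(300L, 300L) else
        as.integer(unlist(syn$frame)),
      panel = panel)
  } else {
    cohort <- lapply(cfg$samples, function(s) {
      stack <- read_stack(s$stack, panel, sample_id = s$sample_id)
      list(sample_id = s$sample_id,
           group = if (is.null(s$group)) NA_character_ else s$group,
           stack = stack,
           rois = if (is.null(s$rois)) NULL else import_rois(s$rois))
    })
  }
  thresholds <- if (is.null(cfg$thresholds)) {
    synth_thresholds(panel)
  } else if (grepl("^auto:", cfg$thresholds)) {
    method <- sub("^auto:", "", cfg$thresholds)
    rows <- list()
    for (s in cohort) {
      frame <- dim(s$stack)[1:2]
      roi <- matrix(TRUE, frame[1L], frame[2L])
      for (m in panel$marker_name) {
        t <- auto_threshold(channel_plane(s$stack, m), roi, method = method)
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = s$sample_id, marker_name = m, threshold = t,
                     provenance = "auto", stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    threshold_set(tab$sample_id, tab$marker_name, tab$threshold,
                  tab$provenance)
  } else {
    read_thresholds(cfg$thresholds)
  }
  seg_cfg <- if (is.null(cfg$segmentation)) list() else cfg$segmentation
  seg <- do.call(segmentation_params,
                 seg_cfg[intersect(names(seg_cfg),
                                   names(formals(segmentation_params)))])
  rules <- positivity_rules(
    default = if (is.null(cfg$positivity$default)) 0.10 else
      cfg$positivity$default,
    overrides = if (is.null(cfg$positivity$overrides)) c(CTGF = 0.05) else
      unlist(cfg$positivity$overrides))
  list(cohort = cohort, thresholds = thresholds, seg = seg, rules = rules,
       panel = panel)
}

#' Run the quantification stage from a config
#'
#' Per-sample, per-ROI, per-marker metrics only (no segmentation);
#' deterministic given config + seed.
#'
#' @param config Path to a config file, or a config list.
#' @return The tidy metrics data.frame (one row per sample x ROI x marker);
#'   written to `<output_dir>/roi_metrics.csv` when the config names an
#'   output directory.
#' @export
run_quantify <- function(config) {
  cfg <- if (is.character(config)) load_run_config(config) else config
  rc <- .config_cohort(cfg)
  rows <- list()
  for (s in rc$cohort) {
    frame <- dim(s$stack)[1:2]
    rois <- if (!is.null(s$rois)) s$rois else NULL
    masks <- if (is.null(rois)) {
      list(whole_section = matrix(TRUE, frame[1L], frame[2L]))
    } else {
      ms <- lapply(rois, rasterize_roi, shape = frame)
      names(ms) <- vapply(rois, function(r) r$roi_id, character(1L))
      ms
    }
    for (rid in names(masks)) {
      rows[[length(rows) + 1L]] <-
        cbind(sample_id = s$sample_id,
              roi_metrics(s$stack, masks[[rid]], rc$thresholds,
                          roi_id = rid))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$roi_id, out$marker_name), ]
  rownames(out) <- NULL
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(cfg$output_dir, "roi_metrics.csv"),
                     row.names = FALSE)
  }
  out
}

#' Run the full pipeline from a config
#'
#' @param config Path to a config file, or a config list.
#' @return A `pipeline_results` list; also written to the config's
#'   `output_dir` when set.
#' @export
run_full <- function(config) {
  cfg <- if (is.character(config)) load_run_config(config) else config
  rc <- .config_cohort(cfg)
  pairs <- if (is.null(cfg$statistics$correlation_pairs)) {
    default_correlation_family()
  } else lapply(cfg$statistics$correlation_pairs, unlist)
  results <- run_full_cohort(rc$cohort, thresholds = rc$thresholds,
                             seg = rc$seg, rules = rc$rules, pairs = pairs)
  if (!is.null(cfg$output_dir)) write_results(results, cfg$output_dir)
  results
}
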