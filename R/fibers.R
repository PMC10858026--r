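#' Per-fiber tables, positivity scoring and CSA summaries
#'
#' For each segmented fiber the pipeline records its cross-sectional area
#' (CSA; pixel count at 1 um^2/px) and, for each marker, the fraction of the
#' fiber's area at or above the marker's threshold. A fiber is scored
#' positive for a marker when that fraction reaches the marker's area rule —
#' 10% of the fiber area by default, 5% for CTGF.
#'
#' @name fiber_analysis
NULL

.groups <- c("control", "mild", "moderate", "advanced_fibrosis",
             "advanced_fat")

.col_key <- function(marker) gsub("[^A-Za-z0-9]+", "_", marker)

#' Fiber positivity rules
#'
#' Area-fraction thresholds deciding per-fiber marker positivity: a fiber is
#' positive when at least the rule's fraction of its area is marker-positive
#' (inclusive).
#'
#' @param default Fraction in (0, 1] applied to every marker without an
#'   override.
#' @param overrides Named numeric vector of per-marker fractions; the
#'   default keeps CTGF at 5%.
#' @return Named closure-free list: `default` and `overrides`.
#' @export
positivity_rules <- function(default = 0.10, overrides = c(CTGF = 0.05)) {
  stopifnot(default > 0, default <= 1,
            all(overrides > 0), all(overrides <= 1))
  list(default = default, overrides = overrides)
}

.rule_for <- function(rules, marker) {
  if (marker %in% names(rules$overrides)) unname(rules$overrides[marker])
  else rules$default
}

#' Score one fiber's positivity for a marker
#'
#' Positive iff `positive_fraction >= rule` (inclusive, "at least"): a fiber
#' with exactly 10.0% positive area is positive under the default rule.
#'
#' @param positive_fraction Fraction of fiber area positive, in `[0, 1]`.
#' @param marker Marker name (must be known when `rules` has overrides by
#'   name; any marker is accepted).
#' @param rules A [positivity_rules()] list.
#' @return Logical.
#' @export
score_positivity <- function(positive_fraction, marker,
                             rules = positivity_rules()) {
  stopifnot(all(positive_fraction >= 0), all(positive_fraction <= 1))
  positive_fraction >= .rule_for(rules, marker)
}

#' Build the per-fiber table
#'
#' One row per fiber: CSA, centroid, and for every panel marker the positive
#' area fraction (column `frac_<marker>`, in 0..1) and the positivity flag
#' (column `pos_<marker>`) under the area rules. Fiber-level fractions use
#' the same per-sample thresholds as the ROI metrics.
#'
#' @param fibers A `label_map` from [segment_fibers()].
#' @param stack The `imc_stack` the fibers were segmented from.
#' @param thresholds A `threshold_set`.
#' @param rules A [positivity_rules()] list.
#' @param roi_id Region identifier copied into the table.
#' @param group Disease-stage group label, one of `control`, `mild`,
#'   `moderate`, `advanced_fibrosis`, `advanced_fat`, or `NA`.
#' @return A `fiber_table` data.frame; empty (0 rows) for an empty label
#'   map.
#' @export
build_fiber_table <- function(fibers, stack, thresholds,
                              rules = positivity_rules(),
                              roi_id = "roi", group = NA_character_) {
  stopifnot(identical(dim(fibers$labels), dim(stack$pixels)[1:2]))
  if (!is.na(group)) group <- match.arg(group, .groups)
  panel <- stack$panel
  feats <- .label_features(fibers$labels)
  n_fib <- nrow(feats)
  tab <- data.frame(fiber_id = feats$label,
                    roi_id = rep_len(roi_id, n_fib),
                    sample_id = rep_len(stack$sample_id, n_fib),
                    group = rep_len(group, n_fib),
                    csa_um2 = feats$area_um2,
                    centroid_x = feats$centroid_x,
                    centroid_y = feats$centroid_y,
                    stringsAsFactors = FALSE)
  sel <- fibers$labels > 0L
  lab <- fibers$labels[sel]
  for (i in seq_len(n_channels(panel))) {
    m <- panel$marker_name[i]
    key <- .col_key(m)
    if (nrow(tab)) {
      t <- get_threshold(thresholds, stack$sample_id, m)
      pos <- stack$pixels[, , i][sel] >= t
      cnt <- rowsum(as.numeric(pos), lab)
      frac <- as.numeric(cnt[, 1L]) / feats$area_um2
    } else frac <- numeric()
    tab[[paste0("frac_", key)]] <- frac
    tab[[paste0("pos_", key)]] <- score_positivity(frac, m, rules)
  }
  class(tab) <- c("fiber_table", "data.frame")
  tab
}

#' Percentages of fiber classes in a fiber table
#'
#' Percent of fibers positive for MYH3, CD56, MYH3-CD56+ (regenerating
#' CD56+ fibers that are not MYH3+), CTGF, PDGFA and TGFb, out of all fibers
#' in the table.
#'
#' @param table A non-empty `fiber_table`.
#' @return Named numeric vector of percentages.
#' @export
class_percentages <- function(table) {
  if (nrow(table) == 0L) stop("fiber table is empty", call. = FALSE)
  flag <- function(m) {
    col <- paste0("pos_", .col_key(m))
    if (is.null(table[[col]])) stop("no positivity column for marker ", m,
                                    call. = FALSE)
    table[[col]]
  }
  n <- nrow(table)
  c(MYH3 = 100 * sum(flag("MYH3")) / n,
    CD56 = 100 * sum(flag("CD56")) / n,
    `MYH3-CD56+` = 100 * sum(!flag("MYH3") & flag("CD56")) / n,
    CTGF = 100 * sum(flag("CTGF")) / n,
    PDGFA = 100 * sum(flag("PDGFA")) / n,
    TGFb = 100 * sum(flag("TGFb")) / n)
}

#' Summarize CSA distributions per group
#'
#' Per-group arithmetic mean and sample (n - 1) standard deviation, a
#' relative-frequency histogram on shared bins, and the pooled per-group
#' ECDF evaluated at the observed CSAs (no binning).
#'
#' @param tables A `fiber_table` (or several rbind-ed) carrying a `group`
#'   column, or a list of `fiber_table`s.
#' @param bin_width Histogram bin width in um^2.
#' @return List with `stats` (group, n_fibers, mean_csa, sd_csa),
#'   `histogram` (group, bin_lo, bin_hi, rel_freq; frequencies sum to 1 per
#'   group) and `ecdf` (group, csa_um2, ecdf). Groups with no fibers are
#'   skipped with a warning.
#' @export
csa_summary <- function(tables, bin_width = 250) {
  if (is.list(tables) && !is.data.frame(tables)) {
    tables <- do.call(rbind, tables)
  }
  stopifnot(bin_width > 0)
  tables <- tables[!is.na(tables$group), , drop = FALSE]
  groups <- unique(tables$group)
  empty <- setdiff(.groups, groups)
  if (length(empty) && length(groups) < length(.groups)) {
    warning("group(s) with no fibers skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  if (!nrow(tables)) stop("no fibers in any group", call. = FALSE)
  breaks <- seq(0, ceiling(max(tables$csa_um2) / bin_width) * bin_width,
                by = bin_width)
  stats <- do.call(rbind, lapply(groups, function(g) {
    x <- tables$csa_um2[tables$group == g]
    data.frame(group = g, n_fibers = length(x), mean_csa = mean(x),
               sd_csa = stats::sd(x), stringsAsFactors = FALSE)
  }))
  hist <- do.call(rbind, lapply(groups, function(g) {
    x <- tables$csa_um2[tables$group == g]
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(group = g, bin_lo = breaks[-length(breaks)],
               bin_hi = breaks[-1L], rel_freq = h$counts / length(x),
               stringsAsFactors = FALSE)
  }))
  ecdf_tab <- do.call(rbind, lapply(groups, function(g) {
    x <- sort(tables$csa_um2[tables$group == g])
    data.frame(group = g, csa_um2 = x,
               ecdf = seq_along(x) / length(x), stringsAsFactors = FALSE)
  }))
  list(stats = stats, histogram = hist, ecdf = ecdf_tab)
}
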