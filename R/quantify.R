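#' Threshold-based region quantification
#'
#' The core region metrics of the pipeline: for each marker channel and each
#' region of interest, the positive fraction (percentage of region pixels at
#' or above the channel threshold), the mean intensity of all region pixels,
#' and the mean intensity of the positive pixels. The positivity comparator
#' is inclusive (`>= t`), so a threshold of 0 marks every pixel positive.
#'
#' @name quantification
NULL

#' Threshold a channel plane
#'
#' @param plane H x W matrix of counts.
#' @param t Threshold in raw counts, `>= 0`. A pixel is positive iff its
#'   value is at or above `t` (inclusive; switch to strict with
#'   `inclusive = FALSE`).
#' @param inclusive Use `>=` (default) or `>`.
#' @return Logical H x W mask.
#' @export
apply_threshold <- function(plane, t, inclusive = TRUE) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  if (inclusive) plane >= t else plane > t
}

#' Automatic threshold from ROI pixels
#'
#' `otsu` maximizes the between-class variance over the histogram of integer
#' counts inside the ROI (the returned threshold `t` splits pixels into
#' `< t` and `>= t`; the smallest maximizer is returned). `quantile` returns
#' the `q` empirical quantile of ROI pixels (type 1, so the threshold is an
#' observed count). A constant plane has no two-class split: the fallback
#' threshold `max + 1` (nothing positive) is returned with a warning.
#'
#' @param plane H x W matrix of counts.
#' @param roi Logical mask restricting the pixels considered.
#' @param method `"otsu"` or `"quantile"`.
#' @param q Quantile for `method = "quantile"`.
#' @return A single threshold in raw counts.
#' @export
auto_threshold <- function(plane, roi, method = c("otsu", "quantile"),
                           q = 0.95) {
  method <- match.arg(method)
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  v <- plane[roi]
  if (length(unique(v)) == 1L) {
    warning("constant plane within ROI; falling back to max + 1 ",
            "(no positive pixels)", call. = FALSE)
    return(v[1L] + 1)
  }
  if (method == "quantile") {
    return(as.numeric(stats::quantile(v, q, type = 1L, names = FALSE)))
  }
  .otsu_counts(v)
}

# Otsu over an integer-count sample: maximize w0*w1*(mu0-mu1)^2 across all
# split points of the sorted unique values; positive class is >= t.
.otsu_counts <- function(v) {
  tab <- table(v)
  vals <- as.numeric(names(tab))
  n <- as.numeric(tab)
  N <- sum(n)
  csum <- cumsum(n)
  cmean <- cumsum(n * vals)
  total <- cmean[length(cmean)]
  k <- seq_len(length(vals) - 1L)  # split after value k: low <= vals[k]
  w0 <- csum[k] / N
  w1 <- 1 - w0
  mu0 <- cmean[k] / csum[k]
  mu1 <- (total - cmean[k]) / (N - csum[k])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  vals[which.max(bcv) + 1L]  # smallest value of the positive class
}

#' Threshold tables
#'
#' Thresholds are per (sample, marker), in raw counts, with a provenance
#' flag (`manual` from a user CSV, `auto` from [auto_threshold()]) carried
#' through to outputs so manual and automatic runs stay distinguishable.
#'
#' @param sample_id,marker_name,threshold,provenance Equal-length vectors.
#' @return A `threshold_set` data.frame.
#' @export
threshold_set <- function(sample_id, marker_name, threshold,
                          provenance = "manual") {
  if (any(threshold < 0)) stop("thresholds must be >= 0", call. = FALSE)
  structure(data.frame(sample_id = sample_id, marker_name = marker_name,
                       threshold = as.numeric(threshold),
                       provenance = provenance,
                       stringsAsFactors = FALSE),
            class = c("threshold_set", "data.frame"))
}

#' @rdname threshold_set
#' @param path CSV with columns sample_id, marker_name, threshold and
#'   optionally provenance.
#' @export
read_thresholds <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "marker_name", "threshold")
  if (!all(need %in% names(tab))) {
    stop("threshold CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tab$provenance)) tab$provenance <- "manual"
  threshold_set(tab$sample_id, tab$marker_name, tab$threshold, tab$provenance)
}

#' @rdname threshold_set
#' @param ts A `threshold_set`.
#' @param sample,marker Sample id and marker name to look up. A row with
#'   `sample_id == "*"` acts as a per-marker default for any sample.
#' @export
get_threshold <- function(ts, sample, marker) {
  hit <- ts$sample_id == sample & ts$marker_name == marker
  if (!any(hit)) hit <- ts$sample_id == "*" & ts$marker_name == marker
  if (!any(hit)) {
    stop("no threshold for sample '", sample, "', marker '", marker, "'",
         call. = FALSE)
  }
  ts$threshold[which(hit)[1L]]
}

#' Per-ROI, per-marker metrics
#'
#' For every marker in the stack's panel: positive fraction
#' `100 * |{p in roi : v(p) >= t}| / |roi|` (percent), mean intensity over
#' all ROI pixels, and mean intensity over the positive pixels (`NA` when no
#' pixel is positive — absent, not zero).
#'
#' @param stack An `imc_stack`.
#' @param roi Logical mask (non-empty) over the stack frame.
#' @param thresholds A `threshold_set` covering every panel marker for the
#'   stack's sample.
#' @param roi_id Identifier copied into the output.
#' @return Data.frame, one row per marker: `roi_id`, `marker_name`,
#'   `roi_area_um2`, `threshold`, `positive_fraction`, `mean_intensity`,
#'   `positive_mean_intensity`.
#' @export
roi_metrics <- function(stack, roi, thresholds, roi_id = "roi") {
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  area <- mask_area(roi)
  panel <- stack$panel
  out <- vector("list", n_channels(panel))
  for (i in seq_len(n_channels(panel))) {
    m <- panel$marker_name[i]
    t <- get_threshold(thresholds, stack$sample_id, m)
    v <- stack$pixels[, , i][roi]
    pos <- v >= t
    out[[i]] <- data.frame(
      roi_id = roi_id, marker_name = m, roi_area_um2 = area, threshold = t,
      positive_fraction = 100 * sum(pos) / area,
      mean_intensity = mean(v),
      positive_mean_intensity = if (any(pos)) mean(v[pos]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Object density per square millimetre
#'
#' @param n Object count (`>= 0`).
#' @param roi Non-empty logical mask; its area (um^2) is the normalizer.
#' @return Objects per mm^2.
#' @export
object_density <- function(n, roi) {
  if (n < 0) stop("object count must be >= 0", call. = FALSE)
  a <- mask_area(roi)
  if (a == 0) stop("ROI is empty", call. = FALSE)
  n / (a / 1e6)
}
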