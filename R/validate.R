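#' Segmentation validation against ground truth
#'
#' Utilities to score a recovered fiber label map against the generator's
#' planted labels: one-to-one greedy matching by intersection-over-union
#' (IoU) and summary recovery statistics.
#'
#' @name validation
NULL

#' Match two label maps one-to-one by IoU
#'
#' Overlapping (truth, predicted) label pairs are ranked by IoU and matched
#' greedily, each label used at most once.
#'
#' @param truth,pred Integer label matrices of equal shape (0 = background).
#' @return Data.frame with one row per truth label: `truth_label`,
#'   `pred_label` (`NA` when unmatched), `iou` (0 when unmatched),
#'   `truth_area`, `pred_area`.
#' @export
match_label_maps <- function(truth, pred) {
  stopifnot(identical(dim(truth), dim(pred)))
  t_ids <- sort(unique(truth[truth > 0L]))
  t_area <- tabulate(truth[truth > 0L])
  p_area <- if (any(pred > 0L)) tabulate(pred[pred > 0L]) else integer()
  out <- data.frame(truth_label = t_ids, pred_label = NA_integer_,
                    iou = 0, truth_area = t_area[t_ids],
                    pred_area = NA_integer_)
  both <- truth > 0L & pred > 0L
  if (any(both)) {
    np <- max(pred)
    key <- (as.numeric(truth[both]) - 1) * np + as.numeric(pred[both])
    cnt <- table(key)
    k <- as.numeric(names(cnt))
    ti <- floor((k - 1) / np) + 1
    pi <- k - (ti - 1) * np
    inter <- as.numeric(cnt)
    iou <- inter / (t_area[ti] + p_area[pi] - inter)
    ord <- order(iou, decreasing = TRUE)
    used_t <- logical(max(ti)); used_p <- logical(np)
    for (j in ord) {
      if (used_t[ti[j]] || used_p[pi[j]]) next
      used_t[ti[j]] <- TRUE; used_p[pi[j]] <- TRUE
      row <- match(ti[j], out$truth_label)
      out$pred_label[row] <- pi[j]
      out$iou[row] <- iou[j]
      out$pred_area[row] <- p_area[pi[j]]
    }
  }
  out
}

#' Summary recovery statistics for a segmentation run
#'
#' @param truth,pred Integer label matrices.
#' @param iou_min IoU at or above which a planted fiber counts as matched.
#' @return List: `n_truth`, `n_pred`, `matched` (count at `iou_min`),
#'   `match_rate`, `mean_iou_matched`.
#' @export
recovery_stats <- function(truth, pred, iou_min = 0.7) {
  m <- match_label_maps(truth, pred)
  hit <- m$iou >= iou_min
  list(n_truth = nrow(m), n_pred = length(unique(pred[pred > 0L])),
       matched = sum(hit),
       match_rate = if (nrow(m)) sum(hit) / nrow(m) else NA_real_,
       mean_iou_matched = if (any(hit)) mean(m$iou[hit]) else NA_real_)
}
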