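#' Jaccard index of two vertex sets
#'
#' `|A n B| / |A u B|`; by convention 1.0 when both sets are empty (a
#' message notes the convention when that happens).
#'
#' @param set_a,set_b integer vectors of vertex indices.
#' @return IoU in [0, 1].
#' @export
vertex_iou <- function(set_a, set_b) {
  if (length(set_a) == 0 && length(set_b) == 0) {
    message("both sets empty: IoU = 1 by convention")
    return(1)
  }
  inter <- length(intersect(set_a, set_b))
  uni <- length(union(set_a, set_b))
  inter / uni
}

#' Match predicted spines to annotated spines
#'
#' Greedy one-to-one matching by descending IoU (the default), or the
#' optimal assignment maximizing total IoU (`optimal = TRUE`, exhaustive
#' over small instances). A matched pair with IoU at or above the
#' threshold is a true positive; unmatched predictions are false
#' positives, unmatched truths false negatives.
#'
#' @param pred,truth lists of vertex-index sets.
#' @param iou_threshold TP threshold in (0, 1].
#' @param optimal use optimal instead of greedy assignment (instances up
#'   to 10 x 10).
#' @return list: `TP`, `FP`, `FN`, `pairs` (data frame pred, truth, iou of
#'   matched pairs), `per_spine_iou` (IoU of each truth's match, 0 if
#'   unmatched).
#' @export
match_spines <- function(pred, truth, iou_threshold = 0.5,
                         optimal = FALSE) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  np <- length(pred)
  nt <- length(truth)
  if (np == 0 || nt == 0) {
    return(list(TP = 0L, FP = np, FN = nt,
                pairs = data.frame(pred = integer(0), truth = integer(0),
                                   iou = numeric(0)),
                per_spine_iou = rep(0, nt)))
  }
  iou <- matrix(0, np, nt)
  for (i in seq_len(np))
    for (j in seq_len(nt))
      iou[i, j] <- length(intersect(pred[[i]], truth[[j]])) /
        length(union(pred[[i]], truth[[j]]))

  if (optimal) {
    if (np > 10 || nt > 10)
      stop("optimal matching supported up to 10 x 10")
    # exhaustive assignment of truths to distinct predictions
    best <- NULL
    best_sum <- -1
    assign_rec <- function(j, used, cur, s) {
      if (j > nt) {
        if (s > best_sum) {
          best_sum <<- s
          best <<- cur
        }
        return(invisible())
      }
      assign_rec(j + 1, used, c(cur, NA), s)  # truth j unmatched
      for (i in seq_len(np)) {
        if (i %in% used) next
        assign_rec(j + 1, c(used, i), c(cur, i), s + iou[i, j])
      }
    }
    assign_rec(1L, integer(0), integer(0), 0)
    pairs <- data.frame(pred = integer(0), truth = integer(0),
                        iou = numeric(0))
    for (j in seq_len(nt)) {
      if (!is.na(best[j]) && iou[best[j], j] > 0)
        pairs <- rbind(pairs, data.frame(pred = best[j], truth = j,
                                         iou = iou[best[j], j]))
    }
  } else {
    ord <- order(-iou)
    used_p <- logical(np)
    used_t <- logical(nt)
    pairs <- data.frame(pred = integer(0), truth = integer(0),
                        iou = numeric(0))
    for (o in ord) {
      if (iou[o] <= 0) break
      i <- (o - 1) %% np + 1
      j <- (o - 1) %/% np + 1
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE
      used_t[j] <- TRUE
      pairs <- rbind(pairs, data.frame(pred = i, truth = j,
                                       iou = iou[i, j]))
    }
  }
  per_spine <- rep(0, nt)
  per_spine[pairs$truth] <- pairs$iou
  TP <- sum(pairs$iou >= iou_threshold)
  list(TP = as.integer(TP), FP = as.integer(np - TP),
       FN = as.integer(nt - TP), pairs = pairs,
       per_spine_iou = per_spine)
}

object_metrics <- function(TP, FP, FN) {
  prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  rec <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else 0
  # object-level accuracy as TP / (TP + FP + FN): the Jaccard form, the
  # only definition consistent with accuracy < min(precision, recall)
  acc <- if (TP + FP + FN > 0) TP / (TP + FP + FN) else NA_real_
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Union-based evaluation of a spine segmentation
#'
#' Vertex-level confusion over the unions of predicted and annotated spine
#' sets: `TP = |U_pred n U_truth|`, `FP = |U_pred \\ U_truth|`,
#' `FN = |U_truth \\ U_pred|`, with IoU and accuracy/precision/recall/F1
#' derived from these counts. The union criterion scores clustered spine
#' groups fairly even when individual spines are merged by the detector.
#'
#' @param pred,truth lists of vertex-index sets.
#' @return list with `TP`, `FP`, `FN`, `iou` and the derived metrics.
#' @export
union_metrics <- function(pred, truth) {
  up <- unique(unlist(pred, use.names = FALSE))
  ut <- unique(unlist(truth, use.names = FALSE))
  TP <- length(intersect(up, ut))
  FP <- length(setdiff(up, ut))
  FN <- length(setdiff(ut, up))
  iou <- if (length(union(up, ut)) > 0) TP / length(union(up, ut)) else 1
  c(list(TP = TP, FP = FP, FN = FN, iou = iou),
    object_metrics(TP, FP, FN))
}

#' Full evaluation report for a segmentation
#'
#' Scores a predicted segmentation against ground truth under both
#' criteria: per-spine IoU with one-to-one matching (object-level
#' accuracy/precision/recall/F1 at the given IoU threshold) and the
#' union-of-spines IoU. Vertex-level IoUs for the shaft and the spine
#' union are also reported.
#'
#' @param pred_spines,truth_spines lists of vertex-index sets.
#' @param n_vertices total vertex count (for the shaft IoU).
#' @param iou_threshold per-spine TP threshold (reported in the output).
#' @param optimal use optimal matching (see [match_spines()]).
#' @return an object of class `spine_eval`.
#' @export
evaluate_segmentation <- function(pred_spines, truth_spines, n_vertices,
                                  iou_threshold = 0.5, optimal = FALSE) {
  mt <- match_spines(pred_spines, truth_spines,
                     iou_threshold = iou_threshold, optimal = optimal)
  um <- union_metrics(pred_spines, truth_spines)
  pred_shaft <- setdiff(seq_len(n_vertices),
                        unlist(pred_spines, use.names = FALSE))
  truth_shaft <- setdiff(seq_len(n_vertices),
                         unlist(truth_spines, use.names = FALSE))
  structure(list(
    per_spine_iou = mt$per_spine_iou,
    mean_spine_iou = if (length(mt$per_spine_iou))
      mean(mt$per_spine_iou) else NA_real_,
    union_iou = um$iou,
    shaft_iou = vertex_iou(pred_shaft, truth_shaft),
    object = c(list(TP = mt$TP, FP = mt$FP, FN = mt$FN),
               object_metrics(mt$TP, mt$FP, mt$FN)),
    union = um,
    iou_threshold = iou_threshold,
    n_pred = length(pred_spines), n_truth = length(truth_spines)
  ), class = "spine_eval")
}

#' @export
print.spine_eval <- function(x, ...) {
  cat("spine segmentation evaluation\n")
  cat(sprintf("  spines: %d predicted / %d annotated\n", x$n_pred,
              x$n_truth))
  cat(sprintf("  per-spine IoU criterion (threshold %.2f):\n",
              x$iou_threshold))
  cat(sprintf("    TP %d  FP %d  FN %d\n", x$object$TP, x$object$FP,
              x$object$FN))
  cat(sprintf(
    "    accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
    x$object$accuracy, x$object$precision, x$object$recall, x$object$f1))
  cat(sprintf("    mean per-spine IoU %.3f\n", x$mean_spine_iou))
  cat("  union-of-spines criterion:\n")
  cat(sprintf(
    "    IoU %.3f  accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
    x$union_iou, x$union$accuracy, x$union$precision, x$union$recall,
    x$union$f1))
  cat(sprintf("  shaft vertex IoU %.3f\n", x$shaft_iou))
  invisible(x)
}

#' Write an evaluation report to JSON plus a per-spine IoU CSV
#' @param ev a `spine_eval`.
#' @param json_path output JSON path.
#' @param csv_path optional per-spine IoU CSV path.
#' @export
write_eval_report <- function(ev, json_path, csv_path = NULL) {
  jsonlite::write_json(unclass(ev), json_path, auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(truth_spine = seq_along(ev$per_spine_iou),
                                iou = ev$per_spine_iou),
                     csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
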