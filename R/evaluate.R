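#' Round half away from zero
#'
#' Rounding to the nearest unit with .5 going up, the convention of
#' most published percentage tables (R's own `round` uses banker's
#' rounding).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Match detected trunks against reference positions
#'
#' Greedy one-to-one matching by ascending pair distance among the
#' estimate/reference pairs within the search radius (15 cm by default).
#' Matched estimates are true positives, unmatched estimates false
#' positives, unmatched references false negatives. Matching distance is
#' horizontal (x, y) by default because detected and reference trunk
#' heights follow different conventions; set `use_z = TRUE` for full 3D
#' distance.
#'
#' @param estimated K x 2 or K x 3 matrix of detected positions, meters.
#' @param reference M x 2 or M x 3 matrix of reference positions, in the
#'   same frame.
#' @param radius match radius in meters (default 0.15).
#' @param use_z include z in the matching distance.
#' @return an object of class `detection_evaluation` with counts `tp`,
#'   `fp`, `fn`, the metrics `precision`, `recall`, `f1` (fractions in
#'   \[0, 1\]; `NA` when the denominator is 0), the `matches` (two-column
#'   index matrix), and the radius used.
#' @export
match_trunks <- function(estimated, reference, radius = 0.15,
                         use_z = FALSE) {
  stopifnot(radius > 0)
  est <- as.matrix(estimated); ref <- as.matrix(reference)
  if (length(est) == 0) est <- matrix(numeric(0), ncol = 3)
  if (length(ref) == 0) ref <- matrix(numeric(0), ncol = 3)
  dcols <- if (use_z) 1:3 else 1:2
  K <- nrow(est); M <- nrow(ref)
  matches <- matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("estimated", "reference")))
  if (K > 0 && M > 0) {
    d2 <- outer(rowSums(est[, dcols, drop = FALSE]^2),
                rowSums(ref[, dcols, drop = FALSE]^2), "+") -
      2 * est[, dcols, drop = FALSE] %*% t(ref[, dcols, drop = FALSE])
    d2[d2 < 0] <- 0
    pairs <- which(d2 <= radius^2, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(d2[pairs])
      used_e <- logical(K); used_r <- logical(M)
      for (p in ord) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        if (used_e[i] || used_r[j]) next
        used_e[i] <- TRUE; used_r[j] <- TRUE
        matches <- rbind(matches, c(i, j))
      }
    }
  }
  tp <- nrow(matches); fp <- K - tp; fn <- M - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, radius = radius,
                 matches = matches),
            class = "detection_evaluation")
}

#' Precision/recall/F1 from raw counts
#'
#' The same metric arithmetic as [match_trunks()], for when the confusion
#' counts are already known (published evaluations, pooled runs).
#'
#' @param tp,fp,fn non-negative counts.
#' @param radius bookkeeping only.
#' @return a `detection_evaluation`.
#' @export
detection_metrics <- function(tp, fp, fn, radius = 0.15) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, radius = radius,
                 matches = NULL),
            class = "detection_evaluation")
}

#' @export
print.detection_evaluation <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else
    sprintf("%d%%", round_half_up(100 * v))
  cat(sprintf("<detection_evaluation> TP %d  FP %d  FN %d | precision %s  recall %s  F1 %s (radius %.2f m)\n",
              x$tp, x$fp, x$fn, fmt(x$precision), fmt(x$recall), fmt(x$f1),
              x$radius))
  invisible(x)
}

#' Row segmentation accuracy against reference labels
#'
#' Pairs each reference row with the predicted row sharing the most points
#' (one-to-one, greedy by descending overlap) and reports each reference
#' row's overlap fraction |intersection| / |reference row|. The overall
#' rate is the fraction of reference rows recovered completely (overlap
#' exactly 1); the mean overlap is reported alongside.
#'
#' @param predicted integer labels, one per point; values < 0 or `NA` mean
#'   unassigned.
#' @param reference integer labels aligned to the same points; rows are
#'   the distinct non-negative values.
#' @return an object of class `row_accuracy`: `per_row` tibble, overall
#'   `rate`, and `mean_overlap` (both in \[0, 1\]).
#' @export
row_segmentation_accuracy <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference label vectors must have equal length")
  pred <- ifelse(is.na(predicted) | predicted < 0, NA_integer_,
                 as.integer(predicted))
  ref <- ifelse(is.na(reference) | reference < 0, NA_integer_,
                as.integer(reference))
  ref_ids <- sort(unique(ref[!is.na(ref)]))
  if (!length(ref_ids)) stop("reference labels contain no rows")
  tab <- table(ref = factor(ref, levels = ref_ids), pred = pred, useNA = "no")
  pred_ids <- as.integer(colnames(tab))
  # greedy one-to-one by descending overlap
  pairing <- rep(NA_integer_, length(ref_ids))
  overlap <- numeric(length(ref_ids))
  if (length(pred_ids)) {
    cells <- which(tab > 0, arr.ind = TRUE)
    ord <- order(tab[cells], decreasing = TRUE)
    used_pred <- logical(length(pred_ids))
    for (p in ord) {
      i <- cells[p, 1]; j <- cells[p, 2]
      if (!is.na(pairing[i]) || used_pred[j]) next
      pairing[i] <- pred_ids[j]
      overlap[i] <- tab[i, j]
      used_pred[j] <- TRUE
    }
  }
  n_ref <- as.vector(table(factor(ref, levels = ref_ids)))
  frac <- overlap / n_ref
  per_row <- tibble::tibble(row = ref_ids, n_ref = n_ref,
                            matched_pred = pairing,
                            overlap = as.integer(overlap),
                            overlap_fraction = frac)
  structure(list(per_row = per_row,
                 rate = mean(overlap == n_ref),
                 mean_overlap = mean(frac)),
            class = "row_accuracy")
}

#' @export
print.row_accuracy <- function(x, ...) {
  cat(sprintf("<row_accuracy> overall rate %.1f%% | mean overlap %.3f over %d rows\n",
              100 * x$rate, x$mean_overlap, nrow(x$per_row)))
  invisible(x)
}
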