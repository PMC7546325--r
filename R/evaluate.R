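#' Grid-discretised comparison of manual and automatic stomate masks
#'
#' Both masks are discretised onto a grid of `cell_size` x `cell_size`
#' cells; a cell takes the value 1 when at least half of its pixels are
#' stomate (partial cells at the right/bottom edge use their actual pixel
#' count as the denominator). Cells where both grids are 1 are true
#' positives, auto-only cells false positives, manual-only cells false
#' negatives, and the rest true negatives.
#'
#' @param manual,auto logical matrices of the same shape (TRUE = stomate).
#' @param cell_size grid cell side in pixels.
#' @return object of class `confusion_counts`: list with `tp,fp,fn,tn`.
#' @export
discretize_compare <- function(manual, auto, cell_size) {
  if (!all(dim(manual) == dim(auto)))
    stop("geometry error: mask shapes differ")
  stopifnot(cell_size >= 1)
  mg <- discretize_mask(manual, cell_size)
  ag <- discretize_mask(auto, cell_size)
  structure(list(tp = sum(mg & ag), fp = sum(!mg & ag),
                 fn = sum(mg & !ag), tn = sum(!mg & !ag)),
            class = "confusion_counts")
}

# cell value = 1 iff >= 50% of the cell's pixels are stomate
discretize_mask <- function(mask, cell_size) {
  gr <- (seq_len(nrow(mask)) - 1) %/% cell_size
  gc <- (seq_len(ncol(mask)) - 1) %/% cell_size
  sums <- rowsum(t(rowsum(mask * 1, gr, reorder = TRUE)), gc, reorder = TRUE)
  cnts <- rowsum(t(rowsum(mask * 0 + 1, gr, reorder = TRUE)), gc,
                 reorder = TRUE)
  t(sums / cnts) >= 0.5
}

#' Precision and recall from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`. A zero
#' denominator makes the corresponding metric undefined and is reported as
#' NA.
#'
#' @param counts a `confusion_counts` (or list with tp/fp/fn).
#' @return named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(counts) {
  p <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp)
       else NA_real_
  r <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn)
       else NA_real_
  c(precision = p, recall = r)
}

#' F-score (harmonic mean of precision and recall)
#'
#' @param precision,recall fractions in \[0, 1\], not both zero.
#' @return `2 * P * R / (P + R)`; NA when both inputs are zero or either is
#'   NA. Report tables round to 5 decimals.
#' @export
f_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision == 0 && recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Average per-image detection metrics
#'
#' Unweighted arithmetic means over images — each micrograph counts equally
#' regardless of how many stomata it holds.
#'
#' @param rows data frame with columns `precision`, `recall`, `fscore`.
#' @param digits decimals for the reported means (default 3).
#' @return named numeric vector of mean precision, recall and F-score.
#' @export
aggregate_metrics <- function(rows, digits = 3) {
  if (nrow(rows) < 1) stop("parameter error: no metric rows")
  round(c(precision = mean(rows$precision), recall = mean(rows$recall),
          fscore = mean(rows$fscore)), digits)
}

#' Per-source pore-accuracy bookkeeping
#'
#' For every source, counts how many pore estimates were produced and how
#' many of those are correct. Estimates whose status is not "accepted"
#' (both explicit no-detections and rejected-with-reason) count as
#' no-detections: the algorithm declined to measure them. The identities
#' `available = total - no_detections`, `correct = available - incorrect`
#' and `pct_correct = 100 * correct / available` hold for every row.
#'
#' On synthetic data the `correct` flag is typically "IoU of estimated and
#' true pore mask at least 0.5"; on real data it is a manual-review column.
#'
#' @param estimates data frame with columns `source_id`, `status`, and
#'   `correct` (logical; may be NA for non-accepted rows, must not be NA
#'   for accepted ones).
#' @return data frame of class rows: `source_id, total, no_detections,
#'   available, incorrect, correct, pct_correct` (percentage, 2 decimals).
#' @export
pore_accuracy_table <- function(estimates) {
  stopifnot(all(c("source_id", "status", "correct") %in% names(estimates)))
  bad <- estimates$status == "accepted" & is.na(estimates$correct)
  if (any(bad))
    stop("data error: missing correctness flag for ", sum(bad),
         " accepted estimate(s)")
  out <- lapply(split(estimates, estimates$source_id), function(d) {
    total <- nrow(d)
    nd <- sum(d$status != "accepted")
    avail <- total - nd
    inc <- sum(d$status == "accepted" & !d$correct)
    cor <- avail - inc
    data.frame(source_id = d$source_id[1], total = total,
               no_detections = nd, available = avail, incorrect = inc,
               correct = cor,
               pct_correct = if (avail > 0) round(100 * cor / avail, 2)
                             else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise a pore-accuracy table
#'
#' Two averaging bases are reported because they genuinely differ: the
#' pooled accuracy `100 * sum(correct) / sum(available)` and the unweighted
#' mean of the per-source percentages.
#'
#' @param table output of [pore_accuracy_table()].
#' @return named numeric vector with `total`, `available`, `correct`,
#'   `pct_pooled` and `pct_mean_rows`.
#' @export
pore_accuracy_summary <- function(table) {
  c(total = sum(table$total), available = sum(table$available),
    correct = sum(table$correct),
    pct_pooled = round(100 * sum(table$correct) / sum(table$available), 2),
    pct_mean_rows = round(mean(table$pct_correct, na.rm = TRUE), 2))
}

#' Write a detection-metrics CSV with a final AVERAGE row
#' @param rows data frame with `source_id, n_stomata, precision, recall,
#'   fscore`.
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(rows, path) {
  avg <- aggregate_metrics(rows)
  out <- rbind(
    data.frame(source_id = rows$source_id, n_stomata = rows$n_stomata,
               precision = round(rows$precision, 4),
               recall = round(rows$recall, 4),
               fscore = round(rows$fscore, 5)),
    data.frame(source_id = "AVERAGE", n_stomata = sum(rows$n_stomata),
               precision = avg[["precision"]], recall = avg[["recall"]],
               fscore = avg[["fscore"]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
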