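#' Published-style benchmark tables
#'
#' Two small reference tables of per-micrograph results from a published
#' stomata study of four species (grape, apricot, orange, periwinkle), each
#' imaged from leaf imprints mounted with a traditional and a modified
#' technique. They serve as fixed inputs for validating the metric
#' arithmetic in [f_score()], [aggregate_metrics()] and
#' [pore_accuracy_table()]: recomputing every derived column from the
#' printed primary columns must reproduce the printed values.
#'
#' `detection_benchmark()` holds per-image detection precision, recall and
#' F-score; `pore_benchmark()` holds per-image pore-estimation counts
#' (total, no-detections, incorrect) with the printed derived columns.
#'
#' @return a data frame (see Details).
#' @export
detection_benchmark <- function() {
  data.frame(
    species = rep(c("Vitis vinifera", "Prunus armeniaca",
                    "Citrus sinensis", "Vinca major"), each = 2),
    technique = rep(c("traditional", "modified"), 4),
    n_stomata = c(248, 207, 791, 917, 932, 1168, 406, 317),
    precision = c(0.6692, 0.7825, 0.7291, 0.7265, 0.7290, 0.9089,
                  0.8673, 0.8138),
    recall = c(0.9254, 0.9055, 0.7388, 0.7517, 0.9076, 0.8850,
               0.9095, 0.8943),
    fscore = c(0.77672, 0.83952, 0.73392, 0.73889, 0.80855, 0.89679,
               0.88790, 0.85215),
    stringsAsFactors = FALSE)
}

#' @rdname detection_benchmark
#' @export
pore_benchmark <- function() {
  data.frame(
    species = rep(c("Vitis vinifera", "Prunus armeniaca",
                    "Citrus sinensis", "Vinca major"), each = 2),
    technique = rep(c("traditional", "modified"), 4),
    total = c(200, 200, 177, 200, 200, 200, 200, 329),
    no_detections = c(21, 4, 28, 29, 20, 38, 4, 5),
    available = c(179, 196, 149, 171, 180, 162, 196, 324),
    incorrect = c(66, 43, 32, 17, 40, 62, 52, 97),
    correct = c(113, 153, 117, 154, 140, 100, 144, 227),
    pct_correct = c(63.13, 78.06, 78.52, 90.06, 77.77, 61.72, 73.47, 70.06),
    stringsAsFactors = FALSE)
}
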