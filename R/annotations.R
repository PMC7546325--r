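#' Read rectangular box annotations from CSV
#'
#' The annotation format is a UTF-8 CSV with header
#' `row0,col0,row1,col1,label`, one axis-aligned box per line. Boxes are
#' 0-based half-open pixel rectangles `[row0, row1) x [col0, col1)`, so a
#' box's area is exactly `(row1 - row0) * (col1 - col0)`.
#'
#' @param path CSV file path.
#' @param source_id identifier attached to the annotation set.
#' @return object of class `box_annotation`: a list with `boxes` (data frame
#'   `row0,col0,row1,col1,label`) and `source_id`.
#' @export
read_annotations <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row0", "col0", "row1", "col1", "label")
  if (!all(need %in% names(df)))
    stop("parse error: annotation header must be 'row0,col0,row1,col1,label'")
  if (nrow(df) > 0) {
    bad <- which(!(df$row1 > df$row0 & df$col1 > df$col0))
    if (length(bad))
      stop("parse error: degenerate box at line ", bad[1] + 1)
    for (col in need[1:4])
      if (any(is.na(df[[col]])))
        stop("parse error: non-numeric value at line ",
             which(is.na(df[[col]]))[1] + 1)
  }
  structure(list(boxes = df[, need], source_id = source_id),
            class = "box_annotation")
}

#' Write box annotations to CSV
#' @param annotation a `box_annotation` or a data frame of boxes with columns
#'   `row0,col0,row1,col1` and optionally `label`.
#' @param path output path.
#' @export
write_annotations <- function(annotation, path) {
  df <- if (inherits(annotation, "box_annotation")) annotation$boxes
        else as.data.frame(annotation)
  if (is.null(df$label)) df$label <- "stomate"
  utils::write.csv(df[, c("row0", "col0", "row1", "col1", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export per-stomate pore measurements
#'
#' Writes a per-stomate CSV (`source_id, box_row0..box_col1, status,
#' polarity, area_px, area_um2`) and a run-level JSON with a config echo and
#' status counts. Output is byte-stable: rerunning on identical inputs
#' produces identical files.
#'
#' @param estimates list of [pore_estimate] objects, one per box.
#' @param boxes data frame of detection boxes (`row0,col0,row1,col1`).
#' @param source_id scan identifier.
#' @param csv_path,json_path output file paths (either may be NULL to skip).
#' @param config the run configuration echoed into the JSON.
#' @return the per-stomate results data frame, invisibly.
#' @export
write_results <- function(estimates, boxes, source_id, csv_path,
                          json_path = NULL, config = stoma_config()) {
  df <- results_frame(estimates, boxes, source_id)
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    run <- list(
      source_id = source_id,
      counts = as.list(table(factor(df$status,
        levels = c("accepted", "no_detection", "rejected")))),
      total_area_um2 = sum(df$area_um2, na.rm = TRUE),
      config = config)
    jsonlite::write_json(run, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(df)
}

results_frame <- function(estimates, boxes, source_id) {
  stopifnot(length(estimates) == nrow(boxes))
  data.frame(
    source_id = rep(source_id, nrow(boxes)),
    box_row0 = boxes$row0, box_col0 = boxes$col0,
    box_row1 = boxes$row1, box_col1 = boxes$col1,
    status = vapply(estimates, function(e) e$status, character(1)),
    polarity = vapply(estimates, function(e) e$polarity, character(1)),
    area_px = vapply(estimates, function(e)
      if (is.na(e$area_px)) NA_real_ else e$area_px, numeric(1)),
    area_um2 = vapply(estimates, function(e)
      if (is.na(e$area_um2)) NA_real_ else e$area_um2, numeric(1)),
    reason = vapply(estimates, function(e)
      if (is.null(e$reason)) "" else e$reason, character(1)),
    stringsAsFactors = FALSE)
}

#' Read back a per-stomate results CSV written by [write_results()]
#' @param path CSV path.
#' @return data frame with the result rows.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(source_id = "character",
                                 status = "character",
                                 polarity = "character"))
}
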