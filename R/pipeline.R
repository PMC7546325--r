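#' Train a detector from synthetic scenes
#'
#' Generates `n_scenes` seeded training scenes, samples labelled patches
#' from each, and fits the default quadratic-SVM classifier on
#' gradient-orientation-histogram features.
#'
#' @param n_scenes number of training scenes.
#' @param n_per_class total training patches per class (split across
#'   scenes).
#' @param base_spec a [scene_spec()] used as the template; each scene gets
#'   seed `base_spec$seed + i`.
#' @param config a [stoma_config()] (window size is taken from here).
#' @param seed RNG seed for patch sampling and SVM fitting.
#' @return a `stomate_classifier`.
#' @export
train_from_scenes <- function(n_scenes = 6, n_per_class = 150,
                              base_spec = scene_spec(),
                              config = stoma_config(), seed = 1) {
  per_scene <- ceiling(n_per_class / n_scenes)
  patches <- list()
  for (i in seq_len(n_scenes)) {
    sp <- base_spec
    sp$seed <- base_spec$seed + i
    scene <- generate_scene(sp)
    patches <- c(patches,
                 make_training_patches(scene, config$window_size, per_scene,
                                       seed = seed + i))
  }
  # trim to exactly n_per_class of each label
  labs <- vapply(patches, `[[`, character(1), "label")
  keep <- unlist(lapply(unique(labs), function(l)
    which(labs == l)[seq_len(min(n_per_class, sum(labs == l)))]))
  train_patch_classifier(patches[sort(keep)],
                         hog_extractor(config$window_size), seed = seed)
}

#' Run the full pipeline on one scan
#'
#' Detection (tiled sliding-window classification and box extraction)
#' followed by per-stomate pore measurement and optional result export.
#' The pipeline is deterministic: identical image, model and config yield
#' byte-identical result files.
#'
#' @param image a [scan_image()].
#' @param model a `stomate_classifier`.
#' @param config a [stoma_config()].
#' @param out_dir if non-NULL, writes `results.csv` and `run.json` here.
#' @return list with `boxes`, `mask`, `estimates` and the per-stomate
#'   `results` data frame.
#' @export
run_pipeline <- function(image, model, config = stoma_config(),
                         out_dir = NULL) {
  det <- detect_stomata(image, model, config)
  est <- measure_pores(image, det$boxes, config)
  res <- results_frame(est, det$boxes, image$source_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(est, det$boxes, image$source_id,
                  file.path(out_dir, "results.csv"),
                  file.path(out_dir, "run.json"), config)
  }
  list(boxes = det$boxes, mask = det$mask, estimates = est, results = res)
}

#' Paint a set of boxes as a binary mask
#' @param boxes data frame with `row0,col0,row1,col1` (0-based half-open).
#' @param shape `c(height, width)`.
#' @return logical matrix.
#' @export
boxes_to_mask <- function(boxes, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (k in seq_len(nrow(boxes)))
    m[(boxes$row0[k] + 1):boxes$row1[k],
      (boxes$col0[k] + 1):boxes$col1[k]] <- TRUE
  m
}

#' Ground-truth bounding boxes of a synthetic scene
#' @param scene a `ground_truth_scene`.
#' @return data frame `row0,col0,row1,col1` (one row per stomate).
#' @export
true_boxes <- function(scene) {
  do.call(rbind, lapply(scene$stomata, function(st)
    data.frame(row0 = st$bbox[1], col0 = st$bbox[2],
               row1 = st$bbox[3], col1 = st$bbox[4])))
}

#' Score detections against a ground-truth scene
#'
#' Grid-discretised comparison in the style of manual-versus-automatic
#' labelling: the manual mask is the union of the scene's true stomate
#' bounding boxes, the automatic mask the union of the detected boxes, and
#' both are discretised onto `cell_size` cells (see [discretize_compare()]).
#'
#' @param scene a `ground_truth_scene`.
#' @param boxes detection boxes from [detect_stomata()].
#' @param cell_size evaluation grid cell in px; should resolve the smallest
#'   stomate.
#' @return a `confusion_counts`.
#' @export
score_detection <- function(scene, boxes, cell_size = 16) {
  shape <- dim(scene$image$pixels)[1:2]
  discretize_compare(boxes_to_mask(true_boxes(scene), shape),
                     boxes_to_mask(boxes, shape), cell_size)
}

#' Intersection-over-union of two binary masks
#' @param a,b logical matrices of equal shape.
#' @return IoU in \[0, 1\]; NA when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
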