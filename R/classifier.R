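#' The three patch classes
#' @keywords internal
PATCH_CLASSES <- c("background", "stomate", "vein")

#' Train the three-class patch classifier
#'
#' Fits a quadratic-kernel support vector machine (polynomial kernel of
#' degree 2) on feature vectors for the classes stomate, vein and
#' background. The vein class exists to absorb the most stomate-like
#' negatives; at box extraction it is folded into "not stomate".
#'
#' @param features numeric matrix, one row per training example.
#' @param labels character/factor of class names, one per row; all three
#'   classes must be present.
#' @param extractor the [feature_extractor] that produced `features`;
#'   recorded so the model refuses mismatched vectors later.
#' @param cost SVM cost parameter.
#' @param class_weights per-class misclassification weights. The default
#'   up-weights the two negative classes: a background or vein window
#'   misread as "stomate" seeds a false detection box, which is costlier
#'   than one missed window of a stomate that neighbouring windows still
#'   catch.
#' @param seed integer; fixed before fitting so training is reproducible.
#' @return object of class `stomate_classifier`.
#' @export
train_classifier <- function(features, labels, extractor, cost = 100,
                             class_weights = c(background = 1.5,
                                               stomate = 1, vein = 1.5),
                             seed = 1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  missing <- setdiff(PATCH_CLASSES, unique(labels))
  if (length(missing))
    stop("training-data error: no examples for class(es): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(features)))
    stop("training-data error: non-finite feature values")
  y <- factor(labels, levels = PATCH_CLASSES)
  set.seed(seed)
  fit <- e1071::svm(features, y, kernel = "polynomial", degree = 2,
                    coef0 = 1, cost = cost, scale = FALSE,
                    class.weights = class_weights)
  structure(list(kind = "quadratic-kernel SVM", fit = fit,
                 classes = PATCH_CLASSES, extractor = extractor,
                 extractor_id = extractor$id,
                 window_size = extractor$window_size),
            class = "stomate_classifier")
}

#' Train a classifier directly from labelled patches
#'
#' Convenience wrapper: extracts features from each patch with `extractor`
#' and calls [train_classifier()].
#'
#' @param patches list of labelled patches (`pixels`, `label`), e.g. from
#'   [make_training_patches()].
#' @inheritParams train_classifier
#' @export
train_patch_classifier <- function(patches, extractor = NULL, cost = 100,
                                   seed = 1) {
  stopifnot(length(patches) > 0)
  if (is.null(extractor))
    extractor <- hog_extractor(nrow(patches[[1]]$pixels))
  feats <- t(vapply(patches, function(p) extract_features(extractor, p$pixels),
                    numeric(extractor$length)))
  train_classifier(feats, vapply(patches, `[[`, character(1), "label"),
                   extractor, cost = cost, seed = seed)
}

#' Predict classes for a feature matrix
#'
#' @param model a `stomate_classifier`.
#' @param features numeric matrix with the model's feature length.
#' @param extractor_id optional id of the extractor that produced `features`;
#'   a mismatch with the model's extractor is an error.
#' @return character vector of class names.
#' @export
predict_classes <- function(model, features, extractor_id = NULL) {
  if (!is.null(extractor_id) && !identical(extractor_id, model$extractor_id))
    stop("feature vectors come from extractor '", extractor_id,
         "' but the model was trained with '", model$extractor_id, "'")
  features <- if (is.matrix(features)) features else matrix(features, 1)
  as.character(stats::predict(model$fit, features))
}

#' Save / load a trained classifier
#'
#' The archive stores the fitted SVM together with its extractor id, window
#' size and class list; [load_classifier()] refuses an archive whose
#' configuration does not match what the caller expects.
#'
#' @param model a `stomate_classifier`.
#' @param path file path for the model archive.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "stomate_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @param expected_extractor_id,expected_window_size if non-NULL, the loaded
#'   model must match, otherwise an error is raised.
#' @export
load_classifier <- function(path, expected_extractor_id = NULL,
                            expected_window_size = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "stomate_classifier"))
    stop("not a classifier archive: ", path)
  if (!is.null(expected_extractor_id) &&
      !identical(model$extractor_id, expected_extractor_id))
    stop("model extractor '", model$extractor_id,
         "' does not match expected '", expected_extractor_id, "'")
  if (!is.null(expected_window_size) &&
      model$window_size != expected_window_size)
    stop("model window size ", model$window_size,
         " does not match expected ", expected_window_size)
  model
}

#' @export
print.stomate_classifier <- function(x, ...) {
  cat(sprintf("<stomate_classifier> %s, %d support vectors, extractor %s (window %d px)\n",
              x$kind, x$fit$tot.nSV, x$extractor_id, x$window_size))
  invisible(x)
}
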