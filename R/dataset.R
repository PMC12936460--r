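#' Labelled image dataset
#'
#' The basic container moved through every stage of the simulator: a list of
#' equally shaped pixel arrays plus one class label per image. Pixel values
#' are 8-bit integers in \[0, 255\] as loaded or generated, and become
#' fractions in \[0, 1\] after [normalize_pixels()].
#'
#' @param images list of numeric arrays, all of one shape
#'   `height x width x channels`. Plain `height x width` matrices are
#'   promoted to single-channel arrays.
#' @param labels character vector of class names, one per image.
#' @param class_names ordered class vocabulary. Defaults to the sorted
#'   unique labels so that the index order ("normal" before "pneumonia")
#'   never depends on file ordering.
#'
#' @return An object of class `labelled_dataset` with fields `images`,
#'   `labels` and `class_names`.
#' @export
labelled_dataset <- function(images, labels,
                             class_names = sort(unique(labels))) {
  if (!is.list(images)) stop("`images` must be a list of arrays")
  if (length(images) != length(labels)) {
    stop("`images` and `labels` lengths differ (",
         length(images), " vs ", length(labels), ")")
  }
  images <- lapply(images, function(im) {
    if (is.matrix(im)) dim(im) <- c(dim(im), 1L)
    if (length(dim(im)) != 3L) {
      stop("each image must be a matrix or a 3-d array")
    }
    im
  })
  if (length(images) > 0L) {
    shp <- dim(images[[1L]])
    ok <- vapply(images, function(im) identical(dim(im), shp), logical(1))
    if (!all(ok)) {
      stop("all images must share one shape; image ", which(!ok)[1L],
           " differs")
    }
  }
  labels <- as.character(labels)
  if (!all(labels %in% class_names)) {
    bad <- setdiff(labels, class_names)[1L]
    stop("label not in class vocabulary: '", bad, "'")
  }
  structure(
    list(images = images, labels = labels,
         class_names = as.character(class_names)),
    class = "labelled_dataset"
  )
}

#' @export
length.labelled_dataset <- function(x) length(x$images)

#' @export
print.labelled_dataset <- function(x, ...) {
  shp <- if (length(x) > 0L) paste(dim(x$images[[1L]]), collapse = "x")
         else "empty"
  cnt <- table(factor(x$labels, levels = x$class_names))
  cat("<labelled_dataset> ", length(x), " images (", shp, "); classes: ",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# subset by integer indices, preserving vocabulary
dataset_subset <- function(dataset, idx) {
  labelled_dataset(dataset$images[idx], dataset$labels[idx],
                   class_names = dataset$class_names)
}

#' Image shape of a dataset
#'
#' @param dataset a non-empty [labelled_dataset()].
#' @return integer vector `(height, width, channels)`.
#' @export
dataset_shape <- function(dataset) {
  if (length(dataset) == 0L) stop("dataset is empty")
  dim(dataset$images[[1L]])
}

#' Flatten a dataset into model-ready tensors
#'
#' Flattens each image in row-major order (row slowest, column next,
#' channel fastest — the usual C order of image tensors) into one row of a
#' design matrix, and one-hot encodes the labels. The flattening order is
#' part of the package contract: checkpointed first-layer weights are tied
#' to it.
#'
#' @param dataset a [labelled_dataset()], normally already normalized.
#' @return list with `x` (n x input_dim matrix) and `y` (n x n_classes
#'   one-hot matrix).
#' @export
dataset_tensors <- function(dataset) {
  n <- length(dataset)
  if (n == 0L) stop("dataset is empty")
  d <- prod(dataset_shape(dataset))
  x <- matrix(0, n, d)
  for (i in seq_len(n)) {
    x[i, ] <- as.numeric(aperm(dataset$images[[i]], c(3L, 2L, 1L)))
  }
  list(x = x, y = one_hot_encode(dataset$labels, dataset$class_names))
}
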