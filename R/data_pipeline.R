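#' Load a class-labelled image directory
#'
#' Reads an image tree laid out in the common Kaggle chest X-ray convention
#' `<root>/<CLASS_NAME>/<file>` (class subdirectory names are lowercased to
#' form the vocabulary), resizes every image to a common size, and returns
#' the pixels on the raw 0--255 scale. Files are visited in lexicographic
#' path order so the dataset ordering is identical across filesystems;
#' randomization is left to the seeded shuffle of [split_train_test()].
#'
#' Resizing uses bilinear interpolation and the result is rounded back to
#' integers, keeping 8-bit pixel semantics end to end (an image already at
#' the target size passes through untouched). Undecodable files are skipped
#' with a warning and counted in the `n_skipped` attribute.
#'
#' @param root_path directory containing one subdirectory per class.
#' @param image_size integer `(height, width)` target, e.g. `c(28, 28)`.
#' @param channels 1 for grayscale, 3 to replicate/keep RGB.
#' @return a [labelled_dataset()] with integer pixel values in \[0, 255\].
#' @export
load_image_dir <- function(root_path, image_size = c(28L, 28L),
                           channels = 1L) {
  if (!dir.exists(root_path)) stop("no such directory: ", root_path)
  stopifnot(length(image_size) == 2L, all(image_size >= 1L))
  if (!channels %in% c(1L, 3L)) stop("`channels` must be 1 or 3")
  class_dirs <- sort(list.dirs(root_path, recursive = FALSE))
  if (length(class_dirs) == 0L) {
    stop("no class subdirectories under ", root_path)
  }
  images <- list(); labels <- character(0); skipped <- 0L
  for (cd in class_dirs) {
    cls <- tolower(basename(cd))
    files <- sort(list.files(cd, full.names = TRUE,
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE))
    for (f in files) {
      im <- tryCatch(read_image_file(f), error = function(e) NULL)
      if (is.null(im)) {
        warning("skipping undecodable image: ", f)
        skipped <- skipped + 1L
        next
      }
      images[[length(images) + 1L]] <-
        conform_image(im, image_size, channels)
      labels <- c(labels, cls)
    }
  }
  if (length(images) == 0L) stop("no decodable images under ", root_path)
  ds <- labelled_dataset(images, labels,
                         class_names = sort(tolower(basename(class_dirs))))
  attr(ds, "n_skipped") <- skipped
  ds
}

# read one PNG/JPEG as an h x w x c array of integers in [0, 255]
read_image_file <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    im <- png::readPNG(path)
  } else {
    # EBImage stores width-first; transpose back to row x column
    e <- EBImage::imageData(EBImage::readImage(path))
    im <- if (length(dim(e)) == 2L) t(e) else aperm(e, c(2L, 1L, 3L))
  }
  if (is.matrix(im)) dim(im) <- c(dim(im), 1L)
  if (dim(im)[3L] == 4L) im <- im[, , 1:3, drop = FALSE]  # drop alpha
  round(im * 255)
}

# resize to (h, w) and adapt the channel count
conform_image <- function(im, image_size, channels) {
  h <- dim(im)[1L]; w <- dim(im)[2L]; c0 <- dim(im)[3L]
  if (channels == 1L && c0 == 3L) {
    im <- array(rowMeans(matrix(im, h * w, 3L)), dim = c(h, w, 1L))
    im <- round(im)
  } else if (channels == 3L && c0 == 1L) {
    im <- array(rep(im, 3L), dim = c(h, w, 3L))
  }
  if (h != image_size[1L] || w != image_size[2L]) {
    out <- array(0, dim = c(image_size[1L], image_size[2L], channels))
    for (k in seq_len(channels)) {
      rz <- EBImage::resize(EBImage::Image(t(im[, , k]) / 255),
                            w = image_size[2L], h = image_size[1L],
                            filter = "bilinear")
      out[, , k] <- round(t(EBImage::imageData(rz)) * 255)
    }
    im <- out
  }
  # guard against interpolation overshoot at boundaries
  im[im < 0] <- 0; im[im > 255] <- 255
  im
}

#' Rescale 8-bit pixels to the unit interval
#'
#' Divides every pixel by 255, the standard preprocessing step for
#' 8-bit radiographs. The input must be integer-valued in \[0, 255\]:
#' applying the function twice is thereby rejected rather than silently
#' shrinking the data. An input whose values are all 0/1 (e.g. a binary
#' mask) is accepted with a warning.
#'
#' @param dataset a [labelled_dataset()] on the 0--255 scale.
#' @return the dataset with every pixel in \[0, 1\].
#' @export
normalize_pixels <- function(dataset) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  all01 <- TRUE
  for (i in seq_along(dataset$images)) {
    v <- dataset$images[[i]]
    bad <- which(v < 0 | v > 255 | v != floor(v))
    if (length(bad) > 0L) {
      stop("pixel not an integer in [0, 255] at image ", i,
           ", flat index ", bad[1L], " (value ", v[bad[1L]], ")")
    }
    if (all01 && any(v > 1)) all01 <- FALSE
  }
  if (all01 && length(dataset) > 0L) {
    warning("all pixel values are 0/1; treating as 8-bit anyway ",
            "(binary mask?)")
  }
  dataset$images <- lapply(dataset$images, function(im) im / 255)
  dataset
}

#' One-hot encode class labels
#'
#' @param labels character vector of class names.
#' @param class_names ordered class vocabulary.
#' @return an `n x length(class_names)` 0/1 matrix; row i has a single 1 at
#'   the vocabulary position of `labels[i]`. Columns are named by class.
#' @export
one_hot_encode <- function(labels, class_names) {
  labels <- as.character(labels)
  idx <- match(labels, class_names)
  if (anyNA(idx)) {
    stop("unknown label: '", labels[which(is.na(idx))[1L]], "'")
  }
  y <- matrix(0, length(labels), length(class_names),
              dimnames = list(NULL, class_names))
  y[cbind(seq_along(idx), idx)] <- 1
  y
}

#' Invert a one-hot matrix back to labels
#'
#' @param y one-hot matrix (each row sums to 1).
#' @param class_names vocabulary in column order.
#' @return character vector of labels.
#' @export
one_hot_decode <- function(y, class_names) {
  if (!all(rowSums(y) == 1) || !all(y %in% c(0, 1))) {
    stop("`y` is not a one-hot matrix")
  }
  class_names[max.col(y, ties.method = "first")]
}

#' Shuffle and split into train and test sets
#'
#' Applies a seeded permutation to the whole dataset and takes the first
#' `round(ratio * n)` images as the training set, the rest as the central
#' test set — the plain (unstratified) shuffle-then-split used throughout
#' the simulator, with a 90:10 default.
#'
#' @param dataset a [labelled_dataset()].
#' @param ratio train fraction in (0, 1); default 0.9.
#' @param seed integer controlling the shuffle; default 42.
#' @return an object of class `split_pair`: list with `train`, `test`,
#'   `ratio`, `seed`.
#' @export
split_train_test <- function(dataset, ratio = 0.9, seed = 42L) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  if (!(is.numeric(ratio) && length(ratio) == 1L && ratio > 0 && ratio < 1)) {
    stop("`ratio` must lie strictly between 0 and 1")
  }
  n <- length(dataset)
  if (n < 2L) stop("need at least 2 images to split")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_train <- round(ratio * n)
  n_train <- max(1L, min(n - 1L, n_train))  # both sides non-empty
  structure(
    list(train = dataset_subset(dataset, perm[seq_len(n_train)]),
         test  = dataset_subset(dataset, perm[(n_train + 1L):n]),
         ratio = ratio, seed = as.integer(seed)),
    class = "split_pair"
  )
}

#' @export
print.split_pair <- function(x, ...) {
  cat("<split_pair> train=", length(x$train), " test=", length(x$test),
      " (ratio ", x$ratio, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a dataset manifest
#'
#' @param split a `split_pair` from [split_train_test()].
#' @param path CSV output path; columns `index,class,split`.
#' @return the path, invisibly.
#' @export
write_manifest <- function(split, path) {
  df <- rbind(
    data.frame(index = seq_along(split$train$labels),
               class = split$train$labels, split = "train"),
    data.frame(index = seq_along(split$test$labels),
               class = split$test$labels, split = "test")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
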