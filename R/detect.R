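#' Per-column layer-integrity profile
#'
#' Flags the columns of a sublayer segmentation in which at least one of the
#' five sublayers is effectively undetectable: a column is affected when any
#' sublayer class occupies fewer than `t_min` pixels there. This
#' operationalises the definition of the severely affected region.
#'
#' On a ground-truth [label_mask()] the thickness of a layer in a column is
#' its pixel count and the default `t_min = 1` flags exactly-zero thickness.
#' On a probability map the soft thickness (per-column sum of the class
#' probabilities) is used instead, which is robust to the one-pixel
#' transition bands a convolutional segmenter paints across layer
#' boundaries. `t_min = "adaptive"` sets a per-layer threshold of 0.6 times
#' that scan's median column thickness, so a layer is flagged where it is
#' substantially thinner than it is elsewhere in the same scan --
#' scale-free, and the recommended setting on predicted maps.
#'
#' @param x A sublayer [label_mask()] or a height x width x 6 probability
#'   array.
#' @param t_min Minimum thickness (pixels) for a sublayer to count as
#'   present: a scalar, a length-5 per-layer vector, or `"adaptive"`.
#' @return A logical vector with one flag per column.
#' @export
column_integrity_profile <- function(x, t_min = 1) {
  if (is.array(x) && length(dim(x)) == 3) {
    thickness <- vapply(1:5, function(k) colSums(x[, , k + 1]),
                        numeric(dim(x)[2]))
  } else {
    labels <- unclass(x)
    thickness <- vapply(1:5, function(k) colSums(labels == k),
                        numeric(ncol(labels)))
  }
  if (identical(t_min, "adaptive")) {
    t_min <- 0.6 * apply(thickness, 2, stats::median)
  }
  t_min <- rep_len(t_min, 5L)
  rowSums(sweep(thickness, 2, t_min, "<")) > 0
}

#' Merge affected columns into a single box
#'
#' Multiple small affected regions are grouped together within a single
#' larger orthogonal box spanning the first to the last affected column;
#' its rows cover the retinal band. The box confidence is the fraction of
#' columns inside the box that are actually flagged.
#'
#' @param affected Logical per-column flags (see
#'   [column_integrity_profile()]).
#' @param row_extent `c(y_start, y_end)` rows of the retinal band
#'   (half-open).
#' @param image_id Optional scan identifier.
#' @return A one-row box tibble, or `NULL` when no column is flagged.
#' @export
merge_single_box <- function(affected, row_extent, image_id = NA_character_) {
  idx <- which(affected)
  if (length(idx) == 0) return(NULL)
  x_start <- min(idx) - 1
  x_end <- max(idx)
  box_annotation(
    x_start, x_end, row_extent[1], row_extent[2],
    confidence = length(idx) / (x_end - x_start),
    image_id = image_id
  )
}

#' Rule-based detector for the severely affected region
#'
#' Desk-scale detection stage: segment the sublayers, flag columns where a
#' sublayer is effectively undetectable in the predicted probability map
#' (adaptive soft-thickness threshold by default, see
#' [column_integrity_profile()]), and merge the flagged columns into a
#' single box whose rows cover the predicted retinal band. The outermost
#' `trim` columns are ignored, as zero padding degrades predictions there.
#' Emits at most one scored box per scan.
#'
#' @param image A grayscale B-scan matrix in `[0, 1]`.
#' @param segmenter A fitted sublayer segmenter (see [train_sublayers()]).
#' @param t_min Thickness threshold, see [column_integrity_profile()].
#' @param trim Number of border columns excluded from flagging.
#' @param image_id Optional scan identifier.
#' @return A tibble of detections (zero or one row).
#' @export
rule_based_detector <- function(image, segmenter, t_min = "adaptive",
                                trim = 2L, image_id = NA_character_) {
  probs <- predict(segmenter, image)
  labels <- prob_argmax(probs)
  affected <- column_integrity_profile(probs, t_min = t_min)
  if (trim > 0) {
    W <- length(affected)
    affected[c(seq_len(trim), W + 1L - seq_len(trim))] <- FALSE
  }
  box <- merge_single_box(affected, retina_row_extent(labels),
                          image_id = image_id)
  if (is.null(box)) return(empty_detections())
  # score the box by how much of it is meaningfully thinned: the fraction
  # of its columns whose thinnest layer is below 0.9x the scan's median
  thickness <- vapply(1:5, function(k) colSums(probs[, , k + 1]),
                      numeric(ncol(image)))
  med <- pmax(apply(thickness, 2, stats::median), 1e-6)
  ratio <- apply(sweep(thickness, 2, med, "/"), 1, min)
  cols <- (floor(box$x_start) + 1):ceiling(box$x_end)
  box$confidence <- mean(ratio[cols] < 0.9)
  box
}

empty_detections <- function() {
  tibble::tibble(
    image_id = character(0), x_start = numeric(0), x_end = numeric(0),
    y_start = numeric(0), y_end = numeric(0), confidence = numeric(0)
  )
}

# per-column intensity-profile features for the learned detector head
column_features <- function(image) {
  qs <- t(apply(image, 2, stats::quantile, probs = c(0.1, 0.5, 0.9)))
  bins <- t(apply(image, 2, function(col) {
    tabulate(findInterval(col, c(0.2, 0.4, 0.6, 0.8)) + 1L, nbins = 5L)
  })) / nrow(image)
  f <- cbind(colMeans(image), apply(image, 2, sd), qs, bins)
  cbind(f, apply(f, 2, moving_average, w = 7L))
}

moving_average <- function(x, w) {
  k <- rep(1 / w, w)
  as.vector(stats::filter(x, k, sides = 2)) |>
    (\(z) { z[is.na(z)] <- x[is.na(z)]; z })()
}

#' Train a learned detector for the severely affected region
#'
#' A lightweight learned alternative to [rule_based_detector()]: a logistic
#' region head over per-column intensity-profile features (column mean, sd,
#' quantiles and intensity-bin histogram, each with a smoothed copy),
#' trained to classify columns as inside/outside the annotated box. At
#' prediction time the per-column probabilities are smoothed, thresholded at
#' 0.5 and merged into a single box; the box confidence is the mean column
#' probability inside it. The fit is deterministic (iteratively reweighted
#' least squares), so identical data give identical predictions.
#'
#' @param images List of grayscale B-scan matrices.
#' @param boxes List (parallel to `images`) of ground-truth box tibbles or
#'   `NULL` for lesion-free scans.
#' @param config Optional list; `smooth` (columns, default 5) and
#'   `threshold` (default 0.5) tune prediction.
#' @return An object of class `learned_detector` with a
#'   `predict(object, image)` method returning a detections tibble.
#' @export
train_learned_detector <- function(images, boxes, config = list()) {
  if (length(images) == 0) abort("Empty training set.")
  stopifnot(length(boxes) == length(images))
  config <- modify_defaults(list(smooth = 5L, threshold = 0.5), config)
  feats <- list()
  labels <- list()
  for (i in seq_along(images)) {
    f <- column_features(images[[i]])
    y <- rep(0, ncol(images[[i]]))
    b <- boxes[[i]]
    if (!is.null(b) && nrow(b) > 0) {
      y[(floor(b$x_start[1]) + 1):ceiling(b$x_end[1])] <- 1
    }
    feats[[i]] <- f
    labels[[i]] <- y
  }
  X <- do.call(rbind, feats)
  y <- unlist(labels)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$y <- y
  fit <- suppressWarnings(
    glm(y ~ ., data = df, family = binomial(), control = list(maxit = 100))
  )
  structure(
    list(fit = fit, config = config, n_features = ncol(X)),
    class = c("learned_detector", "pathaware_detector")
  )
}

#' Predict the severely affected region with a learned detector
#'
#' @param object A [train_learned_detector()] fit.
#' @param image A grayscale B-scan matrix.
#' @param image_id Optional scan identifier.
#' @param ... Unused.
#' @return A tibble of detections (zero or one row).
#' @export
predict.learned_detector <- function(object, image,
                                     image_id = NA_character_, ...) {
  df <- as.data.frame(column_features(image))
  names(df) <- paste0("f", seq_len(ncol(df)))
  p <- suppressWarnings(
    as.vector(predict(object$fit, newdata = df, type = "response"))
  )
  p <- moving_average(p, object$config$smooth)
  affected <- p > object$config$threshold
  if (!any(affected)) return(empty_detections())
  # rows: the bright retinal band, estimated from smoothed row intensity
  row_means <- as.vector(stats::filter(rowMeans(image), rep(1 / 5, 5),
                                       sides = 2))
  bright <- which(!is.na(row_means) & row_means > 0.15)
  extent <- if (length(bright)) c(min(bright) - 1, max(bright)) else
    c(0, nrow(image))
  box <- merge_single_box(affected, extent, image_id = image_id)
  box$confidence <- mean(p[(floor(box$x_start) + 1):ceiling(box$x_end)])
  box
}
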