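#' Expand a box annotation into a full-height exclusion mask
#'
#' The pathology-aware losses exclude the severely affected region via a
#' binary mask that is 0 inside the box and 1 elsewhere. The mask height is
#' extended to span the entire image, so only pixels to the left and right
#' of the box contribute to the loss.
#'
#' @param box A one-row box tibble (see [box_annotation()]) or `NULL`.
#' @param height,width Image size.
#' @return A `height` x `width` 0/1 matrix (all ones when `box` is `NULL`).
#' @export
box_to_mask <- function(box, height, width) {
  mask <- matrix(1, nrow = height, ncol = width)
  if (is.null(box) || nrow(box) == 0) return(mask)
  box <- box[1, ]
  if (box$x_start < 0 || box$x_end > width || box$x_start >= box$x_end) {
    abort("Box columns outside the image.")
  }
  if (box$y_start < 0 || box$y_end > height) {
    abort("Box rows outside the image.")
  }
  cols <- (floor(box$x_start) + 1):ceiling(box$x_end)
  mask[, cols] <- 0
  mask
}

as_label_matrix <- function(labels) {
  matrix(as.integer(labels), nrow = nrow(labels), ncol = ncol(labels))
}

check_prob_array <- function(probs, labels) {
  d <- dim(probs)
  if (length(d) != 3) abort("`probs` must be a height x width x classes array.")
  if (!is.null(labels) && !all(d[1:2] == dim(labels))) {
    abort("`probs` and `labels` shapes differ.")
  }
  sums <- apply(probs, c(1, 2), sum)
  if (max(abs(sums - 1)) > 1e-6) {
    abort("Per-pixel class probabilities must sum to 1 (tolerance 1e-6).")
  }
  invisible(probs)
}

prob_of_truth <- function(probs, labels) {
  d <- dim(probs)
  npix <- d[1] * d[2]
  probs[seq_len(npix) + as.vector(labels) * npix]
}

LOSS_EPS <- 1e-7

#' Cross-entropy loss
#'
#' Mean negative log-likelihood of the true class over all `N` pixels,
#' `-(1/N) sum_i y_i log(yhat_i)`. Probabilities are clamped at `1e-7` for
#' numerical safety.
#'
#' @param probs A height x width x classes probability array.
#' @param labels An integer label matrix (0-based classes).
#' @return A non-negative scalar.
#' @export
cross_entropy <- function(probs, labels) {
  masked_cross_entropy(probs, labels, mask = NULL)
}

#' Dice loss
#'
#' Soft Dice loss `1 - 2 sum(y yhat) / (sum(y) + sum(yhat))`, computed
#' one-vs-rest per class and averaged over classes. Background (class 0) is
#' excluded from the average by default, and a class absent from both the
#' ground truth and the prediction is skipped.
#'
#' @inheritParams cross_entropy
#' @param classes Integer classes to average over; default all non-background
#'   classes of `probs`.
#' @return A scalar in `[0, 1]`.
#' @export
dice_loss <- function(probs, labels, classes = NULL) {
  masked_dice_loss(probs, labels, mask = NULL, classes = classes)
}

#' Pathology-aware (masked) cross-entropy loss
#'
#' Cross-entropy restricted to the pixels outside the severely affected
#' region: `-(1/N) sum_i m_i y_i log(yhat_i)` with `m_i = 0` inside the
#' box's full-height column band. Masked pixels contribute exactly 0 (the
#' `0 log 0` convention), so predictions inside the box never influence the
#' loss. By default `N` counts all pixels in the batch (the literal
#' normalisation); `norm = "unmasked"` divides by the number of unmasked
#' pixels instead.
#'
#' @inheritParams cross_entropy
#' @param mask A 0/1 exclusion mask from [box_to_mask()], or `NULL` for all
#'   ones.
#' @param norm `"literal"` (divide by all pixels) or `"unmasked"` (divide by
#'   the unmasked pixel count).
#' @return A non-negative scalar.
#' @export
masked_cross_entropy <- function(probs, labels, mask,
                                 norm = c("literal", "unmasked")) {
  norm <- match.arg(norm)
  labels <- as_label_matrix(labels)
  check_prob_array(probs, labels)
  p <- pmax(prob_of_truth(probs, labels), LOSS_EPS)
  ll <- -log(p)
  if (!is.null(mask)) ll <- ll * as.vector(mask)
  denom <- if (is.null(mask) || norm == "literal") length(ll) else sum(mask)
  if (denom == 0) return(0)
  sum(ll) / denom
}

#' Pathology-aware (masked) Dice loss
#'
#' Soft Dice loss over the unmasked pixels only:
#' `1 - 2 sum(m y yhat) / (sum(m y) + sum(m yhat))`, one-vs-rest per class
#' and averaged over classes (background excluded by default). A class that
#' is fully masked or absent on both sides (zero denominator) contributes
#' nothing and is skipped.
#'
#' @inheritParams masked_cross_entropy
#' @param classes Integer classes to average over; default all non-background
#'   classes of `probs`.
#' @return A scalar in `[0, 1]` (0 when every class is skipped).
#' @export
masked_dice_loss <- function(probs, labels, mask, classes = NULL) {
  labels <- as_label_matrix(labels)
  check_prob_array(probs, labels)
  C <- dim(probs)[3]
  classes <- classes %||% seq_len(C - 1)
  m <- if (is.null(mask)) 1 else as.vector(mask)
  per_class <- vapply(classes, function(k) {
    y <- as.numeric(as.vector(labels) == k)
    p <- as.vector(probs[, , k + 1])
    denom <- sum(m * y) + sum(m * p)
    if (denom == 0) return(NA_real_)
    1 - 2 * sum(m * y * p) / denom
  }, numeric(1))
  per_class <- per_class[!is.na(per_class)]
  if (length(per_class) == 0) return(0)
  mean(per_class)
}

#' Combined segmentation loss
#'
#' The training loss is the sum of the cross-entropy and Dice components.
#' With an exclusion mask the pathology-aware variants are used; with
#' `mask = NULL` (or an all-ones mask) it reduces exactly to the standard
#' combined loss.
#'
#' @inheritParams masked_cross_entropy
#' @param classes Dice classes, see [masked_dice_loss()].
#' @return A list of class `loss_value` with `ce`, `dice` and `combined`.
#' @export
combined_loss <- function(probs, labels, mask = NULL,
                          norm = c("literal", "unmasked"), classes = NULL) {
  ce <- masked_cross_entropy(probs, labels, mask, norm = norm)
  dc <- masked_dice_loss(probs, labels, mask, classes = classes)
  structure(list(ce = ce, dice = dc, combined = ce + dc),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss: ce = %.6f, dice = %.6f, combined = %.6f>\n",
              x$ce, x$dice, x$combined))
  invisible(x)
}
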