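#' Dice score between two label masks for one class
#'
#' `DC = 2 sum(y yhat) / (sum(y) + sum(yhat))`: 1 means perfect overlap
#' between prediction and ground truth, 0 means none. An optional region
#' restriction (used to evaluate sublayers outside the severely affected
#' box, where ground truth is undefined) limits the computation to pixels
#' where `region` is 1/`TRUE`.
#'
#' @param pred,gt Integer label matrices (see [label_mask()]).
#' @param class Integer class evaluated one-vs-rest.
#' @param region Optional 0/1 or logical matrix; only pixels with 1 count.
#' @return A value in `[0, 1]`, or `NA` when the class is absent from both
#'   masks (undefined; excluded from averages).
#' @export
dice_score <- function(pred, gt, class, region = NULL) {
  stopifnot(all(dim(pred) == dim(gt)))
  p <- unclass(pred) == class
  y <- unclass(gt) == class
  if (!is.null(region)) {
    keep <- as.vector(region) > 0
    p <- as.vector(p)[keep]
    y <- as.vector(y)[keep]
  }
  denom <- sum(p) + sum(y)
  if (denom == 0) return(NA_real_)
  2 * sum(p & y) / denom
}

#' Intersection over union of two boxes
#'
#' @param a,b One-row box tibbles (see [box_annotation()]).
#' @return IoU in `[0, 1]`; a zero-area box gives 0 with a warning.
#' @export
box_iou <- function(a, b) {
  area <- function(z) max(0, z$x_end - z$x_start) * max(0, z$y_end - z$y_start)
  a <- as.list(a[1, ]); b <- as.list(b[1, ])
  if (area(a) == 0 || area(b) == 0) {
    warn("Zero-area box; IoU set to 0.")
    return(0)
  }
  iw <- min(a$x_end, b$x_end) - max(a$x_start, b$x_start)
  ih <- min(a$y_end, b$y_end) - max(a$y_start, b$y_start)
  inter <- max(0, iw) * max(0, ih)
  inter / (area(a) + area(b) - inter)
}

# greedy one-to-one matching: detections in descending confidence order,
# each matched to the unmatched ground-truth box of its image with the
# highest IoU, provided IoU >= threshold. Returns logical TP flags aligned
# with the confidence-sorted detections.
match_detections <- function(detections, ground_truths, iou_threshold) {
  ord <- order(-detections$confidence)
  det <- detections[ord, , drop = FALSE]
  gt_matched <- rep(FALSE, nrow(ground_truths))
  tp <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(det))) {
    cand <- which(!gt_matched &
                    ground_truths$image_id == det$image_id[i])
    if (length(cand) == 0) next
    ious <- vapply(cand, function(j) {
      box_iou(det[i, ], ground_truths[j, ])
    }, numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      gt_matched[cand[best]] <- TRUE
    }
  }
  list(tp = tp, det = det, n_gt = nrow(ground_truths))
}

#' Precision and recall of box detections
#'
#' Detections at or above the confidence threshold are greedily matched
#' one-to-one to ground-truth boxes by descending confidence; a prediction
#' whose best IoU falls below the IoU threshold is a false positive and an
#' unmatched ground-truth box is a false negative. `Precision = TP / (TP +
#' FP)` and `Recall = TP / (TP + FN)`. With neither detections nor ground
#' truths, both are vacuously 1.
#'
#' @param detections Tibble of predicted boxes with `image_id` and
#'   `confidence`.
#' @param ground_truths Tibble of ground-truth boxes with `image_id`.
#' @param iou_threshold Minimum IoU for a match.
#' @param confidence_threshold Minimum confidence for a detection to count.
#' @return A one-row tibble: `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
precision_recall <- function(detections, ground_truths,
                             iou_threshold = 0.5, confidence_threshold = 0.5) {
  detections <- detections[!is.na(detections$confidence) &
                             detections$confidence >= confidence_threshold, ,
                           drop = FALSE]
  if (nrow(detections) == 0 && nrow(ground_truths) == 0) {
    return(tibble::tibble(precision = 1, recall = 1, tp = 0L, fp = 0L, fn = 0L))
  }
  m <- match_detections(detections, ground_truths, iou_threshold)
  tp <- sum(m$tp)
  fp <- sum(!m$tp)
  fn <- m$n_gt - tp
  tibble::tibble(
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn)
  )
}

ap_at_threshold <- function(detections, ground_truths, iou_threshold) {
  if (nrow(detections) == 0) {
    return(list(ap = 0, curve = tibble::tibble(recall = numeric(0),
                                               precision = numeric(0))))
  }
  m <- match_detections(detections, ground_truths, iou_threshold)
  tp_cum <- cumsum(m$tp)
  fp_cum <- cumsum(!m$tp)
  recall <- tp_cum / m$n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # 101-point interpolated precision (COCO convention)
  grid <- seq(0, 1, by = 0.01)
  interp <- vapply(grid, function(r) {
    ok <- recall >= r
    if (!any(ok)) 0 else max(precision[ok])
  }, numeric(1))
  list(ap = 100 * mean(interp),
       curve = tibble::tibble(recall = recall, precision = precision))
}

#' Average precision of box detections
#'
#' AP is the area under the interpolated precision-recall curve obtained by
#' ranking all detections by confidence (101-point interpolation). AP50 and
#' AP75 use IoU thresholds of 0.5 and 0.75; mAP is the mean AP over the
#' threshold grid 0.50:0.05:0.95. Values are reported on a 0--100 scale.
#'
#' @inheritParams precision_recall
#' @param iou_thresholds IoU threshold grid.
#' @return An object of class `ap_result`: a list with `ap` (tibble of
#'   per-threshold APs), `ap50`, `ap75`, `map` and `pr_curves`.
#' @export
average_precision <- function(detections, ground_truths,
                              iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (nrow(ground_truths) == 0) {
    abort("AP is undefined without any ground-truth boxes.")
  }
  per <- lapply(iou_thresholds, function(thr) {
    ap_at_threshold(detections, ground_truths, thr)
  })
  ap_tbl <- tibble::tibble(
    iou_threshold = iou_thresholds,
    ap = vapply(per, function(x) x$ap, numeric(1))
  )
  curves <- purrr::map2_dfr(per, iou_thresholds, function(x, thr) {
    dplyr::mutate(x$curve, iou_threshold = thr, .before = 1)
  })
  pick <- function(thr) {
    i <- which(abs(ap_tbl$iou_threshold - thr) < 1e-9)
    if (length(i)) ap_tbl$ap[i] else NA_real_
  }
  structure(
    list(ap = ap_tbl, ap50 = pick(0.5), ap75 = pick(0.75),
         map = mean(ap_tbl$ap), pr_curves = curves),
    class = "ap_result"
  )
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result: mAP = %.2f, AP50 = %.2f, AP75 = %.2f (%d thresholds)>\n",
              x$map, x$ap50, x$ap75, nrow(x$ap)))
  invisible(x)
}

#' Per-layer Dice evaluation of a set of segmentations
#'
#' Computes the Dice score of every layer for every image and summarises
#' each layer as mean +/- sd over images, plus an overall score (per-image
#' mean over layers, then averaged over images). In sublayer mode the
#' evaluation is restricted to pixels outside the ground-truth box of each
#' image, where sublayer ground truth is defined.
#'
#' @param predictions,ground_truths Lists of [label_mask()]s of equal
#'   length.
#' @param mode `"total"` (single retina class) or `"sublayer"` (IR, ONL,
#'   PR-IS, PR-OS, RPE).
#' @param boxes Optional list (parallel to the images) of ground-truth box
#'   tibbles or `NULL`s, used to exclude box columns in sublayer mode.
#' @return An object of class `dice_report`: list with `per_image` and
#'   `summary` tibbles; the summary has one row per layer plus `Overall`.
#' @export
evaluate_segmentation <- function(predictions, ground_truths,
                                  mode = c("total", "sublayer"),
                                  boxes = NULL) {
  mode <- match.arg(mode)
  n <- length(predictions)
  if (n == 0) abort("Empty test set.")
  stopifnot(length(ground_truths) == n)
  layers <- switch(mode,
    total = c(`total retina` = 1L),
    sublayer = SUBLAYER_CLASSES
  )
  per_image <- purrr::map_dfr(seq_len(n), function(i) {
    region <- NULL
    if (mode == "sublayer" && !is.null(boxes) && !is.null(boxes[[i]]) &&
        nrow(boxes[[i]]) > 0) {
      region <- box_to_mask(boxes[[i]], nrow(ground_truths[[i]]),
                            ncol(ground_truths[[i]]))
    }
    tibble::tibble(
      image = i,
      layer = names(layers),
      dice = unname(vapply(layers, function(k) {
        dice_score(predictions[[i]], ground_truths[[i]], k, region = region)
      }, numeric(1)))
    )
  })
  by_layer <- per_image |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      mean = mean(.data$dice, na.rm = TRUE),
      sd = sd(.data$dice, na.rm = TRUE),
      n_images = sum(!is.na(.data$dice)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$layer, names(layers)))
  overall_by_image <- per_image |>
    dplyr::group_by(.data$image) |>
    dplyr::summarise(dice = mean(.data$dice, na.rm = TRUE), .groups = "drop")
  summary <- dplyr::bind_rows(
    by_layer,
    tibble::tibble(layer = "Overall",
                   mean = mean(overall_by_image$dice),
                   sd = sd(overall_by_image$dice),
                   n_images = nrow(overall_by_image))
  )
  structure(
    list(per_image = per_image, summary = summary,
         overall_by_image = overall_by_image, mode = mode,
         averaging = "layer-then-image"),
    class = "dice_report"
  )
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice_report (%s mode, %s averaging)>\n", x$mode, x$averaging))
  print(x$summary)
  invisible(x)
}

#' Paired comparison of two segmentation methods
#'
#' Two-sided paired t-test on matched per-image overall Dice scores of two
#' methods. A zero-variance difference vector is reported explicitly as a
#' degenerate case (t = 0, p = 1 for identical vectors; infinite t and
#' p = 0 for a constant nonzero shift).
#'
#' @param dice_a,dice_b Numeric vectors of per-image Dice scores, paired by
#'   position, with length >= 2.
#' @return A one-row tibble: `estimate` (mean of a - b), `statistic`,
#'   `p_value`, `df`, `degenerate`.
#' @export
compare_methods <- function(dice_a, dice_b) {
  stopifnot(length(dice_a) == length(dice_b), length(dice_a) >= 2)
  d <- dice_a - dice_b
  if (sd(d) == 0) {
    est <- mean(d)
    return(tibble::tibble(
      estimate = est,
      statistic = if (est == 0) 0 else sign(est) * Inf,
      p_value = if (est == 0) 1 else 0,
      df = length(d) - 1L,
      degenerate = TRUE
    ))
  }
  tt <- t.test(dice_a, dice_b, paired = TRUE)
  tibble::tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    degenerate = FALSE
  )
}

#' Write a Dice report to CSV (summary) and JSON (full)
#'
#' @param report A `dice_report` from [evaluate_segmentation()].
#' @param path Output path without extension; `<path>.csv` holds the
#'   per-layer summary and `<path>.json` the full report including
#'   per-image scores and the averaging convention.
#' @return The two paths, invisibly.
#' @export
write_dice_report <- function(report, path) {
  stopifnot(inherits(report, "dice_report"))
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(report$summary, csv, row.names = FALSE)
  jsonlite::write_json(
    list(mode = report$mode, averaging = report$averaging,
         summary = report$summary, per_image = report$per_image),
    json, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, json))
}

#' Write a detection AP result to JSON and its PR curves to CSV
#'
#' @param ap An `ap_result` from [average_precision()].
#' @param path Output path without extension; `<path>.json` holds the AP
#'   values and `<path>_pr.csv` the precision-recall curve samples.
#' @return The two paths, invisibly.
#' @export
write_ap_result <- function(ap, path) {
  stopifnot(inherits(ap, "ap_result"))
  json <- paste0(path, ".json")
  csv <- paste0(path, "_pr.csv")
  jsonlite::write_json(
    list(map = ap$map, ap50 = ap$ap50, ap75 = ap$ap75, ap = ap$ap),
    json, auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(ap$pr_curves, csv, row.names = FALSE)
  invisible(c(json, csv))
}
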