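mask_of <- function(v, H = 2) matrix(as.integer(v), H, length(v) / H)

test_that("dice score matches pixel counting and handles absent classes", {
  a <- mask_of(c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(dice_score(a, a, 1), 1)
  b <- mask_of(c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(dice_score(a, b, 1), 0)
  # |gt| = 6, |pred| = 4, overlap 3
  gt <- mask_of(c(1, 1, 1, 1, 1, 1, 0, 0))
  pred <- mask_of(c(1, 1, 0, 0, 1, 0, 1, 0))
  expect_equal(dice_score(pred, gt, 1), 2 * 3 / 10)
  # absent from both: undefined sentinel
  expect_true(is.na(dice_score(a, a, 3)))
  # region restriction
  region <- mask_of(c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(dice_score(pred, gt, 1, region = region), 2 * 2 / 6)
})

test_that("dice score is symmetric and monotone in the overlap", {
  set.seed(1)
  for (i in 1:5) {
    a <- matrix(sample(0:1, 48, replace = TRUE), 6, 8)
    b <- matrix(sample(0:1, 48, replace = TRUE), 6, 8)
    expect_equal(dice_score(a, b, 1), dice_score(b, a, 1))
    # growing the true overlap (flip one mismatched pred pixel to match gt)
    d0 <- dice_score(a, b, 1)
    miss <- which(b == 1 & a == 0)
    if (length(miss) > 0 && !is.na(d0)) {
      a2 <- a
      a2[miss[1]] <- 1L
      expect_gte(dice_score(a2, b, 1), d0)
    }
  }
})

test_that("box IoU matches area arithmetic and rasterised counting", {
  b1 <- box_annotation(0, 10, 0, 10)
  expect_equal(box_iou(b1, b1), 1)
  expect_equal(box_iou(b1, box_annotation(20, 30, 0, 10)), 0)
  expect_equal(box_iou(b1, box_annotation(5, 15, 0, 10)), 1 / 3)
  set.seed(4)
  for (i in 1:6) {
    z <- sort(sample(0:20, 4))
    q <- sort(sample(0:20, 4))
    if (z[1] == z[2] || z[3] == z[4] || q[1] == q[2] || q[3] == q[4]) next
    a <- box_annotation(z[1], z[2], q[1], q[2])
    b <- box_annotation(z[3], z[4], q[3], q[4])
    expect_equal(box_iou(a, b), oracle_raster_iou(a, b))
  }
  degenerate <- tibble::tibble(x_start = 5, x_end = 5, y_start = 0, y_end = 3)
  expect_warning(v <- box_iou(degenerate, b1), "Zero-area")
  expect_equal(v, 0)
})

test_that("precision and recall follow the TP/FP/FN arithmetic", {
  # 9 TP + 1 FP detections over 12 ground truths -> precision 0.9, recall 0.75
  gts <- purrr::map_dfr(1:12, function(i) {
    box_annotation(0, 10, 0, 10, image_id = sprintf("img%02d", i))
  })
  dets <- dplyr::bind_rows(
    purrr::map_dfr(1:9, function(i) {
      box_annotation(0, 10, 0, 10, confidence = 0.9,
                     image_id = sprintf("img%02d", i))
    }),
    box_annotation(25, 35, 25, 35, confidence = 0.8, image_id = "img10")
  )
  pr <- precision_recall(dets, gts)
  expect_equal(pr$precision, 0.9)
  expect_equal(pr$recall, 0.75)
  expect_equal(c(pr$tp, pr$fp, pr$fn), c(9L, 1L, 3L))
  # all correct
  pr2 <- precision_recall(dets[1:9, ], gts[1:9, ])
  expect_equal(c(pr2$precision, pr2$recall), c(1, 1))
  # no detections with ground truth present
  pr3 <- precision_recall(dets[0, ], gts)
  expect_equal(pr3$recall, 0)
  # vacuous case
  pr4 <- precision_recall(dets[0, ], gts[0, ])
  expect_equal(c(pr4$precision, pr4$recall), c(1, 1))
  # below-confidence detections are discarded
  low <- dplyr::mutate(dets, confidence = 0.3)
  expect_equal(precision_recall(low, gts)$tp, 0L)
})

test_that("AP saturates at 100 for a perfect detection and 0 below threshold", {
  gt <- box_annotation(10, 30, 5, 25, image_id = "a")
  hit <- box_annotation(11, 30, 5, 25, confidence = 0.9, image_id = "a")
  expect_equal(average_precision(hit, gt, iou_thresholds = 0.5)$ap$ap, 100)
  miss <- box_annotation(24, 44, 5, 25, confidence = 0.9, image_id = "a") # IoU < 0.5
  expect_lt(box_iou(miss, gt), 0.5)
  expect_equal(average_precision(miss, gt, iou_thresholds = 0.5)$ap$ap, 0)
  expect_error(average_precision(hit, gt[0, ]), "undefined")
})

test_that("AP on a two-detection ranking equals hand enumeration", {
  # ranking: FP (conf 0.95) then TP (conf 0.9) over one ground truth:
  # precision points (0, 1/2) at recalls (0, 1); 101-point interpolated
  # precision is 0.5 everywhere -> AP = 50
  gt <- box_annotation(0, 20, 0, 20, image_id = "a")
  dets <- dplyr::bind_rows(
    box_annotation(50, 70, 0, 20, confidence = 0.95, image_id = "a"),
    box_annotation(0, 20, 0, 20, confidence = 0.90, image_id = "a")
  )
  expect_equal(average_precision(dets, gt, iou_thresholds = 0.5)$ap$ap, 50)
})

test_that("AP is invariant to monotone rescaling of confidences", {
  set.seed(8)
  gts <- purrr::map_dfr(1:4, function(i) {
    x0 <- sample(0:20, 1); y0 <- sample(0:20, 1)
    box_annotation(x0, x0 + 10, y0, y0 + 10, image_id = sprintf("im%d", i))
  })
  dets <- purrr::map_dfr(1:6, function(j) {
    i <- sample(1:4, 1)
    x0 <- sample(0:20, 1); y0 <- sample(0:20, 1)
    box_annotation(x0, x0 + 10, y0, y0 + 10, confidence = runif(1),
                   image_id = sprintf("im%d", i))
  })
  base <- average_precision(dets, gts)
  squashed <- dplyr::mutate(dets, confidence = confidence^3 / 2)
  expect_equal(average_precision(squashed, gts)$ap, base$ap)
  expect_equal(base$map, mean(base$ap$ap))
})

test_that("greedy matching agrees with a naive protocol reimplementation", {
  set.seed(11)
  for (rep in 1:6) {
    gts <- purrr::map_dfr(1:sample(1:3, 1), function(i) {
      x0 <- sample(0:15, 1); y0 <- sample(0:15, 1)
      box_annotation(x0, x0 + sample(5:12, 1), y0, y0 + sample(5:12, 1),
                     image_id = "img")
    })
    dets <- purrr::map_dfr(1:sample(2:4, 1), function(j) {
      x0 <- sample(0:15, 1); y0 <- sample(0:15, 1)
      box_annotation(x0, x0 + sample(5:12, 1), y0, y0 + sample(5:12, 1),
                     confidence = round(runif(1), 3), image_id = "img")
    })
    m <- pathaware:::match_detections(dets, gts, 0.5)
    expect_equal(m$tp, oracle_match(dets, gts, 0.5))
  }
})

test_that("segmentation reports match a spreadsheet-style hand computation", {
  gt1 <- mask_of(c(1, 1, 2, 2, 0, 0), H = 2)
  pr1 <- mask_of(c(1, 1, 2, 0, 0, 0), H = 2)
  gt2 <- mask_of(c(1, 0, 2, 2, 3, 3), H = 2)
  pr2 <- mask_of(c(1, 0, 2, 2, 0, 0), H = 2)
  rep <- evaluate_segmentation(list(pr1, pr2), list(gt1, gt2),
                               mode = "sublayer")
  # hand-computed per-image Dice: image 1: IR 1, ONL 2/3; image 2: IR 1,
  # ONL 1, PR-IS 0; absent classes are NA
  per <- rep$per_image
  expect_equal(per$dice[per$image == 1 & per$layer == "IR"], 1)
  expect_equal(per$dice[per$image == 1 & per$layer == "ONL"], 2 / 3)
  expect_true(is.na(per$dice[per$image == 1 & per$layer == "PR-IS"]))
  expect_equal(per$dice[per$image == 2 & per$layer == "PR-IS"], 0)
  # summary: 5 layer rows + Overall
  expect_equal(rep$summary$layer,
               c("IR", "ONL", "PR-IS", "PR-OS", "RPE", "Overall"))
  expect_equal(rep$summary$mean[rep$summary$layer == "ONL"],
               mean(c(2 / 3, 1)))
  expect_equal(rep$summary$sd[rep$summary$layer == "ONL"],
               sd(c(2 / 3, 1)))
  # overall: mean over layers per image, then over images
  img_means <- c(mean(c(1, 2 / 3)), mean(c(1, 1, 0)))
  expect_equal(rep$summary$mean[rep$summary$layer == "Overall"],
               mean(img_means))
  expect_equal(rep$averaging, "layer-then-image")
  expect_error(evaluate_segmentation(list(), list(), mode = "total"), "Empty")
})

test_that("perfect predictions give a report of ones with zero spread", {
  spec <- flat_phantom()
  r <- render_bscan(generate_boundaries(spec), spec)
  rep <- evaluate_segmentation(list(r$sublayer, r$sublayer),
                               list(r$sublayer, r$sublayer),
                               mode = "sublayer")
  expect_true(all(rep$summary$mean == 1))
  expect_true(all(rep$summary$sd == 0))
})

test_that("sublayer evaluation can exclude the boxed region", {
  gt <- mask_of(rep(c(1, 2), each = 4), H = 2)
  pred <- gt
  pred[, 1:2] <- 0L # corrupt inside a box spanning columns [0, 2)
  box <- box_annotation(0, 2, 0, 2)
  rep_in <- evaluate_segmentation(list(pred), list(gt), mode = "sublayer")
  rep_out <- evaluate_segmentation(list(pred), list(gt), mode = "sublayer",
                                   boxes = list(box))
  expect_lt(rep_in$summary$mean[1], 1)
  expect_equal(rep_out$summary$mean[rep_out$summary$layer == "Overall"], 1)
})

test_that("paired comparison reproduces the textbook t statistic", {
  a <- c(0.90, 0.80, 0.85, 0.95, 0.70)
  b <- c(0.88, 0.78, 0.80, 0.99, 0.65)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = length(d) - 1)
  res <- compare_methods(a, b)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p_value, p_hand)
  expect_equal(res$df, 4)
  expect_false(res$degenerate)
})

test_that("degenerate paired comparisons are reported explicitly", {
  same <- c(0.9, 0.8, 0.7)
  res <- compare_methods(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  shifted <- compare_methods(same + 0.1, same)
  expect_true(is.infinite(shifted$statistic) && shifted$statistic > 0)
  expect_equal(shifted$p_value, 0)
  # p-value shrinks as a constant positive difference accumulates evidence
  set.seed(3)
  base <- runif(40, 0.7, 0.9)
  p10 <- compare_methods(base[1:10] + 0.05 + rnorm(10, 0, 0.01), base[1:10])$p_value
  p40 <- compare_methods(base + 0.05 + rnorm(40, 0, 0.01), base)$p_value
  expect_lt(p40, p10)
})

test_that("reports round-trip to disk as CSV and JSON", {
  dir <- withr::local_tempdir()
  gt <- matrix(as.integer(c(1, 1, 2, 2, 0, 0)), 2, 3)
  rep <- evaluate_segmentation(list(gt), list(gt), mode = "sublayer")
  paths <- write_dice_report(rep, file.path(dir, "dice"))
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(back$layer, rep$summary$layer)
  gtb <- box_annotation(0, 10, 0, 10, image_id = "a")
  det <- box_annotation(0, 10, 0, 10, confidence = 0.9, image_id = "a")
  ap <- average_precision(det, gtb)
  ap_paths <- write_ap_result(ap, file.path(dir, "boxes"))
  expect_true(all(file.exists(ap_paths)))
  expect_equal(jsonlite::read_json(ap_paths[1])$ap50, 100)
})
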