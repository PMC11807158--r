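#' Iterative annotation-budget learning loop
#'
#' Emulates the iterative labeling strategy: starting from the initial
#' training manifest, each loop (optionally) trains a model, evaluates it on
#' the fixed validation set, then transfers `per_loop` randomly sampled
#' scans from the unannotated pool into the training set (the phantom
#' ground truth stands in for the human annotator). The validation and test
#' manifests remain unchanged throughout; the training manifest grows by
#' exactly `per_loop` scans per loop (or by the pool remainder, after which
#' the loop stops early).
#'
#' @param sets A list with `train`, `validation`, `test`, `pool` manifests
#'   (see [build_initial_sets()]).
#' @param loops Maximum number of loops.
#' @param per_loop Scans transferred from the pool per loop (default 200).
#' @param seed Integer seed for the random pool sampling.
#' @param train_fn Optional `function(train, validation)` returning a
#'   fitted model; `NULL` skips training (loop accounting only).
#' @param eval_fn Optional `function(model, validation)` returning a scalar
#'   validation metric (Dice or mAP).
#' @param stop_on_plateau If `TRUE`, stop when the validation metric
#'   improves by less than `plateau_eps` (absolute) for `plateau_loops`
#'   consecutive loops.
#' @param plateau_eps,plateau_loops Plateau rule parameters.
#' @return A list of class `loop_state`: `history` (tibble with one row per
#'   loop), `model` (last trained model or `NULL`) and the final `sets`.
#' @export
run_iterative <- function(sets, loops, per_loop = 200L, seed = 1L,
                          train_fn = NULL, eval_fn = NULL,
                          stop_on_plateau = FALSE,
                          plateau_eps = 0.005, plateau_loops = 2L) {
  stopifnot(all(c("train", "validation", "pool") %in% names(sets)))
  val_hash <- rlang::hash(sets$validation[order(sets$validation$scan_id), ])
  history <- list()
  model <- NULL
  last_metric <- NULL
  stalled <- 0L

  for (loop in seq_len(loops)) {
    metric <- NA_real_
    if (!is.null(train_fn)) {
      model <- train_fn(sets$train, sets$validation)
      if (!is.null(eval_fn)) metric <- eval_fn(model, sets$validation)
    }
    n_before <- nrow(sets$train)
    n_pool <- nrow(sets$pool)
    if (n_pool == 0) {
      message("Unannotated pool exhausted; stopping after loop ", loop - 1L, ".")
      break
    }
    n_take <- min(per_loop, n_pool)
    idx <- with_local_seed(seed + loop, sample.int(n_pool, n_take))
    sets$train <- dplyr::bind_rows(sets$train, sets$pool[idx, ])
    sets$pool <- sets$pool[-idx, ]
    history[[loop]] <- tibble::tibble(
      loop = loop, n_train_before = n_before, n_transferred = n_take,
      n_train_after = nrow(sets$train), n_pool = nrow(sets$pool),
      metric = metric,
      validation_hash = rlang::hash(
        sets$validation[order(sets$validation$scan_id), ]
      )
    )
    if (stop_on_plateau && !is.na(metric)) {
      if (!is.null(last_metric) && metric - last_metric < plateau_eps) {
        stalled <- stalled + 1L
      } else {
        stalled <- 0L
      }
      last_metric <- metric
      if (stalled >= plateau_loops) {
        message("Validation metric plateaued; stopping after loop ", loop, ".")
        break
      }
    }
  }

  structure(
    list(history = dplyr::bind_rows(history), model = model, sets = sets,
         initial_validation_hash = val_hash),
    class = "loop_state"
  )
}

#' @export
print.loop_state <- function(x, ...) {
  cat(sprintf("<loop_state: %d loop(s)>\n", nrow(x$history)))
  print(x$history)
  invisible(x)
}

#' Run the composed three-stage pipeline on a test set
#'
#' For every test scan: detect the severely affected region (with the
#' learned detector if supplied, otherwise the rule-based detector built on
#' the sublayer segmenter), segment the total retina and the sublayers, and
#' compose the final mask (total retina inside the box, sublayers outside).
#' Evaluation reports box AP (when ground-truth boxes exist), total-retina
#' Dice over the full image (from the aggregated composed mask) and
#' sublayer Dice outside the ground-truth boxes.
#'
#' @param test A manifest tibble or list of `bscan_render` objects.
#' @param models A list with `total` and `sublayer` segmenters and
#'   optionally `detector` (a `learned_detector`).
#' @param spec The [cohort_spec()] behind a manifest input, if not attached.
#' @param t_min Thickness threshold of the rule-based detector.
#' @return A list of class `pipeline_result` with `predictions`,
#'   `detections`, `ap`, `dice_total`, `dice_sublayer`.
#' @export
run_pipeline <- function(test, models, spec = NULL, t_min = "adaptive") {
  for (nm in c("total", "sublayer")) {
    if (is.null(models[[nm]])) abort(paste0("Missing model: ", nm, "."))
  }
  renders <- as_render_list(test, spec)
  ids <- vapply(seq_along(renders), function(i) {
    id <- renders[[i]]$image$meta$patient_id
    if (is.na(id)) sprintf("scan%03d", i) else
      sprintf("%s_v%s_s%s_%d", id, renders[[i]]$image$meta$visit,
              renders[[i]]$image$meta$slice_index, i)
  }, character(1))

  detections <- list()
  predictions <- list()
  for (i in seq_along(renders)) {
    image <- renders[[i]]$image$image
    det <- if (!is.null(models$detector)) {
      predict(models$detector, image, image_id = ids[i])
    } else {
      rule_based_detector(image, models$sublayer, t_min = t_min,
                          image_id = ids[i])
    }
    det <- det[det$confidence >= 0.5, , drop = FALSE]  # top-1 above 0.5
    if (nrow(det) > 1) det <- det[which.max(det$confidence), , drop = FALSE]
    detections[[i]] <- det
    predictions[[i]] <- compose_prediction(image, det, models$total,
                                           models$sublayer)
  }

  gt_boxes <- purrr::map2_dfr(renders, ids, function(r, id) {
    if (is.null(r$box)) return(NULL)
    dplyr::mutate(r$box, image_id = id)
  })
  det_tbl <- dplyr::bind_rows(detections)
  ap <- if (nrow(gt_boxes) > 0) {
    average_precision(det_tbl, gt_boxes)
  } else {
    NULL
  }

  dice_total <- evaluate_segmentation(
    lapply(predictions, aggregate_sublayers_to_total),
    lapply(renders, function(r) r$total),
    mode = "total"
  )
  dice_sublayer <- evaluate_segmentation(
    predictions,
    lapply(renders, function(r) r$sublayer),
    mode = "sublayer",
    boxes = lapply(renders, function(r) r$box)
  )

  structure(
    list(predictions = predictions, detections = det_tbl, ap = ap,
         dice_total = dice_total, dice_sublayer = dice_sublayer),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$ap)) {
    cat(sprintf("  boxes: mAP %.2f, AP50 %.2f, AP75 %.2f\n",
                x$ap$map, x$ap$ap50, x$ap$ap75))
  }
  ov <- function(rep) rep$summary$mean[rep$summary$layer == "Overall"]
  cat(sprintf("  total-retina Dice %.4f; sublayer Dice (outside boxes) %.4f\n",
              ov(x$dice_total), ov(x$dice_sublayer)))
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys: `train` (fields of [train_config()]),
#' `cohort` (fields of [cohort_spec()]), `detect` (`t_min`), `iterate`
#' (`loops`, `per_loop`).
#'
#' @param path YAML file.
#' @return A named list; `$train` is a [train_config()] when present.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$train)) cfg$train <- do.call(train_config, cfg$train)
  cfg
}
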