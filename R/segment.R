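#' Training configuration for the segmentation models
#'
#' Defaults follow the training schedule used for the full-scale task:
#' Adam with learning rate 0.0005, batch size 15, a learning-rate scheduler
#' with decay 0.5 and patience 15 epochs monitoring validation Dice, and 15
#' epochs per loop for the total-retina task (30 for the harder sublayer
#' task). At reduced phantom sizes a larger learning rate and smaller batch
#' converge in fewer epochs; see the package vignette.
#'
#' @param lr Initial learning rate.
#' @param epochs Training epochs.
#' @param batch_size Images per optimisation step.
#' @param scheduler_decay,scheduler_patience Learning-rate decay factor and
#'   the number of epochs without validation-Dice improvement before decay.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @param loss_mode `"standard"` (plain combined loss) or
#'   `"pathology-aware"` (masked loss excluding ground-truth box columns).
#' @param masked_norm Normalisation of the masked cross-entropy, see
#'   [masked_cross_entropy()].
#' @param n_filters Base filter count of the encoder-decoder.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 0.0005, epochs = 15L, batch_size = 15L,
                         scheduler_decay = 0.5, scheduler_patience = 15L,
                         seed = 1L,
                         loss_mode = c("standard", "pathology-aware"),
                         masked_norm = c("literal", "unmasked"),
                         n_filters = 16L) {
  loss_mode <- match.arg(loss_mode)
  masked_norm <- match.arg(masked_norm)
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, scheduler_decay > 0,
            scheduler_patience >= 1, n_filters >= 1)
  structure(
    list(lr = lr, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         scheduler_decay = scheduler_decay,
         scheduler_patience = as.integer(scheduler_patience),
         seed = as.integer(seed), loss_mode = loss_mode,
         masked_norm = masked_norm, n_filters = as.integer(n_filters)),
    class = "train_config"
  )
}

as_render_list <- function(x, spec = NULL) {
  if (is.data.frame(x)) {
    spec <- spec %||% attr(x, "cohort_spec")
    return(lapply(seq_len(nrow(x)), function(i) {
      render_manifest_row(x[i, ], spec)
    }))
  }
  stopifnot(all(vapply(x, inherits, logical(1), "bscan_render")))
  x
}

render_targets <- function(render, mode, use_masks) {
  image <- render$image$image
  H <- nrow(image)
  W <- ncol(image)
  labels <- if (mode == "total") render$total else render$sublayer
  m <- NULL
  if (use_masks && !is.null(render$box) && nrow(render$box) > 0) {
    m <- as.vector(box_to_mask(render$box, H, W))
  }
  list(x = nn_input(image), y = as.vector(unclass(labels)), m = m,
       H = H, W = W)
}

train_segmenter <- function(train, val, mode, config, spec = NULL) {
  train <- as_render_list(train, spec)
  val <- as_render_list(val, spec)
  if (length(train) == 0) abort("Empty training set.")
  n_classes <- if (mode == "total") 2L else 6L
  use_masks <- config$loss_mode == "pathology-aware"
  data <- lapply(train, render_targets, mode = mode, use_masks = use_masks)

  present <- sort(unique(unlist(lapply(data, function(d) unique(d$y)))))
  if (!all(0:1 %in% present)) {
    abort("A class is missing from the training labels.")
  }
  H <- data[[1]]$H
  W <- data[[1]]$W
  if (H %% 2L != 0L || W %% 2L != 0L) {
    abort("Image height and width must be even for the encoder-decoder.")
  }

  set.seed(config$seed)
  params <- nn_init(n_classes, in_channels = 2L, n_filters = config$n_filters)
  state <- adam_init(params)
  lr <- config$lr
  log <- vector("list", config$epochs)
  best <- list(dice = -Inf, params = params, epoch = 0L)
  since_improve <- 0L

  for (epoch in seq_len(config$epochs)) {
    order_idx <- sample.int(length(data))
    batch_starts <- seq(1, length(data), by = config$batch_size)
    epoch_losses <- numeric(0)
    for (bs in batch_starts) {
      idx <- order_idx[bs:min(bs + config$batch_size - 1L, length(data))]
      n_pix <- sum(vapply(idx, function(i) length(data[[i]]$y), numeric(1)))
      n_unmasked <- sum(vapply(idx, function(i) {
        d <- data[[i]]
        if (is.null(d$m)) length(d$y) else sum(d$m)
      }, numeric(1)))
      grads <- NULL
      batch_ce <- 0
      batch_dice <- numeric(0)
      for (i in idx) {
        d <- data[[i]]
        if (!is.null(d$m) && sum(d$m) == 0) {
          message("Image with a full-width box contributes zero loss; skipping.")
          next
        }
        fwd <- nn_forward(params, d$x, d$H, d$W)
        lg <- nn_loss_grad(fwd$probs, d$y, d$m, n_pix, n_unmasked,
                           length(idx), norm = config$masked_norm)
        batch_ce <- batch_ce + lg$ce
        batch_dice <- c(batch_dice, lg$dice)
        g <- nn_backward(params, fwd, lg$dz, d$H, d$W)
        grads <- if (is.null(grads)) g else
          purrr::map2(grads, g, `+`)
      }
      if (is.null(grads)) next
      step <- adam_step(params, grads, state, lr)
      params <- step$params
      state <- step$state
      epoch_losses <- c(epoch_losses,
                        batch_ce + if (length(batch_dice)) mean(batch_dice) else 0)
    }
    vd <- validation_dice(params, val, mode)
    if (vd > best$dice + 1e-12) {
      best <- list(dice = vd, params = params, epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$scheduler_patience) {
        lr <- lr * config$scheduler_decay
        since_improve <- 0L
      }
    }
    log[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(epoch_losses), val_dice = vd, lr = lr
    )
  }

  structure(
    list(params = best$params, final_params = params, mode = mode,
         n_classes = n_classes, config = config,
         log = dplyr::bind_rows(log), best_epoch = best$epoch,
         best_val_dice = best$dice),
    class = "pathaware_segmenter"
  )
}

validation_dice <- function(params, renders, mode) {
  if (length(renders) == 0) return(NA_real_)
  scores <- vapply(renders, function(render) {
    probs <- forward_image(params, render$image$image)
    pred <- prob_argmax(probs)
    gt <- if (mode == "total") render$total else render$sublayer
    region <- NULL
    if (mode == "sublayer" && !is.null(render$box) && nrow(render$box) > 0) {
      region <- box_to_mask(render$box, nrow(pred), ncol(pred))
    }
    classes <- if (mode == "total") 1L else 1:5
    d <- vapply(classes, function(k) {
      dice_score(pred, gt, k, region = region)
    }, numeric(1))
    mean(d, na.rm = TRUE)
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

forward_image <- function(params, image) {
  x <- nn_input(image)
  fwd <- nn_forward(params, x, nrow(image), ncol(image))
  array(fwd$probs, c(nrow(image), ncol(image), ncol(fwd$probs)))
}

#' Train the total-retina segmenter
#'
#' Trains the encoder-decoder to segment each B-scan into two classes
#' (total retina vs background) with the combined cross-entropy + Dice
#' loss, logging validation Dice once per epoch and returning the
#' checkpoint with the best validation Dice.
#'
#' @param train,val Cohort-manifest tibbles (rendered on the fly) or lists
#'   of `bscan_render` objects.
#' @param config A [train_config()].
#' @param spec The [cohort_spec()] behind manifest inputs, if not attached.
#' @return A fitted `pathaware_segmenter`; inspect with [tidy()] and
#'   [glance()].
#' @export
train_total_retina <- function(train, val, config = train_config(),
                               spec = NULL) {
  config$loss_mode <- "standard"
  train_segmenter(train, val, mode = "total", config = config, spec = spec)
}

#' Train the sublayer segmenter (standard or pathology-aware)
#'
#' Trains the six-class sublayer segmenter. In `"pathology-aware"` mode the
#' loss excludes the severely affected region of each training scan: the
#' annotated box is expanded to a full-height column mask and both the
#' cross-entropy and Dice terms are masked, so labels and predictions inside
#' the box never influence the parameters. In `"standard"` mode the plain
#' combined loss is used (and, as at full scale, such a model can only be
#' trained on scans whose sublayer ground truth is defined everywhere,
#' i.e. lesion-free data).
#'
#' @inheritParams train_total_retina
#' @param boxes Optional list of ground-truth boxes overriding the boxes
#'   attached to the training renders.
#' @return A fitted `pathaware_segmenter`.
#' @export
train_sublayers <- function(train, val, config = train_config(epochs = 30L),
                            boxes = NULL, spec = NULL) {
  train <- as_render_list(train, spec)
  if (!is.null(boxes)) {
    stopifnot(length(boxes) == length(train))
    for (i in seq_along(train)) train[[i]]$box <- boxes[[i]]
  }
  train_segmenter(train, as_render_list(val, spec), mode = "sublayer",
                  config = config, spec = spec)
}

#' Predict per-pixel class probabilities for a B-scan
#'
#' @param object A fitted `pathaware_segmenter`.
#' @param image A grayscale B-scan matrix in `[0, 1]` (or a `bscan`).
#' @param ... Unused.
#' @return A height x width x classes probability array.
#' @export
predict.pathaware_segmenter <- function(object, image, ...) {
  if (inherits(image, "bscan")) image <- image$image
  forward_image(object$params, image)
}

#' @export
print.pathaware_segmenter <- function(x, ...) {
  cat(sprintf(
    "<pathaware_segmenter: %s mode, %s loss, best val Dice %.4f @ epoch %d/%d>\n",
    x$mode, x$config$loss_mode, x$best_val_dice, x$best_epoch,
    x$config$epochs))
  invisible(x)
}

#' Per-epoch training log of a fitted segmenter
#'
#' @param x A `pathaware_segmenter`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `train_loss`, `val_dice`, `lr`.
#' @export
tidy.pathaware_segmenter <- function(x, ...) x$log

#' One-row summary of a fitted segmenter
#'
#' @param x A `pathaware_segmenter`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.pathaware_segmenter <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    loss_mode = x$config$loss_mode,
    epochs = x$config$epochs,
    best_epoch = x$best_epoch,
    best_val_dice = x$best_val_dice,
    n_parameters = sum(vapply(x$params, length, numeric(1)))
  )
}

#' Compose the final prediction from the three stages
#'
#' Pixels in the detected box columns carry the total-retina prediction
#' (encoded as class 6, "total retina inside the severely affected
#' region"); pixels outside carry the sublayer prediction. Without a
#' detection the output is the pure sublayer argmax.
#'
#' @param image A grayscale B-scan matrix.
#' @param detection A detections tibble (zero or one row), e.g. from
#'   [rule_based_detector()].
#' @param total_segmenter,sublayer_segmenter Fitted segmenters.
#' @return A `"composed"`-mode [label_mask()].
#' @export
compose_prediction <- function(image, detection, total_segmenter,
                               sublayer_segmenter) {
  sub_labels <- prob_argmax(predict(sublayer_segmenter, image))
  if (is.null(detection) || nrow(detection) == 0) {
    return(label_mask(sub_labels, "composed"))
  }
  total_labels <- prob_argmax(predict(total_segmenter, image))
  cols <- (floor(detection$x_start[1]) + 1):ceiling(detection$x_end[1])
  out <- sub_labels
  out[, cols] <- total_labels[, cols] * COMPOSED_TOTAL_CLASS
  label_mask(out, "composed")
}

#' Aggregate a sublayer mask to a total-retina mask
#'
#' Maps the five sublayer classes (and the composed in-box total class) to
#' the single total-retina class, preserving background.
#'
#' @param mask A sublayer or composed [label_mask()].
#' @return A total-mode [label_mask()].
#' @export
aggregate_sublayers_to_total <- function(mask) {
  label_mask((unclass(mask) > 0L) * 1L, "total")
}
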