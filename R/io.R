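#' Create a box annotation
#'
#' Boxes use 0-based, half-open pixel coordinates: columns
#' `[x_start, x_end)` and rows `[y_start, y_end)`. At most one box exists
#' per B-scan (disjoint affected regions are merged into one larger box).
#'
#' @param x_start,x_end,y_start,y_end Box extent.
#' @param confidence Optional detection confidence in `[0, 1]`.
#' @param image_id Optional scan identifier.
#' @return A one-row tibble.
#' @export
box_annotation <- function(x_start, x_end, y_start, y_end,
                           confidence = NA_real_, image_id = NA_character_) {
  if (x_start >= x_end || y_start >= y_end) {
    abort("Box must have positive width and height.")
  }
  tibble::tibble(
    image_id = image_id,
    x_start = as.numeric(x_start), x_end = as.numeric(x_end),
    y_start = as.numeric(y_start), y_end = as.numeric(y_end),
    confidence = as.numeric(confidence)
  )
}

box_to_coco <- function(box) {
  list(bbox = c(box$x_start, box$y_start,
                box$x_end - box$x_start, box$y_end - box$y_start),
       category_id = 1L,
       score = if (is.na(box$confidence)) NULL else box$confidence)
}

#' Write box annotations as COCO-style JSON
#'
#' One category ("severely_affected_region"), `bbox` in `[x, y, w, h]`
#' float pixel coordinates.
#'
#' @param boxes A list of annotation entries or a tibble of boxes (see
#'   [box_annotation()]).
#' @param path Output file.
#' @export
write_coco_boxes <- function(boxes, path) {
  if (is.data.frame(boxes)) {
    boxes <- purrr::map(seq_len(nrow(boxes)), function(i) {
      b <- boxes[i, ]
      c(list(image_id = b$image_id), box_to_coco(b))
    })
  }
  payload <- list(
    categories = list(list(id = 1L, name = "severely_affected_region")),
    annotations = boxes
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style box annotations
#'
#' @param path JSON file written by [write_coco_boxes()] (or any COCO-style
#'   file with `annotations[].bbox` in xywh).
#' @return A tibble of boxes in the package's half-open convention.
#' @export
read_coco_boxes <- function(path) {
  payload <- jsonlite::read_json(path)
  purrr::map_dfr(payload$annotations, function(a) {
    bb <- unlist(a$bbox)
    tibble::tibble(
      image_id = a$image_id %||% NA_character_,
      x_start = bb[1], x_end = bb[1] + bb[3],
      y_start = bb[2], y_end = bb[2] + bb[4],
      confidence = a$score %||% NA_real_
    )
  })
}

#' Read a label mask written as an indexed PNG
#'
#' @param path PNG file whose pixel values are class indices (written by
#'   [generate_cohort()] as index/255 gray levels).
#' @param mode Label mode, see [label_mask()].
#' @return A [label_mask()].
#' @export
read_mask_png <- function(path, mode = "sublayer") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  label_mask(round_half_up(m * 255), mode = mode)
}

#' Read a grayscale B-scan image
#'
#' @param path PNG file.
#' @return A numeric matrix in `[0, 1]`.
#' @export
read_bscan_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}
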