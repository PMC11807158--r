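#' Specification of a synthetic layered B-scan phantom
#'
#' Describes the geometry, reflectivity and noise of a synthetic retinal
#' B-scan. The retina is modelled as five stacked sublayers (IR, ONL, PR-IS,
#' PR-OS, RPE) delimited by six smooth boundary curves, with a foveal dip in
#' the inner surface and speckle-like noise on top of piecewise-constant
#' layer reflectivity.
#'
#' All coordinates are 0-based with row 0 at the top (vitreous side); column
#' intervals are half-open `[start, end)`.
#'
#' @param width,height Image size in pixels (nominally 1024 x 496).
#' @param base_depths Mean row offset of each of the six boundaries, a
#'   strictly increasing numeric vector of length 6. Defaults to anatomically
#'   plausible fractions of `height`.
#' @param undulation List with `amplitude` (pixels) and `frequency` (cycles
#'   across the image width) of the shared smooth curvature applied to all
#'   boundaries, plus `jitter` (pixels), the amplitude of small independent
#'   per-boundary sinusoidal perturbations.
#' @param foveal_dip List with `center` (column), `width` (pixels) and
#'   `depth` (pixels) of the Gaussian foveal depression. The dip acts fully
#'   on the inner surface and decays for deeper boundaries via `dip_weights`.
#' @param dip_weights Per-boundary multipliers for the foveal dip.
#' @param layer_intensities Named numeric vector of mean gray levels in
#'   `[0, 1]` for background and the five sublayers.
#' @param noise List with `speckle` (shape of the unit-mean multiplicative
#'   gamma speckle; `0` disables it) and `gaussian_sd` (additive noise sd).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   phantoms.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 1024L,
                         height = 496L,
                         base_depths = NULL,
                         undulation = list(),
                         foveal_dip = list(),
                         dip_weights = c(1, 0.35, 0.1, 0, 0, 0),
                         layer_intensities = NULL,
                         noise = list(),
                         seed = NULL) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.null(base_depths)) {
    base_depths <- round(height * c(0.25, 0.47, 0.59, 0.64, 0.69, 0.76))
  }
  undulation <- modify_defaults(
    list(amplitude = 0.016 * height, frequency = 1.25, jitter = 0),
    undulation
  )
  foveal_dip <- modify_defaults(
    list(center = (width - 1) / 2, width = width / 5, depth = 0.06 * height),
    foveal_dip
  )
  if (is.null(layer_intensities)) {
    layer_intensities <- c(
      background = 0.05, IR = 0.55, ONL = 0.30,
      `PR-IS` = 0.80, `PR-OS` = 0.65, RPE = 0.90
    )
  }
  noise <- modify_defaults(list(speckle = 30, gaussian_sd = 0.02), noise)

  spec <- structure(
    list(
      width = width, height = height, base_depths = as.numeric(base_depths),
      undulation = undulation, foveal_dip = foveal_dip,
      dip_weights = as.numeric(dip_weights),
      layer_intensities = layer_intensities, noise = noise, seed = seed
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  if (length(spec$base_depths) != 6L) {
    abort("`base_depths` must list six boundary depths (five sublayers).")
  }
  if (any(diff(spec$base_depths) <= 0)) {
    abort("`base_depths` must be strictly increasing from the vitreous down.")
  }
  if (any(spec$base_depths < 0) || any(spec$base_depths > spec$height - 1)) {
    abort("`base_depths` must lie within the image height.")
  }
  if (length(spec$layer_intensities) != 6L ||
      any(spec$layer_intensities < 0) || any(spec$layer_intensities > 1)) {
    abort("`layer_intensities` must give six gray levels in [0, 1].")
  }
  if (length(spec$dip_weights) != 6L) {
    abort("`dip_weights` must have one entry per boundary.")
  }
  spec
}

modify_defaults <- function(defaults, x) {
  stopifnot(is.list(x))
  defaults[names(x)] <- x
  defaults
}

#' Specification of a degeneration lesion
#'
#' Describes one or more column spans in which at least one outer-retinal
#' sublayer collapses, mimicking the severely affected regions of Stargardt
#' disease where a sublayer becomes undetectable. Thickness removed from the
#' collapsing layers is redistributed to the remaining sublayers so the total
#' retinal band stays continuous, and hyper-reflective debris is painted
#' inside the span.
#'
#' @param column_spans List of `c(start, end)` half-open column intervals.
#' @param absent_layers Character vector naming the collapsing sublayers,
#'   a subset of `ONL`, `PR-IS`, `PR-OS`, `RPE`.
#' @param debris_intensity Gray level of the hyper-reflective debris.
#' @param debris_density Fraction of band pixels seeded with debris blobs.
#' @param severity Fraction in `[0, 1]`: 1 collapses the listed layers to
#'   zero thickness, 0 leaves the scan untouched.
#' @param redistribute Fraction of the removed thickness handed to the
#'   surviving sublayers (debris accumulation); the remainder thins the
#'   total band, as atrophic regions do. The band always stays connected.
#'
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(column_spans,
                        absent_layers,
                        debris_intensity = 0.85,
                        debris_density = 0.08,
                        severity = 1,
                        redistribute = 0.35) {
  if (!is.list(column_spans)) column_spans <- list(column_spans)
  allowed <- c("ONL", "PR-IS", "PR-OS", "RPE")
  if (severity > 0) {
    if (length(absent_layers) == 0) {
      abort("A severely affected region requires at least one absent sublayer.")
    }
    if (!all(absent_layers %in% allowed)) {
      abort(paste0("`absent_layers` must be drawn from: ",
                   paste(allowed, collapse = ", "), "."))
    }
  }
  if (severity < 0 || severity > 1) abort("`severity` must be in [0, 1].")
  stopifnot(redistribute >= 0, redistribute <= 1)
  structure(
    list(
      column_spans = lapply(column_spans, function(s) as.numeric(s[1:2])),
      absent_layers = absent_layers,
      debris_intensity = debris_intensity,
      debris_density = debris_density,
      severity = severity,
      redistribute = redistribute
    ),
    class = "lesion_spec"
  )
}

#' Generate the six smooth boundary curves of a phantom B-scan
#'
#' Builds the boundary geometry: per-boundary base depths, a shared smooth
#' undulation (so boundaries stay parallel and ordered), optional small
#' independent jitter, and a Gaussian foveal dip applied with depth-dependent
#' weights. Curves are validated to stay strictly ordered with at least one
#' pixel of separation at every column.
#'
#' @param spec A [phantom_spec()].
#' @return A 6 x width numeric matrix; entry `[k, j]` is the (0-based,
#'   fractional) row of boundary `k` at column `j - 1`.
#' @export
generate_boundaries <- function(spec) {
  spec <- validate_phantom_spec(spec)
  W <- spec$width
  x <- seq_len(W) - 1

  curves <- with_local_seed(spec$seed, {
    und <- spec$undulation
    phase <- runif(1, 0, 2 * pi)
    shared <- und$amplitude * sin(2 * pi * und$frequency * x / W + phase)
    dip <- spec$foveal_dip
    sigma <- dip$width / 4
    dip_profile <- dip$depth * exp(-0.5 * ((x - dip$center) / sigma)^2)

    out <- matrix(0, nrow = 6, ncol = W)
    for (k in 1:6) {
      jitter <- 0
      if (und$jitter > 0) {
        jitter <- und$jitter * sin(2 * pi * (und$frequency + k / 3) * x / W +
                                     runif(1, 0, 2 * pi))
      }
      out[k, ] <- spec$base_depths[k] + shared + jitter +
        spec$dip_weights[k] * dip_profile
    }
    out
  })

  if (any(curves < 0) || any(curves > spec$height - 1)) {
    abort("Boundary curves leave the image after undulation/dip; adjust the spec.")
  }
  if (any(apply(curves, 2, diff) < 1)) {
    abort("Boundary ordering violated (layers thinner than 1 px); adjust the spec.")
  }
  rownames(curves) <- paste0("b", 1:6)
  curves
}

# integer row of each boundary at each column (pixel r belongs to layer k
# when round(b_k) <= r < round(b_{k+1}))
round_boundaries <- function(boundaries) round_half_up(boundaries)

labels_from_boundaries <- function(boundaries, height) {
  rb <- round_boundaries(boundaries)
  W <- ncol(boundaries)
  labels <- matrix(0L, nrow = height, ncol = W)
  rows <- seq_len(height) - 1
  for (j in seq_len(W)) {
    for (k in 1:5) {
      r0 <- rb[k, j]
      r1 <- rb[k + 1, j]
      if (r1 > r0) labels[rows >= r0 & rows < r1, j] <- k
    }
  }
  labels
}

#' Construct a per-pixel label mask
#'
#' @param labels Integer matrix of class labels.
#' @param mode `"sublayer"` (0 = background, 1..5 = IR..RPE), `"total"`
#'   (0 = background, 1 = total retina) or `"composed"` (sublayer encoding
#'   plus 6 = total retina inside the severely affected box).
#' @return An integer matrix of class `label_mask` with a `mode` attribute.
#' @export
label_mask <- function(labels, mode = c("sublayer", "total", "composed")) {
  mode <- match.arg(mode)
  labels <- matrix(as.integer(labels), nrow = nrow(labels), ncol = ncol(labels))
  max_class <- switch(mode, total = 1L, sublayer = 5L, composed = 6L)
  if (any(labels < 0L) || any(labels > max_class)) {
    abort(paste0("Labels out of range for mode '", mode, "'."))
  }
  structure(labels, mode = mode, class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask [%d x %d], mode = %s>\n",
              nrow(x), ncol(x), attr(x, "mode")))
  invisible(x)
}

#' Render a phantom B-scan from boundary curves
#'
#' Converts boundary geometry into a per-pixel sublayer label mask, the
#' matching total-retina mask (the union of the five sublayers) and a
#' grayscale image: per-class mean reflectivity multiplied by unit-mean
#' gamma speckle, plus additive Gaussian noise, clipped to `[0, 1]`.
#'
#' @param boundaries Output of [generate_boundaries()].
#' @param spec The [phantom_spec()] the boundaries were generated from.
#' @param meta Optional named list of provenance fields (`patient_id`,
#'   `site_id`, `eye`, `visit`, `slice_index`) attached to the scan.
#' @return A list of class `bscan_render` with elements `image` (a `bscan`),
#'   `sublayer` and `total` ([label_mask()]s), `boundaries`, `spec` and
#'   `box` (`NULL`; filled by [inject_lesion()]).
#' @export
render_bscan <- function(boundaries, spec, meta = list()) {
  labels <- labels_from_boundaries(boundaries, spec$height)
  image <- with_local_seed(spec$seed, render_intensities(labels, spec))
  scan <- new_bscan(image, meta)
  structure(
    list(
      image = scan,
      sublayer = label_mask(labels, "sublayer"),
      total = label_mask((labels > 0L) * 1L, "total"),
      boundaries = boundaries,
      spec = spec,
      box = NULL
    ),
    class = "bscan_render"
  )
}

render_intensities <- function(labels, spec) {
  img <- matrix(spec$layer_intensities[labels + 1L],
                nrow = nrow(labels), ncol = ncol(labels))
  n <- length(img)
  s <- spec$noise$speckle
  if (!is.null(s) && s > 0) img <- img * rgamma(n, shape = s, rate = s)
  sdv <- spec$noise$gaussian_sd
  if (!is.null(sdv) && sdv > 0) img <- img + rnorm(n, 0, sdv)
  pmin(pmax(img, 0), 1)
}

new_bscan <- function(image, meta = list()) {
  meta <- modify_defaults(
    list(patient_id = NA_character_, site_id = NA_character_,
         eye = NA_character_, visit = NA_integer_, slice_index = NA_integer_),
    meta
  )
  structure(list(image = image, meta = meta), class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan [%d x %d] patient=%s visit=%s slice=%s>\n",
              nrow(x$image), ncol(x$image), x$meta$patient_id,
              x$meta$visit, x$meta$slice_index))
  invisible(x)
}

#' Inject a degeneration lesion and derive its ground-truth box
#'
#' Inside each lesion span the listed sublayers collapse by `severity`
#' (to zero thickness at severity 1); the removed thickness is redistributed
#' proportionally to the surviving sublayers so the total retinal band stays
#' a single connected run per column. Hyper-reflective debris is painted in
#' the band and the span columns are re-rendered (columns outside the spans
#' are untouched). The ground-truth box is the single orthogonal box covering
#' every column in which at least one sublayer has zero rendered thickness;
#' disjoint spans are merged into one larger box.
#'
#' @param render A `bscan_render` from [render_bscan()].
#' @param lesion A [lesion_spec()].
#' @param min_thickness Columns count as affected when any sublayer has
#'   rendered thickness below this many pixels (default 1, i.e. exactly zero
#'   thickness).
#' @param seed Optional seed for debris/noise re-rendering; defaults to the
#'   phantom seed.
#' @return A `bscan_render` whose `box` element is a one-row tibble
#'   (`x_start`, `x_end`, `y_start`, `y_end`, half-open columns) or `NULL`
#'   when no column is affected.
#' @export
inject_lesion <- function(render, lesion, min_thickness = 1, seed = NULL) {
  stopifnot(inherits(render, "bscan_render"), inherits(lesion, "lesion_spec"))
  if (lesion$severity == 0) return(render)
  spec <- render$spec
  boundaries <- render$boundaries
  W <- spec$width

  spans <- lapply(lesion$column_spans, function(s) {
    if (s[1] < 0 || s[2] > W || s[1] >= s[2]) {
      abort("Lesion span outside the image width.")
    }
    as.integer(c(floor(s[1]), ceiling(s[2])))
  })

  absent_idx <- match(lesion$absent_layers, names(SUBLAYER_CLASSES))
  new_bnd <- boundaries
  for (s in spans) {
    cols <- (s[1] + 1):s[2]  # 1-based column indices
    for (j in cols) {
      t_k <- diff(boundaries[, j])  # five continuous thicknesses
      t_new <- t_k
      t_new[absent_idx] <- t_k[absent_idx] * (1 - lesion$severity)
      removed <- sum(t_k[absent_idx] - t_new[absent_idx])
      keep <- setdiff(1:5, absent_idx)
      # part of the removed thickness accumulates as debris in the
      # surviving layers; the rest thins the band (atrophy)
      t_new[keep] <- t_k[keep] *
        (1 + lesion$redistribute * removed / sum(t_k[keep]))
      new_bnd[, j] <- boundaries[1, j] + c(0, cumsum(t_new))
    }
  }

  labels <- labels_from_boundaries(new_bnd, spec$height)
  image <- render$image$image
  seed <- seed %||% spec$seed
  image <- with_local_seed(seed, {
    for (s in spans) {
      cols <- (s[1] + 1):s[2]
      sub_labels <- labels[, cols, drop = FALSE]
      patch <- matrix(spec$layer_intensities[sub_labels + 1L],
                      nrow = spec$height)
      # hyper-reflective debris: small blobs seeded in the retinal band
      band <- sub_labels > 0L
      n_seeds <- round_half_up(lesion$debris_density * sum(band))
      if (n_seeds > 0) {
        idx <- sample(which(band), n_seeds)
        blob <- arrayInd(idx, dim(band))
        for (b in seq_len(nrow(blob))) {
          r0 <- max(1, blob[b, 1] - 1); r1 <- min(spec$height, blob[b, 1] + 1)
          c0 <- max(1, blob[b, 2] - 1); c1 <- min(length(cols), blob[b, 2] + 1)
          sel <- band[r0:r1, c0:c1, drop = FALSE]
          tmp <- patch[r0:r1, c0:c1, drop = FALSE]
          tmp[sel] <- lesion$debris_intensity
          patch[r0:r1, c0:c1] <- tmp
        }
      }
      n <- length(patch)
      if (spec$noise$speckle > 0) {
        patch <- patch * rgamma(n, shape = spec$noise$speckle,
                                rate = spec$noise$speckle)
      }
      if (spec$noise$gaussian_sd > 0) {
        patch <- patch + rnorm(n, 0, spec$noise$gaussian_sd)
      }
      image[, cols] <- pmin(pmax(patch, 0), 1)
    }
    image
  })

  sublayer <- label_mask(labels, "sublayer")
  total <- label_mask((labels > 0L) * 1L, "total")
  affected <- column_integrity_profile(sublayer, t_min = min_thickness)
  box <- merge_single_box(affected, retina_row_extent(sublayer))

  out <- render
  out$image$image <- image
  out$sublayer <- sublayer
  out$total <- total
  out$boundaries <- new_bnd
  out$box <- box
  out
}

# row extent (0-based, half-open) of the retinal band over given columns
retina_row_extent <- function(mask, cols = NULL) {
  m <- unclass(mask)
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  rows <- which(apply(m > 0L, 1, any))
  if (length(rows) == 0) return(c(0, nrow(m)))
  c(min(rows) - 1, max(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
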