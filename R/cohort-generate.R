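#' Specification of a synthetic multi-site longitudinal cohort
#'
#' Describes a cohort of patients imaged at several sites over repeated
#' visits, with both eyes scanned as 49-slice macular volumes. Each patient
#' carries a baseline disease severity and a patient-specific progression
#' slope, so severity increases monotonically across visits; all slices of a
#' volume share the visit's severity. Scans above `lesion_threshold` develop
#' a degeneration lesion (with ground-truth box); below it they remain
#' lesion-free, and a `healthy` cohort fixes severity at zero everywhere.
#'
#' @param sites Named integer vector (or tibble with `site_id`,
#'   `n_patients`) giving the number of patients per site.
#' @param visits Number of study visits per patient.
#' @param eyes Character vector of eyes examined per visit.
#' @param slices_per_volume Number of B-scans per volume (default 49).
#' @param width,height Pixel size of the generated B-scans.
#' @param noise Noise options forwarded to [phantom_spec()].
#' @param baseline_range,slope_range Ranges of the per-patient uniform draws
#'   for baseline severity and per-visit progression slope.
#' @param lesion_threshold Severity above which a scan carries a lesion.
#' @param healthy If `TRUE`, severity is zero for every scan.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(sites,
                        visits = 5L,
                        eyes = c("OD", "OS"),
                        slices_per_volume = 49L,
                        width = 1024L,
                        height = 496L,
                        noise = list(),
                        baseline_range = c(0.05, 0.55),
                        slope_range = c(0.03, 0.09),
                        lesion_threshold = 0.35,
                        healthy = FALSE,
                        seed = 1L) {
  if (is.data.frame(sites)) {
    sites <- stats::setNames(as.integer(sites$n_patients), sites$site_id)
  }
  if (is.null(names(sites))) {
    names(sites) <- sprintf("site%02d", seq_along(sites))
  }
  structure(
    list(
      sites = sites, visits = as.integer(visits), eyes = eyes,
      slices_per_volume = as.integer(slices_per_volume),
      width = as.integer(width), height = as.integer(height), noise = noise,
      baseline_range = baseline_range, slope_range = slope_range,
      lesion_threshold = lesion_threshold, healthy = isTRUE(healthy),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort manifest (and optionally its images)
#'
#' Builds one volume per (patient, visit, eye) and one manifest row per
#' B-scan. Each row records provenance (patient, site, eye, visit, slice
#' index), the scan's disease severity, whether it carries a lesion, and a
#' per-scan seed from which the B-scan, its label masks and its ground-truth
#' box can be re-rendered deterministically with [render_manifest_row()].
#' When `dir` is given, 8-bit grayscale PNG images, indexed PNG label masks,
#' a COCO-style box JSON and a `manifest.csv` are written there.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory for images, masks, boxes, manifest.
#' @param write_images Whether to render and write images (default: only
#'   when `dir` is given).
#' @return A tibble manifest with one row per B-scan.
#' @export
generate_cohort <- function(spec, dir = NULL, write_images = !is.null(dir)) {
  stopifnot(inherits(spec, "cohort_spec"))
  patients <- purrr::imap_dfr(as.list(spec$sites), function(n, site) {
    tibble::tibble(
      site_id = site,
      patient_id = sprintf("%s-P%03d", site, seq_len(n))
    )
  })

  manifest <- with_local_seed(spec$seed, {
    patients$baseline <- if (spec$healthy) 0 else {
      runif(nrow(patients), spec$baseline_range[1], spec$baseline_range[2])
    }
    patients$slope <- if (spec$healthy) 0 else {
      runif(nrow(patients), spec$slope_range[1], spec$slope_range[2])
    }
    grid <- tidyr::expand_grid(
      patients,
      visit = seq_len(spec$visits),
      eye = spec$eyes,
      slice_index = seq_len(spec$slices_per_volume) - 1L
    )
    grid$severity <- pmin(1, grid$baseline + grid$slope * (grid$visit - 1))
    grid$scan_seed <- sample.int(.Machine$integer.max, nrow(grid),
                                 replace = TRUE)
    grid
  })

  manifest <- manifest |>
    dplyr::mutate(
      has_lesion = .data$severity >= spec$lesion_threshold,
      scan_id = sprintf("%s_%s_v%d_s%02d", .data$patient_id, .data$eye,
                        .data$visit, .data$slice_index)
    ) |>
    dplyr::select("scan_id", "patient_id", "site_id", "eye", "visit",
                  "slice_index", "severity", "has_lesion", "scan_seed")

  if (write_images) {
    if (is.null(dir)) abort("`dir` must be given to write images.")
    write_cohort_images(manifest, spec, dir)
  }
  attr(manifest, "cohort_spec") <- spec
  manifest
}

# phantom spec adapted to a scan's severity and slice position:
# photoreceptor reflectivity attenuates and the outer layers thin with
# severity; the foveal dip (and lesion extent) is strongest centrally.
scan_phantom_spec <- function(spec, severity, slice_index) {
  n <- spec$slices_per_volume
  centrality <- exp(-0.5 * ((slice_index - (n - 1) / 2) / (0.18 * n))^2)

  intens <- c(background = 0.05, IR = 0.55, ONL = 0.30,
              `PR-IS` = 0.80, `PR-OS` = 0.65, RPE = 0.90)
  intens["PR-IS"] <- intens["PR-IS"] - 0.35 * severity
  intens["PR-OS"] <- intens["PR-OS"] - 0.25 * severity
  intens["RPE"] <- intens["RPE"] - 0.10 * severity

  depths <- round(spec$height * c(0.25, 0.47, 0.59, 0.64, 0.69, 0.76))
  t_k <- diff(depths)
  t_k[2:4] <- t_k[2:4] * (1 - 0.4 * severity)  # ONL, PR-IS, PR-OS thin
  depths <- depths[1] + c(0, cumsum(t_k))

  phantom_spec(
    width = spec$width, height = spec$height,
    base_depths = depths,
    foveal_dip = list(depth = 0.06 * spec$height * (0.25 + 0.75 * centrality)),
    layer_intensities = intens,
    noise = spec$noise,
    seed = NULL
  )
}

#' Re-render one manifest row into a B-scan with ground truth
#'
#' Deterministically regenerates the B-scan described by a manifest row of
#' [generate_cohort()]: the same severity, slice position and per-scan seed
#' always reproduce the same image, label masks and ground-truth box.
#'
#' @param row A one-row slice of a cohort manifest.
#' @param spec The [cohort_spec()] the manifest came from (defaults to the
#'   spec attached to the manifest).
#' @return A `bscan_render` (see [render_bscan()]); its `box` element is
#'   `NULL` for lesion-free scans.
#' @export
render_manifest_row <- function(row, spec = NULL) {
  spec <- spec %||% attr(row, "cohort_spec")
  if (is.null(spec)) abort("Supply the `cohort_spec` for this manifest.")
  row <- as.list(dplyr::slice(tibble::as_tibble(row), 1))

  pspec <- scan_phantom_spec(spec, row$severity, row$slice_index)
  pspec$seed <- row$scan_seed %% .Machine$integer.max
  boundaries <- generate_boundaries(pspec)
  render <- render_bscan(boundaries, pspec, meta = row[c(
    "patient_id", "site_id", "eye", "visit", "slice_index"
  )])

  if (isTRUE(row$has_lesion)) {
    lesion <- with_local_seed(pspec$seed + 1L, {
      W <- spec$width
      n <- spec$slices_per_volume
      centrality <- exp(-0.5 * ((row$slice_index - (n - 1) / 2) / (0.18 * n))^2)
      sev <- row$severity
      thr <- spec$lesion_threshold
      grow <- (sev - thr) / (1 - thr)
      half <- W * (0.06 + 0.22 * grow) * (0.5 + 0.5 * centrality)
      center <- (W - 1) / 2 + rnorm(1, 0, 0.05 * W)
      span1 <- c(max(0, center - half), min(W, center + half))
      spans <- list(span1)
      if (runif(1) < 0.4) {
        off <- sample(c(-1, 1), 1) * runif(1, 0.18, 0.3) * W
        c2 <- center + off
        h2 <- half * runif(1, 0.3, 0.6)
        span2 <- c(max(0, c2 - h2), min(W, c2 + h2))
        if (span2[2] - span2[1] > 2) spans <- c(spans, list(span2))
      }
      absent <- "PR-OS"
      if (sev > 0.55) absent <- c(absent, "PR-IS")
      if (sev > 0.75) absent <- c(absent, "ONL")
      if (sev > 0.90) absent <- c(absent, "RPE")
      lesion_spec(spans, absent_layers = absent, severity = 1)
    })
    render <- inject_lesion(render, lesion, seed = pspec$seed + 2L)
  }
  render
}

write_cohort_images <- function(manifest, spec, dir) {
  for (sub in c("images", "masks_sublayer", "masks_total")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  boxes <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    render <- render_manifest_row(row, spec)
    id <- row$scan_id
    png::writePNG(render$image$image, file.path(dir, "images", paste0(id, ".png")))
    png::writePNG(unclass(render$sublayer) / 255,
                  file.path(dir, "masks_sublayer", paste0(id, ".png")))
    png::writePNG(unclass(render$total) / 255,
                  file.path(dir, "masks_total", paste0(id, ".png")))
    if (!is.null(render$box)) {
      boxes[[length(boxes) + 1L]] <- c(list(image_id = id),
                                       box_to_coco(render$box))
    }
  }
  write_coco_boxes(boxes, file.path(dir, "boxes.json"))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
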