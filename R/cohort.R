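#' Site-stratified patient split
#'
#' Randomly assigns patients to training, validation and test sets in an
#' 8:1:1 ratio within each site, so each site approximately follows the
#' proportion and no patient appears in more than one set. Validation and
#' test counts are floored (minimum 1 per set when the site has at least 3
#' patients) and the remainder goes to training; sites with fewer than 3
#' patients go entirely to training with a warning.
#'
#' @param patients Data frame with `patient_id` and `site_id` columns (a
#'   cohort manifest works; duplicates are collapsed).
#' @param ratio Length-3 train:validation:test ratio.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A tibble with `patient_id`, `site_id`, `set`.
#' @export
split_patients_by_site <- function(patients, ratio = c(8, 1, 1), seed = 1L) {
  patients <- dplyr::distinct(
    tibble::as_tibble(patients)[, c("patient_id", "site_id")]
  )
  if (anyDuplicated(patients$patient_id)) {
    abort("Each patient must belong to exactly one site.")
  }
  frac <- ratio / sum(ratio)
  with_local_seed(seed, {
    patients |>
      dplyr::group_by(.data$site_id) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        df <- df[sample.int(n), , drop = FALSE]
        if (n < 3) {
          warn(sprintf("Site %s has %d patient(s); all assigned to training.",
                       key$site_id, n))
          df$set <- "train"
          return(df)
        }
        n_val <- max(1L, floor(n * frac[2]))
        n_test <- max(1L, floor(n * frac[3]))
        df$set <- c(rep("validation", n_val), rep("test", n_test),
                    rep("train", n - n_val - n_test))
        df
      }) |>
      dplyr::ungroup() |>
      dplyr::select("patient_id", "site_id", "set") |>
      dplyr::arrange(.data$site_id, .data$patient_id)
  })
}

#' Central/peripheral grouping of the slices of a volume
#'
#' The middle 11 slices of a volume are central, the rest peripheral (for a
#' 49-slice macular volume: slices 19..29 central, 38 peripheral). The
#' centred window uses a floor offset, `floor((n - 11) / 2)`.
#'
#' @param n_slices Number of slices in the volume.
#' @param n_central Size of the central window (default 11).
#' @return A list with 0-based `central` and `peripheral` slice indices.
#' @export
group_bscans <- function(n_slices, n_central = 11L) {
  n_slices <- as.integer(n_slices)
  if (n_slices < n_central) {
    warn(sprintf("Volume has %d (< %d) slices; all classified as central.",
                 n_slices, n_central))
    return(list(central = seq_len(n_slices) - 1L, peripheral = integer(0)))
  }
  offset <- floor((n_slices - n_central) / 2)
  central <- offset + seq_len(n_central) - 1L
  list(central = central,
       peripheral = setdiff(seq_len(n_slices) - 1L, central))
}

#' Tag manifest rows as central or peripheral
#'
#' @param manifest A cohort manifest (see [generate_cohort()]).
#' @param n_slices Slices per volume; inferred from the manifest if omitted.
#' @return The manifest with a `region` column.
#' @export
classify_slices <- function(manifest, n_slices = NULL) {
  spec <- attr(manifest, "cohort_spec")
  n_slices <- n_slices %||% spec$slices_per_volume %||%
    (max(manifest$slice_index) + 1L)
  groups <- group_bscans(n_slices)
  dplyr::mutate(
    manifest,
    region = ifelse(.data$slice_index %in% groups$central,
                    "central", "peripheral")
  )
}

#' Sample a fixed number of B-scans per patient
#'
#' From each patient's pooled scans (across all visits and both eyes),
#' samples `n_per_patient` B-scans without replacement: 30% from the central
#' group and 70% from the peripheral group by default, with the central
#' count rounded half-up. If a group's pool is smaller than requested, all
#' available scans are taken with a warning.
#'
#' @param manifest Manifest rows for the patients to sample, carrying a
#'   `region` column (see [classify_slices()]).
#' @param n_per_patient Scans per patient (3 for training, 16 for the
#'   validation and test sets).
#' @param central_fraction Fraction drawn from the central group.
#' @param seed Integer seed.
#' @return The sampled manifest rows.
#' @export
sample_bscans <- function(manifest, n_per_patient,
                          central_fraction = 0.3, seed = 1L) {
  stopifnot("region" %in% names(manifest),
            central_fraction >= 0, central_fraction <= 1,
            n_per_patient >= 0)
  if (n_per_patient == 0) return(manifest[0, ])
  n_c <- round_half_up(n_per_patient * central_fraction)
  n_p <- n_per_patient - n_c
  with_local_seed(seed, {
    manifest |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::group_modify(function(df, key) {
        take <- function(pool, n, what) {
          if (nrow(pool) < n) {
            warn(sprintf("Patient %s: only %d %s scan(s) available (%d requested).",
                         key$patient_id, nrow(pool), what, n))
            n <- nrow(pool)
          }
          pool[sample.int(nrow(pool), n), , drop = FALSE]
        }
        dplyr::bind_rows(
          take(df[df$region == "central", , drop = FALSE], n_c, "central"),
          take(df[df$region == "peripheral", , drop = FALSE], n_p, "peripheral")
        )
      }) |>
      dplyr::ungroup()
  })
}

#' Build the initial training, validation, test and pool manifests
#'
#' Applies the site-stratified split, samples a fixed number of scans per
#' patient (3 for training, 16 for validation and test), and returns the
#' remaining scans of the training patients as the unannotated pool used by
#' the iterative learning loop.
#'
#' @param manifest A cohort manifest.
#' @param split Output of [split_patients_by_site()].
#' @param n_train,n_eval Scans sampled per training patient and per
#'   validation/test patient.
#' @param central_fraction Fraction drawn from the central group.
#' @param seed Integer seed.
#' @return A list of tibbles: `train`, `validation`, `test`, `pool`.
#' @export
build_initial_sets <- function(manifest, split, n_train = 3L, n_eval = 16L,
                               central_fraction = 0.3, seed = 1L) {
  spec <- attr(manifest, "cohort_spec")
  if (!"region" %in% names(manifest)) manifest <- classify_slices(manifest)
  tagged <- dplyr::inner_join(manifest, split[, c("patient_id", "set")],
                              by = "patient_id")
  pick <- function(which_set, n, s) {
    sample_bscans(dplyr::filter(tagged, .data$set == which_set),
                  n, central_fraction, seed = s)
  }
  train <- pick("train", n_train, seed)
  validation <- pick("validation", n_eval, seed + 1L)
  test <- pick("test", n_eval, seed + 2L)
  pool <- tagged |>
    dplyr::filter(.data$set == "train") |>
    dplyr::anti_join(train[, "scan_id"], by = "scan_id")
  out <- list(train = train, validation = validation, test = test, pool = pool)
  lapply(out, function(m) {
    attr(m, "cohort_spec") <- spec
    m
  })
}
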