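test_that("flat specs give horizontal boundaries at the base depths", {
  spec <- flat_phantom()
  b <- generate_boundaries(spec)
  expect_equal(dim(b), c(6L, spec$width))
  for (k in 1:6) {
    expect_true(all(b[k, ] == spec$base_depths[k]))
  }
})

test_that("boundary generation is deterministic under a fixed seed", {
  spec <- tiny_phantom(seed = 42)
  expect_identical(generate_boundaries(spec), generate_boundaries(spec))
  r1 <- render_bscan(generate_boundaries(spec), spec)
  r2 <- render_bscan(generate_boundaries(spec), spec)
  expect_identical(r1$image$image, r2$image$image)
})

test_that("the foveal dip depresses the inner surface by its stated depth", {
  spec <- phantom_spec(
    width = 512, height = 256,
    undulation = list(amplitude = 0, frequency = 1, jitter = 0),
    foveal_dip = list(center = 255.5, width = 60, depth = 40),
    noise = list(speckle = 0, gaussian_sd = 0), seed = 3
  )
  b <- generate_boundaries(spec)
  center <- b[1, 256] # column 255, at the dip centre (within half a pixel)
  far <- b[1, 2]      # ~17 sigma away: dip contribution is negligible
  expect_equal(unname(center - far), 40, tolerance = 1e-3)
})

test_that("a spec whose dip collapses the layer ordering is rejected", {
  spec <- flat_phantom()
  spec$foveal_dip <- list(center = 31.5, width = 30, depth = 30)
  expect_error(generate_boundaries(spec), "ordering|leave")
})

test_that("noise-free rendering is a piecewise-constant map of the labels", {
  spec <- flat_phantom()
  r <- render_bscan(generate_boundaries(spec), spec)
  expected <- matrix(spec$layer_intensities[unclass(r$sublayer) + 1L],
                     nrow = spec$height)
  expect_equal(r$image$image, expected)
})

test_that("sublayers partition the retina and flat bands have exact areas", {
  spec <- flat_phantom()
  r <- render_bscan(generate_boundaries(spec), spec)
  counts <- tabulate(unclass(r$sublayer) + 1L, nbins = 6L)
  # background + five sublayers tile the image
  expect_equal(sum(counts), spec$width * spec$height)
  # total mask is the union of the five sublayers
  expect_equal(sum(r$total), sum(counts[2:6]))
  # flat bands: class-k area = thickness * width
  t_k <- diff(spec$base_depths)
  expect_equal(counts[2:6], t_k * spec$width)
})

test_that("lesion-free sublayer columns run 1..5 contiguously top to bottom", {
  for (seed in 1:4) {
    spec <- tiny_phantom(seed = seed)
    r <- render_bscan(generate_boundaries(spec), spec)
    labels <- unclass(r$sublayer)
    for (j in seq(1, spec$width, by = 13)) {
      runs <- rle(labels[, j])
      expect_identical(runs$values[runs$values > 0L], 1:5)
    }
  }
})

test_that("severity-zero lesions leave the scan untouched and emit no box", {
  spec <- tiny_phantom(seed = 5)
  r <- render_bscan(generate_boundaries(spec), spec)
  les <- lesion_spec(list(c(40, 70)), "PR-OS", severity = 0)
  out <- inject_lesion(r, les)
  expect_identical(out, r)
  expect_null(out$box)
})

test_that("a full-collapse lesion yields a box covering exactly its span", {
  spec <- tiny_phantom(seed = 6)
  r <- render_bscan(generate_boundaries(spec), spec)
  out <- inject_lesion(r, lesion_spec(list(c(40, 70)), "PR-IS", severity = 1))
  expect_equal(out$box$x_start, 40)
  expect_equal(out$box$x_end, 70)
  expect_equal(out$box$confidence, 1)
  # column-wise audit: inside the box PR-IS is absent, outside all 5 present
  labels <- unclass(out$sublayer)
  for (j in seq_len(spec$width)) {
    thick <- tabulate(labels[labels[, j] > 0L, j], nbins = 5L)
    if (j >= 41 && j <= 70) {
      expect_equal(thick[3], 0)
    } else {
      expect_true(all(thick >= 1))
    }
  }
  # columns outside the spans keep their original pixels
  keep <- setdiff(seq_len(spec$width), 41:70)
  expect_identical(out$image$image[, keep], r$image$image[, keep])
})

test_that("two disjoint lesions merge into a single larger box", {
  spec <- phantom_spec(seed = 8) # nominal 1024 x 496 geometry
  r <- render_bscan(generate_boundaries(spec), spec)
  les <- lesion_spec(list(c(100, 150), c(800, 850)), c("PR-OS"), severity = 1)
  out <- inject_lesion(r, les)
  expect_equal(nrow(out$box), 1L)
  expect_equal(out$box$x_start, 100)
  expect_equal(out$box$x_end, 850)
  expect_equal(out$box$confidence, 100 / 750)
})

test_that("the total band stays connected per column after collapse", {
  spec <- tiny_phantom(seed = 9)
  r <- render_bscan(generate_boundaries(spec), spec)
  out <- inject_lesion(r, lesion_spec(list(c(30, 90)),
                                      c("ONL", "PR-IS", "PR-OS"),
                                      severity = 1))
  total <- unclass(out$total)
  for (j in seq_len(spec$width)) {
    runs <- rle(total[, j])
    expect_equal(sum(runs$values == 1L), 1L)
  }
  # the atrophic band thins inside the span and is untouched outside
  inside <- 31:90
  expect_true(all(colSums(total[, inside]) < colSums(unclass(r$total))[inside]))
  expect_equal(colSums(total)[-inside], colSums(unclass(r$total))[-inside])
})

test_that("invalid lesion specs are rejected", {
  expect_error(lesion_spec(list(c(0, 10)), character(0)), "at least one")
  expect_error(lesion_spec(list(c(0, 10)), "IR"), "drawn from")
  spec <- tiny_phantom(seed = 2)
  r <- render_bscan(generate_boundaries(spec), spec)
  expect_error(
    inject_lesion(r, lesion_spec(list(c(100, 300)), "RPE", severity = 1)),
    "outside the image"
  )
})

test_that("cohort manifests have one row per B-scan and are reproducible", {
  cs <- cohort_spec(sites = c(X = 1), visits = 1, eyes = "OD",
                    slices_per_volume = 49, width = 64, height = 64, seed = 4)
  man <- generate_cohort(cs)
  expect_equal(nrow(man), 49L)
  expect_identical(man, generate_cohort(cs))
})

test_that("patient severity increases monotonically across visits", {
  cs <- cohort_spec(sites = c(A = 4, B = 3), visits = 5,
                    slices_per_volume = 3, width = 64, height = 64, seed = 10)
  man <- generate_cohort(cs)
  by_visit <- man |>
    dplyr::distinct(patient_id, visit, severity) |>
    dplyr::arrange(patient_id, visit)
  deltas <- by_visit |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(ok = all(diff(severity) >= 0))
  expect_true(all(deltas$ok))
  # volume bookkeeping: one volume per patient x visit x eye
  vols <- dplyr::distinct(man, patient_id, visit, eye)
  expect_equal(nrow(vols), 7 * 5 * 2)
})

test_that("cohort images round-trip through PNG and COCO files", {
  dir <- withr::local_tempdir()
  cs <- cohort_spec(sites = c(A = 1), visits = 1, eyes = "OD",
                    slices_per_volume = 2, width = 64, height = 64,
                    baseline_range = c(0.7, 0.8), seed = 21)
  man <- generate_cohort(cs, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  r <- render_manifest_row(man[1, ], cs)
  img <- read_bscan_png(file.path(dir, "images", paste0(man$scan_id[1], ".png")))
  expect_equal(dim(img), dim(r$image$image))
  mask <- read_mask_png(file.path(dir, "masks_sublayer",
                                  paste0(man$scan_id[1], ".png")))
  expect_identical(unclass(mask), unclass(r$sublayer))
  boxes <- read_coco_boxes(file.path(dir, "boxes.json"))
  expect_true(all(c("x_start", "x_end", "y_start", "y_end") %in% names(boxes)))
  expect_true(man$scan_id[1] %in% boxes$image_id)
})
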