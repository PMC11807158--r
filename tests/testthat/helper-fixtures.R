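# Shared fixtures and independent oracles for the test suite.

# label-mask values as a bare integer matrix (drops class/mode attributes)
mask_values <- function(m) {
  matrix(as.integer(m), nrow = nrow(m), ncol = ncol(m))
}

# small phantom spec used across tests (even dims for the encoder-decoder)
tiny_phantom <- function(seed = 1, width = 128L, height = 64L, ...) {
  phantom_spec(width = width, height = height, seed = seed, ...)
}

# noise- and curvature-free spec: flat boundaries, piecewise-constant image
flat_phantom <- function(width = 64L, height = 64L,
                         base_depths = c(10, 24, 34, 40, 46, 54), seed = 1) {
  phantom_spec(
    width = width, height = height, base_depths = base_depths,
    undulation = list(amplitude = 0, frequency = 1, jitter = 0),
    foveal_dip = list(depth = 0),
    noise = list(speckle = 0, gaussian_sd = 0),
    seed = seed
  )
}

# random probability array via a softmax of Gaussian scores
random_probs <- function(H, W, C, seed) {
  set.seed(seed)
  z <- array(rnorm(H * W * C), c(H, W, C))
  e <- exp(z)
  s <- apply(e, c(1, 2), sum)
  e / array(rep(s, C), c(H, W, C))
}

# brute-force per-pixel loss oracles (plain loops, no vectorisation)
oracle_masked_ce <- function(probs, labels, mask, norm = "literal") {
  H <- dim(probs)[1]; W <- dim(probs)[2]
  total <- 0
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      m <- if (is.null(mask)) 1 else mask[r, cc]
      if (m == 0) next
      p <- max(probs[r, cc, labels[r, cc] + 1], 1e-7)
      total <- total - log(p)
    }
  }
  denom <- if (is.null(mask) || norm == "literal") H * W else sum(mask)
  total / denom
}

oracle_masked_dice <- function(probs, labels, mask, classes) {
  H <- dim(probs)[1]; W <- dim(probs)[2]
  vals <- c()
  for (k in classes) {
    num <- 0; den <- 0
    for (r in seq_len(H)) {
      for (cc in seq_len(W)) {
        m <- if (is.null(mask)) 1 else mask[r, cc]
        y <- as.numeric(labels[r, cc] == k)
        p <- probs[r, cc, k + 1]
        num <- num + m * y * p
        den <- den + m * y + m * p
      }
    }
    if (den > 0) vals <- c(vals, 1 - 2 * num / den)
  }
  if (length(vals) == 0) 0 else mean(vals)
}

# independent IoU via rasterisation on an integer grid
oracle_raster_iou <- function(a, b, H = 40, W = 40) {
  rast <- function(z) {
    m <- matrix(FALSE, H, W)
    if (z$x_end > z$x_start && z$y_end > z$y_start) {
      m[(z$y_start + 1):z$y_end, (z$x_start + 1):z$x_end] <- TRUE
    }
    m
  }
  ra <- rast(as.list(a[1, ])); rb <- rast(as.list(b[1, ]))
  if (sum(ra | rb) == 0) return(0)
  sum(ra & rb) / sum(ra | rb)
}

# naive reimplementation of the confidence-ordered greedy matching protocol,
# using rasterised IoU
oracle_match <- function(detections, ground_truths, iou_threshold) {
  det <- detections[order(-detections$confidence), , drop = FALSE]
  used <- rep(FALSE, nrow(ground_truths))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    best <- 0; best_j <- 0
    for (j in seq_len(nrow(ground_truths))) {
      if (used[j] || ground_truths$image_id[j] != det$image_id[i]) next
      iou <- oracle_raster_iou(det[i, ], ground_truths[j, ])
      if (iou > best) { best <- iou; best_j <- j }
    }
    if (best_j > 0 && best >= iou_threshold) {
      tp[i] <- TRUE
      used[best_j] <- TRUE
    }
  }
  tp
}

# a small diseased + healthy render pool shared by model-dependent tests;
# built once per test run
fixture_env <- new.env(parent = emptyenv())

tiny_cohort_renders <- function() {
  if (!is.null(fixture_env$renders)) return(fixture_env$renders)
  dis_spec <- cohort_spec(sites = c(A = 6), visits = 2, slices_per_volume = 5,
                          width = 64, height = 64, seed = 101)
  hea_spec <- cohort_spec(sites = c(A = 6), visits = 2, slices_per_volume = 5,
                          width = 64, height = 64, healthy = TRUE, seed = 102)
  dis <- generate_cohort(dis_spec)
  hea <- generate_cohort(hea_spec)
  set.seed(7)
  lesioned <- which(dis$has_lesion)
  clean <- which(!dis$has_lesion)
  renders <- list(
    diseased = lapply(sample(lesioned, min(10, length(lesioned))),
                      function(i) render_manifest_row(dis[i, ], dis_spec)),
    healthy = lapply(sample(nrow(hea), 10),
                     function(i) render_manifest_row(hea[i, ], hea_spec)),
    mild = lapply(head(clean, 4),
                  function(i) render_manifest_row(dis[i, ], dis_spec))
  )
  fixture_env$renders <- renders
  renders
}

# small trained segmenters shared by the detection/composition tests
tiny_models <- function() {
  if (!is.null(fixture_env$models)) return(fixture_env$models)
  r <- tiny_cohort_renders()
  train <- c(r$healthy[1:6], r$diseased[1:6])
  val <- c(r$healthy[7:8], r$diseased[7:8])
  cfg <- train_config(lr = 0.01, epochs = 25, batch_size = 4, seed = 11,
                      loss_mode = "pathology-aware")
  cfg_tot <- train_config(lr = 0.01, epochs = 8, batch_size = 4, seed = 11)
  models <- list(
    total = train_total_retina(train, val, config = cfg_tot),
    sublayer = train_sublayers(train, val, config = cfg)
  )
  fixture_env$models <- models
  models
}
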