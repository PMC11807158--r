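# Small encoder-decoder segmenter: 3x3 conv (16 filters) -> 2x2 average
# pool -> 3x3 conv -> nearest 2x upsample -> skip concatenation -> 3x3 conv
# -> 1x1 conv to class logits. Feature maps are (H*W) x channels matrices
# (pixel index = row + H * col); the conv/pool/upsample kernels live in
# src/convops.cpp. Trained with Adam on the combined (optionally masked)
# cross-entropy + Dice loss.

relu <- function(x) x * (x > 0)

nn_init <- function(n_classes, in_channels = 2L, n_filters = 16L) {
  he <- function(nin, nout, fan) {
    matrix(rnorm(nin * nout, sd = sqrt(2 / fan)), nrow = nin, ncol = nout)
  }
  f <- n_filters
  list(
    w1 = he(9 * in_channels, f, 9 * in_channels), b1 = rep(0, f),
    w2 = he(9 * f, f, 9 * f), b2 = rep(0, f),
    w3 = he(9 * 2 * f, f, 9 * 2 * f), b3 = rep(0, f),
    w4 = he(f, n_classes, f), b4 = rep(0, n_classes)
  )
}

nn_forward <- function(params, x, H, W) {
  a1 <- relu(cpp_conv3_fwd(x, H, W, params$w1, params$b1))
  p <- cpp_pool2_fwd(a1, H, W)
  a2 <- relu(cpp_conv3_fwd(p, H %/% 2L, W %/% 2L, params$w2, params$b2))
  u <- cpp_up2_fwd(a2, H %/% 2L, W %/% 2L)
  cat1u <- cbind(a1, u)
  a3 <- relu(cpp_conv3_fwd(cat1u, H, W, params$w3, params$b3))
  z <- sweep(a3 %*% params$w4, 2, params$b4, "+")
  zs <- z - apply(z, 1, max)
  e <- exp(zs)
  probs <- e / rowSums(e)
  list(x = x, a1 = a1, p = p, a2 = a2, cat1u = cat1u, a3 = a3, probs = probs)
}

nn_backward <- function(params, cache, dz, H, W) {
  gw4 <- crossprod(cache$a3, dz)
  gb4 <- colSums(dz)
  da3 <- tcrossprod(dz, params$w4) * (cache$a3 > 0)
  b3 <- cpp_conv3_bwd(cache$cat1u, H, W, params$w3, da3)
  f <- ncol(cache$a1)
  da1_skip <- b3$gx[, seq_len(f), drop = FALSE]
  du <- b3$gx[, f + seq_len(f), drop = FALSE]
  da2 <- cpp_up2_bwd(du, H %/% 2L, W %/% 2L) * (cache$a2 > 0)
  b2 <- cpp_conv3_bwd(cache$p, H %/% 2L, W %/% 2L, params$w2, da2)
  gp <- cpp_pool2_bwd(b2$gx, H, W)
  da1 <- (da1_skip + gp) * (cache$a1 > 0)
  b1 <- cpp_conv3_bwd(cache$x, H, W, params$w1, da1)
  list(
    w1 = b1$gw, b1 = as.vector(b1$gb),
    w2 = b2$gw, b2 = as.vector(b2$gb),
    w3 = b3$gw, b3 = as.vector(b3$gb),
    w4 = gw4, b4 = gb4
  )
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# combined-loss value and gradient w.r.t. the logits for one image within a
# batch. probs: (H*W) x C; y: 0-based label vector; m: 0/1 vector or NULL.
# n_batch_pixels / n_unmasked_batch normalise the CE term over the whole
# batch; the Dice term is averaged per image (n_images).
nn_loss_grad <- function(probs, y, m, n_batch_pixels, n_unmasked_batch,
                         n_images, norm = "literal") {
  npix <- nrow(probs)
  C <- ncol(probs)
  mvec <- if (is.null(m)) rep(1, npix) else m
  Y <- matrix(0, npix, C)
  Y[cbind(seq_len(npix), y + 1L)] <- 1

  ce_denom <- if (norm == "literal") n_batch_pixels else max(n_unmasked_batch, 1)
  p_true <- pmax(probs[cbind(seq_len(npix), y + 1L)], LOSS_EPS)
  ce <- sum(mvec * -log(p_true)) / ce_denom
  dz_ce <- (probs - Y) * (mvec / ce_denom)

  classes <- seq_len(C - 1)  # Dice excludes background
  dLdp <- matrix(0, npix, C)
  dice_terms <- numeric(0)
  for (k in classes) {
    yk <- Y[, k + 1L]
    pk <- probs[, k + 1L]
    Dk <- sum(mvec * yk) + sum(mvec * pk)
    if (Dk == 0) next
    Nk <- sum(mvec * yk * pk)
    dice_terms <- c(dice_terms, 1 - 2 * Nk / Dk)
    dLdp[, k + 1L] <- -2 * mvec * (yk * Dk - Nk) / Dk^2
  }
  n_active <- length(dice_terms)
  dice <- if (n_active == 0) 0 else mean(dice_terms)
  if (n_active > 0) {
    dLdp <- dLdp / (n_active * n_images)
    dz_dice <- probs * (dLdp - rowSums(dLdp * probs))
  } else {
    dz_dice <- dLdp
  }
  # `dice` is this image's Dice loss; the caller averages over the batch,
  # matching the 1/n_images factor already inside dz_dice.
  list(ce = ce, dice = dice, dz = dz_ce + dz_dice)
}

# input feature planes: the image and a normalised row coordinate
nn_input <- function(image) {
  H <- nrow(image)
  W <- ncol(image)
  rowcoord <- matrix(seq_len(H) / H - 0.5, H, W)
  cbind(as.vector(image), as.vector(rowcoord))
}

#' Per-pixel argmax labels of a probability map
#'
#' @param probs A height x width x classes array.
#' @return An integer matrix of 0-based class labels.
#' @export
prob_argmax <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}
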