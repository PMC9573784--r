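# Minimal U-Net-style encoder-decoder. Feature maps are C x N' matrices over
# a zero-padded (H+2) x (W+2) grid (flat pixel p = col*(H+2) + row, 0-based),
# so the compiled conv kernel can run each 3x3 offset as one accumulating
# GEMM on a pointer-offset view (see src/convops.cpp). Pooling, upsampling
# and their gradients are compiled; activations, the loss and Adam live in R.

# 1-based flat indices of the interior (true image) pixels of a padded grid,
# in column-major image order.
interior_index <- function(H, W) {
  as.vector(outer(2:(H + 1), (1:W) * (H + 2), `+`))
}

# H x W x C array -> C x N' padded flat matrix with zero border.
pad_flat <- function(a) {
  H <- dim(a)[1]; W <- dim(a)[2]; C <- dim(a)[3]
  X <- matrix(0, C, (H + 2) * (W + 2))
  X[, interior_index(H, W)] <- matrix(aperm(a, c(3, 1, 2)), C, H * W)
  X
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Soft Dice loss (smooth = 1), averaged over output channels. P and Tm are
# unpadded K x (H*W) matrices.
soft_dice_loss <- function(P, Tm, smooth = 1) {
  K <- nrow(P)
  loss <- 0
  dP <- matrix(0, K, ncol(P))
  for (k in seq_len(K)) {
    p <- P[k, ]; t <- Tm[k, ]
    num <- 2 * sum(p * t) + smooth
    den <- sum(p) + sum(t) + smooth
    loss <- loss + (1 - num / den)
    dP[k, ] <- -(2 * t * den - num) / den^2 / K
  }
  list(loss = loss / K, dP = dP)
}

# --- model -----------------------------------------------------------------

he_init <- function(c_out, c_in, k2 = 9L) {
  matrix(rnorm(c_out * c_in * k2, 0, sqrt(2 / (c_in * k2))), c_out, c_in * k2)
}

# Parameter list + level bookkeeping. `depth` encoder levels (conv + pool
# each), a bottleneck conv, `depth` decoder levels (upsample + skip concat +
# conv), and a final 1x1 conv to n_out logits. The output bias starts at -2
# so early predictions lean empty: the soft-Dice loss is then driven by its
# true-positive term, which avoids the all-background local minimum that
# half-on initial predictions can fall into on small foregrounds.
unet_init <- function(input_size, depth, base_channels, n_out, seed) {
  chans <- base_channels * 2^(0:(depth - 1))
  sizes <- input_size / 2^(0:depth)
  if (any(sizes != floor(sizes)))
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  params <- with_seed(seed, {
    p <- list()
    c_prev <- 3L
    for (l in seq_len(depth)) {
      p[[paste0("enc", l)]] <- list(W = he_init(chans[l], c_prev),
                                    b = numeric(chans[l]))
      c_prev <- chans[l]
    }
    cb <- base_channels * 2^depth
    p$bott <- list(W = he_init(cb, c_prev), b = numeric(cb))
    c_prev <- cb
    for (l in rev(seq_len(depth))) {
      p[[paste0("dec", l)]] <- list(W = he_init(chans[l], c_prev + chans[l]),
                                    b = numeric(chans[l]))
      c_prev <- chans[l]
    }
    p$out <- list(W = matrix(rnorm(n_out * chans[1], 0, sqrt(2 / chans[1])),
                             n_out, chans[1]),
                  b = rep(-2, n_out))
    p
  })
  list(params = params, depth = depth, chans = chans, sizes = sizes,
       n_out = n_out, input_size = input_size,
       int_idx = interior_index(input_size, input_size))
}

# Forward pass. X: 3 x N' padded input. Returns unpadded K x (H*W)
# probabilities; with `keep`, also the caches needed for backprop.
unet_fw <- function(net, X, keep = FALSE) {
  D <- net$depth
  enc_in <- vector("list", D); enc_act <- vector("list", D)
  pool_arg <- vector("list", D)
  h <- X
  for (l in seq_len(D)) {
    S <- net$sizes[l]
    enc_in[[l]] <- h
    A <- pmax(conv3p_fw(h, net$params[[paste0("enc", l)]]$W,
                        net$params[[paste0("enc", l)]]$b, S, S), 0)
    enc_act[[l]] <- A
    mp <- maxpool2p(A, S, S)
    pool_arg[[l]] <- if (keep) mp$argmax else NULL
    h <- mp$out
  }
  Sb <- net$sizes[D + 1L]
  bott_in <- h
  Ab <- pmax(conv3p_fw(h, net$params$bott$W, net$params$bott$b, Sb, Sb), 0)
  h <- Ab
  dec_in <- vector("list", D); dec_act <- vector("list", D)
  for (l in rev(seq_len(D))) {
    S2 <- net$sizes[l + 1L]
    U <- upsample2p(h, S2, S2)
    Cc <- rbind(U, enc_act[[l]])
    dec_in[[l]] <- Cc
    h <- pmax(conv3p_fw(Cc, net$params[[paste0("dec", l)]]$W,
                        net$params[[paste0("dec", l)]]$b,
                        net$sizes[l], net$sizes[l]), 0)
    dec_act[[l]] <- h
  }
  logits <- net$params$out$W %*% h + net$params$out$b
  P <- sigmoid(logits[, net$int_idx, drop = FALSE])
  if (!keep) return(list(P = P))
  list(P = P, enc_in = enc_in, enc_act = enc_act, pool_arg = pool_arg,
       bott_in = bott_in, bott_act = Ab, dec_in = dec_in, dec_act = dec_act)
}

# Backward pass from dL/dP (unpadded). Returns gradients shaped like params.
unet_bw <- function(net, cache, dP) {
  D <- net$depth
  g <- list()
  P <- cache$P
  dZi <- dP * P * (1 - P)                      # through the sigmoid
  dZ <- matrix(0, nrow(dZi), (net$input_size + 2)^2)
  dZ[, net$int_idx] <- dZi
  g$out <- list(W = tcrossprod(dZ, cache$dec_act[[1L]]), b = rowSums(dZ))
  dh <- crossprod(net$params$out$W, dZ)
  skip_grad <- vector("list", D)
  for (l in seq_len(D)) {                      # finest decoder level first
    S <- net$sizes[l]
    dZl <- dh * (cache$dec_act[[l]] > 0)
    bw <- conv3p_bw(dZl, cache$dec_in[[l]],
                    net$params[[paste0("dec", l)]]$W, S, S)
    g[[paste0("dec", l)]] <- list(W = bw$dW, b = bw$db)
    c_up <- nrow(cache$dec_in[[l]]) - net$chans[l]
    S2 <- net$sizes[l + 1L]
    dh <- upsample2p_bw(bw$dX[seq_len(c_up), , drop = FALSE], S2, S2)
    skip_grad[[l]] <- bw$dX[(c_up + 1L):nrow(cache$dec_in[[l]]), ,
                            drop = FALSE]
  }
  Sb <- net$sizes[D + 1L]
  dZb <- dh * (cache$bott_act > 0)
  bw <- conv3p_bw(dZb, cache$bott_in, net$params$bott$W, Sb, Sb)
  g$bott <- list(W = bw$dW, b = bw$db)
  dh <- bw$dX
  for (l in rev(seq_len(D))) {
    S <- net$sizes[l]
    dA <- maxpool2p_bw(dh, cache$pool_arg[[l]], (S + 2L)^2) + skip_grad[[l]]
    dZl <- dA * (cache$enc_act[[l]] > 0)
    bw <- conv3p_bw(dZl, cache$enc_in[[l]],
                    net$params[[paste0("enc", l)]]$W, S, S)
    g[[paste0("enc", l)]] <- list(W = bw$dW, b = bw$db)
    dh <- bw$dX
  }
  g
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

# b2 = 0.99 (not the textbook 0.999): with only ~200 updates per training
# run, a long second-moment memory would keep the step size depressed for
# the whole run after any early gradient spike; 0.99 lets the optimiser
# recover within ~100 steps.
adam_step <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.99, eps = 1e-8) {
  for (nm in names(params)) {
    s <- state[[nm]]; gr <- grads[[nm]]
    s$mW <- b1 * s$mW + (1 - b1) * gr$W
    s$vW <- b2 * s$vW + (1 - b2) * gr$W^2
    s$mb <- b1 * s$mb + (1 - b1) * gr$b
    s$vb <- b2 * s$vb + (1 - b2) * gr$b^2
    mhW <- s$mW / (1 - b1^t); vhW <- s$vW / (1 - b2^t)
    mhb <- s$mb / (1 - b1^t); vhb <- s$vb / (1 - b2^t)
    params[[nm]]$W <- params[[nm]]$W - lr * mhW / (sqrt(vhW) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# Sum two gradient lists (batch accumulation).
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(a)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

grad_scale <- function(g, f) {
  for (nm in names(g)) { g[[nm]]$W <- g[[nm]]$W * f; g[[nm]]$b <- g[[nm]]$b * f }
  g
}
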