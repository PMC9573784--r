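#' Segmentation network configuration
#'
#' Hyperparameters for the encoder-decoder segmentation networks. The stigma
#' network has one output channel (stigma envelope); the ovary network has two
#' (ovary, stigma), mirroring how the two traits are annotated.
#'
#' @param input_size square side length images are resized to for the network,
#'   pixels; must be divisible by `2^depth`. 256 for production use, 128 for
#'   the desk-scale benchmark.
#' @param depth number of encoder levels (each halves the resolution).
#' @param base_channels feature channels at the first level; doubled per level.
#' @param n_output_channels 1 (stigma net) or 2 (ovary net).
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size images per weight update.
#' @param val_fraction fraction of the training images held aside for the
#'   per-epoch validation loss.
#' @param seed seed fixing initialisation, the train/validation split,
#'   shuffling and augmentation draws.
#' @param binarize_threshold threshold on the sigmoid output.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(input_size = 256L, depth = 4L, base_channels = 16L,
                       n_output_channels = 1L, learning_rate = 1e-3,
                       epochs = 15L, batch_size = 4L, val_fraction = 0.2,
                       seed = 0L, binarize_threshold = 0.5) {
  cfg <- structure(list(
    input_size = as.integer(input_size), depth = as.integer(depth),
    base_channels = as.integer(base_channels),
    n_output_channels = as.integer(n_output_channels),
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), val_fraction = val_fraction,
    seed = as.integer(seed), binarize_threshold = binarize_threshold
  ), class = "seg_config")
  if (cfg$input_size %% 2^cfg$depth != 0)
    stop(sprintf("input_size (%d) must be divisible by 2^depth (%d)",
                 cfg$input_size, 2^cfg$depth), call. = FALSE)
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    stop("val_fraction must lie in (0, 1)", call. = FALSE)
  if (cfg$binarize_threshold <= 0 || cfg$binarize_threshold >= 1)
    stop("binarize_threshold must lie in (0, 1)", call. = FALSE)
  if (!cfg$n_output_channels %in% 1:2)
    stop("n_output_channels must be 1 (stigma net) or 2 (ovary net)",
         call. = FALSE)
  cfg
}

# --- resizing helpers (EBImage, bilinear) ---------------------------------

resize_mat <- function(m, H2, W2) {
  if (nrow(m) == H2 && ncol(m) == W2) return(m)
  t(as.matrix(EBImage::resize(t(m), w = W2, h = H2)))
}

resize_rgb <- function(a, H2, W2) {
  if (dim(a)[1] == H2 && dim(a)[2] == W2) return(a)
  out <- array(0, c(H2, W2, dim(a)[3]))
  for (ch in seq_len(dim(a)[3])) out[, , ch] <- resize_mat(a[, , ch], H2, W2)
  out
}

# --- augmentation (flips and 90-degree rotations) -------------------------

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

aug_mat <- function(m, code) {
  k <- code %% 4L
  for (i in seq_len(k)) m <- rot90cw(m)
  if (code >= 4L) m <- m[, ncol(m):1, drop = FALSE]
  m
}

# array/matrix <-> C x N flattening (pixel p = (col-1)*H + row)

flatten_masks <- function(ms) do.call(rbind, lapply(ms, as.vector))

carpel_pixels <- function(image) {
  if (inherits(image, "carpel_image")) image$img else image
}

# Normalise `truths` to a list of length-K mask lists and validate.
canon_truths <- function(truths, images, K) {
  lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    if (is.matrix(tr)) tr <- list(tr)
    if (length(tr) != K)
      stop(sprintf("image %d: %d truth mask(s) supplied but the network has %d output channel(s)",
                   i, length(tr), K), call. = FALSE)
    img <- carpel_pixels(images[[i]])
    for (m in tr) {
      assert_mask(m, sprintf("truths[[%d]]", i))
      if (!all(dim(m) == dim(img)[1:2]))
        stop(sprintf("image %d: truth mask dimensions %dx%d do not match image %dx%d",
                     i, nrow(m), ncol(m), dim(img)[1], dim(img)[2]), call. = FALSE)
    }
    tr
  })
}

#' Train a segmentation network
#'
#' Trains a small encoder-decoder network with a soft-Dice loss (1 minus the
#' smoothed Dice coefficient, averaged over output channels) and Adam weight
#' updates. Images and truth masks are resized to `config$input_size` for
#' training; prediction resizes masks back to native resolution, so geometry
#' is always measured at the acquisition scale. Training is deterministic
#' given `(data, config)`: the seed fixes initialisation, the 80/20
#' train/validation split, shuffling and the flip/rotation augmentation.
#'
#' @param images list of `carpel_image` objects (or H x W x 3 arrays).
#' @param truths list of ground-truth masks: for a 1-channel network a binary
#'   matrix (or list of one) per image; for the 2-channel ovary network a list
#'   `(ovary, stigma)` per image.
#' @param config a [seg_config()].
#' @return An object of class `carpel_segmenter` with elements `net` (weights
#'   and index caches), `config`, and `training_log` (data.frame: epoch,
#'   train_loss, val_loss).
#' @export
train_segmenter <- function(images, truths, config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  n <- length(images)
  if (n < 10L) stop("at least 10 annotated images are required", call. = FALSE)
  if (length(truths) != n)
    stop("images and truths must have the same length", call. = FALSE)
  K <- config$n_output_channels
  truths <- canon_truths(truths, images, K)
  S <- config$input_size

  # resize once, up front
  xs <- lapply(images, function(im) resize_rgb(carpel_pixels(im), S, S))
  ts <- lapply(truths, function(tr)
    lapply(tr, function(m) (resize_mat(m, S, S) > 0.5) * 1))

  # One full training run from a given initialisation seed. The learning
  # rate is warmed up linearly over the first 50 updates: full-size Adam
  # steps straight from initialisation can push all logits deep into
  # sigmoid saturation, where the Dice gradient vanishes and training
  # freezes on an all-background prediction. If the first epochs
  # nevertheless end in that collapsed state (validation loss near its
  # empty-prediction ceiling), the run is abandoned and restarted from a
  # re-derived initialisation seed; the whole procedure stays a
  # deterministic function of (data, config).
  run_training <- function(init_seed) {
    net <- unet_init(S, config$depth, config$base_channels, K, init_seed)
    st <- adam_init(net$params)
    with_seed(config$seed + 1L, {
      n_val <- max(1L, round(config$val_fraction * n))
      val_idx <- sample(n, n_val)
      tr_idx <- setdiff(seq_len(n), val_idx)
      step <- 0L
      log_rows <- vector("list", config$epochs)
      for (ep in seq_len(config$epochs)) {
        ord <- sample(tr_idx)
        codes <- sample(0:7, length(ord), replace = TRUE)
        ep_loss <- 0
        bstarts <- seq(1L, length(ord), by = config$batch_size)
        for (bs in bstarts) {
          be <- min(bs + config$batch_size - 1L, length(ord))
          gacc <- NULL
          for (j in bs:be) {
            i <- ord[j]; code <- codes[j]
            a <- xs[[i]]
            Xa <- array(0, dim(a))
            for (ch in 1:3) Xa[, , ch] <- aug_mat(a[, , ch], code)
            Tm <- flatten_masks(lapply(ts[[i]], aug_mat, code = code))
            X <- pad_flat(Xa)
            fw <- unet_fw(net, X, keep = TRUE)
            sd <- soft_dice_loss(fw$P, Tm)
            if (!is.finite(sd$loss))
              stop(sprintf("non-finite training loss at epoch %d; aborting",
                           ep), call. = FALSE)
            ep_loss <- ep_loss + sd$loss
            gacc <- grad_add(gacc, unet_bw(net, fw, sd$dP))
          }
          gacc <- grad_scale(gacc, 1 / (be - bs + 1L))
          step <- step + 1L
          lr_eff <- config$learning_rate * min(1, step / 50)
          upd <- adam_step(net$params, gacc, st, lr_eff, step)
          net$params <- upd$params; st <- upd$state
        }
        vloss <- mean(vapply(val_idx, function(i) {
          fw <- unet_fw(net, pad_flat(xs[[i]]))
          soft_dice_loss(fw$P, flatten_masks(ts[[i]]))$loss
        }, numeric(1)))
        log_rows[[ep]] <- data.frame(epoch = ep,
                                     train_loss = ep_loss / length(ord),
                                     val_loss = vloss)
        if (ep >= 4L && vloss > 0.9)
          return(list(collapsed = TRUE, net = net,
                      log = do.call(rbind, log_rows[seq_len(ep)])))
      }
      list(collapsed = FALSE, net = net, log = do.call(rbind, log_rows))
    })
  }

  attempt <- 1L
  res <- run_training(config$seed)
  while (res$collapsed && attempt < 4L) {
    attempt <- attempt + 1L
    res <- run_training(config$seed + 1000L * (attempt - 1L))
  }
  structure(list(net = res$net, config = config, training_log = res$log,
                 restarts = attempt - 1L),
            class = "carpel_segmenter")
}

#' Predict tissue masks for one image
#'
#' Runs the trained network on an RGB image: the image is resized to the
#' network's input size, the sigmoid probability maps are resized back to the
#' image's native resolution (bilinear), and thresholded at
#' `config$binarize_threshold`. Inference is deterministic.
#'
#' @param segmenter a trained [train_segmenter()] object.
#' @param image a `carpel_image` or H x W x 3 array.
#' @return For a stigma network, `list(stigma = mask)`; for an ovary network,
#'   `list(ovary = mask, stigma = mask)`. Masks are binary matrices at native
#'   resolution.
#' @export
predict_masks <- function(segmenter, image) {
  stopifnot(inherits(segmenter, "carpel_segmenter"))
  a <- carpel_pixels(image)
  if (!is.array(a) || length(dim(a)) != 3L || dim(a)[3] != 3L)
    stop("image must be an RGB array (H x W x 3); grayscale or empty input is not supported",
         call. = FALSE)
  if (any(dim(a)[1:2] == 0L)) stop("empty image", call. = FALSE)
  S <- segmenter$config$input_size
  X <- pad_flat(resize_rgb(a, S, S))
  P <- unet_fw(segmenter$net, X)$P
  H <- dim(a)[1]; W <- dim(a)[2]
  thr <- segmenter$config$binarize_threshold
  masks <- lapply(seq_len(nrow(P)), function(k) {
    pm <- resize_mat(matrix(P[k, ], S, S), H, W)
    (pm > thr) * 1
  })
  if (segmenter$config$n_output_channels == 1L) {
    names(masks) <- "stigma"
  } else {
    names(masks) <- c("ovary", "stigma")
  }
  masks
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a small union-find.
label8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  H <- nrow(lab); W <- ncol(lab)
  d1 <- cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1]))   # \ diagonal
  d2 <- cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1]))   # / diagonal
  prs <- rbind(d1, d2)
  prs <- unique(prs[prs[, 1] > 0 & prs[, 2] > 0 & prs[, 1] != prs[, 2], ,
                    drop = FALSE])
  for (i in seq_len(nrow(prs))) {
    ra <- find(prs[i, 1]); rb <- find(prs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lab
  out[lab > 0] <- roots[lab[lab > 0]]
  out
}

#' Post-process a predicted mask
#'
#' Keeps the largest 8-connected component and fills interior holes, so the
#' downstream diameter algorithm sees a single simply-connected region. An
#' empty input yields an empty mask carrying attribute `empty = TRUE`.
#'
#' @param mask binary matrix.
#' @return Binary matrix; largest component with holes filled. Attribute
#'   `empty` is TRUE when the input had no foreground pixels.
#' @export
postprocess_mask <- function(mask) {
  assert_mask(mask)
  if (sum(mask) == 0) {
    attr(mask, "empty") <- TRUE
    return(mask)
  }
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)              # ties: lowest label, deterministic
  comp <- (lab == keep) * 1
  filled <- (as.matrix(EBImage::fillHull(comp)) > 0) * 1
  attr(filled, "empty") <- FALSE
  filled
}

#' Save / load a trained segmenter
#'
#' Single-file checkpoint with a versioned header (format tag and config echo)
#' so stale checkpoints are rejected on load.
#'
#' @param segmenter a `carpel_segmenter`.
#' @param path file path.
#' @export
save_segmenter <- function(segmenter, path) {
  stopifnot(inherits(segmenter, "carpel_segmenter"))
  obj <- list(format = "carpelseg-segmenter-v1",
              config = segmenter$config,
              training_log = segmenter$training_log,
              params = segmenter$net$params,
              arch = segmenter$net[c("depth", "chans", "sizes", "n_out",
                                     "input_size")])
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "carpelseg-segmenter-v1"))
    stop("not a carpelseg segmenter checkpoint (or unsupported version)",
         call. = FALSE)
  cfg <- obj$config
  net <- unet_init(cfg$input_size, cfg$depth, cfg$base_channels,
                   cfg$n_output_channels, cfg$seed)
  net$params <- obj$params
  structure(list(net = net, config = cfg, training_log = obj$training_log),
            class = "carpel_segmenter")
}

#' @export
print.carpel_segmenter <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<carpel_segmenter> %d-channel, input %dpx, depth %d, base %d\n",
              cfg$n_output_channels, cfg$input_size, cfg$depth,
              cfg$base_channels))
  if (nrow(x$training_log))
    cat(sprintf("  trained %d epochs; final val soft-Dice loss %.4f\n",
                nrow(x$training_log),
                x$training_log$val_loss[nrow(x$training_log)]))
  invisible(x)
}
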