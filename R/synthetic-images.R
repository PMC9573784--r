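#' Parameters for a synthetic carpel scene
#'
#' Describes one rendered unpollinated wheat carpel: an ellipse-like ovary on
#' a dark background topped by a fan-shaped plumose stigma whose envelope
#' shrinks as the tissue deteriorates. Chemically fixed samples are rendered
#' with an additional envelope shrinkage, mimicking the area reduction that
#' fixation causes in real material.
#'
#' @param ovary_semi_axis_x horizontal (column) semi-axis of the ovary, pixels.
#' @param ovary_semi_axis_y vertical (row) semi-axis of the ovary, pixels.
#' @param ovary_center numeric length-2, (row, col) centre of the ovary.
#' @param stigma_fan_half_angle half-opening of the stigma fan, degrees.
#' @param stigma_branch_length radial extent of a turgid stigma branch, pixels.
#' @param hair_count number of stigma hair strokes rendered inside the fan.
#' @param deterioration_level fraction in \[0, 1\]; 0 = turgid, 1 = fully
#'   collapsed. The envelope's linear scale shrinks by
#'   `1 - 0.7 * deterioration_level`.
#' @param fixation logical; fixed samples get a further 0.85 linear shrink of
#'   the stigma envelope.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param mm_per_px physical scale, mm per pixel.
#' @param image_size integer length-2, (rows, cols) of the rendered image.
#' @return An object of class `carpel_scene_params`.
#' @export
carpel_scene_params <- function(ovary_semi_axis_x = 22,
                                ovary_semi_axis_y = 20,
                                ovary_center = NULL,
                                stigma_fan_half_angle = 35,
                                stigma_branch_length = 55,
                                hair_count = 400,
                                deterioration_level = 0,
                                fixation = FALSE,
                                noise_sd = 0.02,
                                mm_per_px = 0.01,
                                image_size = c(128, 128)) {
  image_size <- as.integer(image_size)
  if (is.null(ovary_center))
    ovary_center <- c(round(image_size[1] * 0.70), round(image_size[2] * 0.50))
  p <- structure(list(
    ovary_semi_axis_x = ovary_semi_axis_x,
    ovary_semi_axis_y = ovary_semi_axis_y,
    ovary_center = as.numeric(ovary_center),
    stigma_fan_half_angle = stigma_fan_half_angle,
    stigma_branch_length = stigma_branch_length,
    hair_count = as.integer(hair_count),
    deterioration_level = deterioration_level,
    fixation = isTRUE(fixation),
    noise_sd = noise_sd,
    mm_per_px = mm_per_px,
    image_size = image_size
  ), class = "carpel_scene_params")
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  stopifnot(inherits(p, "carpel_scene_params"))
  if (p$ovary_semi_axis_x <= 0 || p$ovary_semi_axis_y <= 0)
    stop("ovary semi-axes must be > 0", call. = FALSE)
  if (p$deterioration_level < 0 || p$deterioration_level > 1)
    stop("deterioration_level must lie in [0, 1]", call. = FALSE)
  if (p$mm_per_px <= 0) stop("mm_per_px must be > 0", call. = FALSE)
  if (p$stigma_fan_half_angle <= 0 || p$stigma_fan_half_angle >= 90)
    stop("stigma_fan_half_angle must lie in (0, 90) degrees", call. = FALSE)
  H <- p$image_size[1]; W <- p$image_size[2]
  cr <- p$ovary_center[1]; cc <- p$ovary_center[2]
  if (cr - p$ovary_semi_axis_y < 1 || cr + p$ovary_semi_axis_y > H ||
      cc - p$ovary_semi_axis_x < 1 || cc + p$ovary_semi_axis_x > W)
    stop("ovary ellipse exceeds image bounds", call. = FALSE)
  # turgid (unshrunk) fan must fit: it is the largest envelope ever drawn
  apex_r <- cr - p$ovary_semi_axis_y + 1
  th <- p$stigma_fan_half_angle * pi / 180
  L <- p$stigma_branch_length
  if (apex_r - L < 1 || cc - L * sin(th) < 1 || cc + L * sin(th) > W)
    stop("stigma fan exceeds image bounds", call. = FALSE)
  invisible(p)
}

# Linear scale factor applied to the stigma envelope.
stigma_shrink_factor <- function(p) {
  s <- 1 - 0.7 * p$deterioration_level
  if (p$fixation) s <- s * 0.85
  s
}

#' Generate a synthetic carpel image with ground-truth masks
#'
#' Renders one carpel scene: a textured greenish ovary (filled ellipse), a
#' plumose stigma drawn as bright hair strokes densely filling a fan-shaped
#' envelope above the ovary, and a dark noisy background. The ground truth
#' for the stigma is the fan envelope polygon (the area covered by the
#' stigmatic hairs, as annotated in practice), not the individual hairs.
#'
#' The same `(params, seed)` pair always yields bit-identical outputs.
#'
#' @param params a [carpel_scene_params()] object.
#' @param seed integer seed controlling hair placement and pixel noise.
#' @return A list with components `image` (a `carpel_image`: list with `img`,
#'   an H x W x 3 array in \[0,1\], plus `mm_per_px` and `id`),
#'   `stigma_truth` and `ovary_truth` (H x W binary matrices).
#' @export
generate_carpel_image <- function(params, seed = 1L) {
  validate_scene_params(params)
  H <- params$image_size[1]; W <- params$image_size[2]
  cr <- params$ovary_center[1]; cc <- params$ovary_center[2]
  ax <- params$ovary_semi_axis_x; ay <- params$ovary_semi_axis_y

  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)

  # --- ovary truth: filled ellipse over pixel centres ---------------------
  ov <- ((rows - cr) / ay)^2 + ((cols - cc) / ax)^2 <= 1
  ovary_truth <- matrix(as.numeric(ov), H, W)

  # --- stigma truth: fan sector anchored just inside the ovary apex ------
  s <- stigma_shrink_factor(params)
  L <- params$stigma_branch_length * s
  th <- params$stigma_fan_half_angle * pi / 180
  apex_r <- cr - ay + 1          # one pixel inside the ovary top
  dy <- apex_r - rows            # positive pointing up
  dx <- cols - cc
  dist <- sqrt(dx^2 + dy^2)
  ang <- atan2(abs(dx), dy)      # angle from the upward vertical
  st <- (rows <= apex_r) & (dist <= L) & (ang <= th)
  st[apex_r, cc] <- TRUE         # keep the apex pixel so the fan is attached
  stigma_truth <- matrix(as.numeric(st), H, W)

  with_seed(seed, {
    # --- background ------------------------------------------------------
    r_ch <- matrix(0.045, H, W); g_ch <- matrix(0.050, H, W)
    b_ch <- matrix(0.040, H, W)

    # --- ovary rendering: green, cell-like sinusoidal texture, shading ---
    tex <- 0.82 + 0.18 * sin(rows / 2.6) * sin(cols / 2.4)
    shade <- 1 - 0.35 * ((rows - cr) / ay)^2
    ovv <- ov * tex * pmax(shade, 0.4)
    r_ch <- r_ch + 0.34 * ovv
    g_ch <- g_ch + 0.55 * ovv
    b_ch <- b_ch + 0.27 * ovv

    # faint plumose haze over the envelope (out-of-focus hair mass)
    r_ch <- r_ch + 0.13 * st
    g_ch <- g_ch + 0.12 * st
    b_ch <- b_ch + 0.07 * st

    # --- stigma hairs: radial strokes inside the fan ---------------------
    n_hair <- params$hair_count
    if (n_hair > 0L && L > 2) {
      phi <- runif(n_hair, -th, th)
      r0 <- runif(n_hair, 0, 0.12 * L)
      r1 <- runif(n_hair, 0.70 * L, L)
      bend <- runif(n_hair, -0.15, 0.15)
      bright <- runif(n_hair, 0.70, 1.00)
      for (i in seq_len(n_hair)) {
        rad <- seq(r0[i], r1[i], by = 0.6)
        a <- phi[i] + bend[i] * (rad / L)^2
        a <- pmin(pmax(a, -th), th)      # keep stroke inside the envelope
        pr <- round(apex_r - rad * cos(a))
        pc <- round(cc + rad * sin(a))
        keep <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
        ii <- cbind(pr[keep], pc[keep])
        r_ch[ii] <- pmin(1, pmax(r_ch[ii], 0.85 * bright[i]))
        g_ch[ii] <- pmin(1, pmax(g_ch[ii], 0.80 * bright[i]))
        b_ch[ii] <- pmin(1, pmax(b_ch[ii], 0.52 * bright[i]))
      }
    }

    # --- pixel noise -----------------------------------------------------
    if (params$noise_sd > 0) {
      r_ch <- r_ch + rnorm(H * W, 0, params$noise_sd)
      g_ch <- g_ch + rnorm(H * W, 0, params$noise_sd)
      b_ch <- b_ch + rnorm(H * W, 0, params$noise_sd)
    }
    img <- array(0, dim = c(H, W, 3))
    img[, , 1] <- clamp01(r_ch); img[, , 2] <- clamp01(g_ch)
    img[, , 3] <- clamp01(b_ch)

    list(
      image = structure(list(img = img, mm_per_px = params$mm_per_px,
                             id = sprintf("synthetic_%d", as.integer(seed))),
                        class = "carpel_image"),
      stigma_truth = stigma_truth,
      ovary_truth = ovary_truth
    )
  })
}

#' Generate a batch of synthetic carpel scenes along a deterioration gradient
#'
#' Convenience wrapper used by training, benchmarking and the pipeline's
#' `generate` step: draws `n` scenes with randomised ovary size/position, fan
#' geometry, deterioration level and fixation status, each rendered with its
#' own sub-seed derived from `seed`.
#'
#' @param n number of scenes.
#' @param seed master seed; scene `i` is rendered with seed
#'   `(seed * 1000 + i) %% 2^31`.
#' @param image_size (rows, cols) of every image.
#' @param mm_per_px physical scale recorded for every image.
#' @return A list with `images`, `stigma_truths`, `ovary_truths` (parallel
#'   lists) and `manifest` (data.frame: image_id, cultivar, timepoint_days,
#'   fixation, mm_per_px, seed).
#' @export
generate_carpel_batch <- function(n, seed = 1L, image_size = c(128, 128),
                                  mm_per_px = 0.01) {
  H <- image_size[1]; W <- image_size[2]
  sc <- min(H, W) / 128           # geometry scales with the canvas
  draws <- with_seed(seed, data.frame(
    ax   = runif(n, 16, 26) * sc,
    ay   = runif(n, 15, 24) * sc,
    crow = runif(n, 0.64, 0.76),
    ccol = runif(n, 0.44, 0.56),
    half = runif(n, 28, 42),
    len  = runif(n, 45, 60) * sc,
    det  = runif(n, 0, 1),
    fix  = runif(n) < 0.5,
    tp   = sample(c(0, 3, 7, 13, 18), n, replace = TRUE)
  ))
  images <- vector("list", n); stigs <- vector("list", n)
  ovs <- vector("list", n)
  for (i in seq_len(n)) {
    cr <- round(H * draws$crow[i]); cc <- round(W * draws$ccol[i])
    apex_r <- cr - draws$ay[i] + 1
    sth <- sin(draws$half[i] * pi / 180)
    len_max <- min(apex_r - 1.5, (W - cc - 0.5) / sth, (cc - 1.5) / sth)
    p <- carpel_scene_params(
      ovary_semi_axis_x = draws$ax[i], ovary_semi_axis_y = draws$ay[i],
      ovary_center = c(cr, cc),
      stigma_fan_half_angle = draws$half[i],
      stigma_branch_length = min(draws$len[i], len_max),
      deterioration_level = draws$det[i], fixation = draws$fix[i],
      image_size = image_size, mm_per_px = mm_per_px)
    scene <- generate_carpel_image(p, seed = (seed * 1000 + i) %% 2147483647)
    scene$image$id <- sprintf("carpel_%03d", i)
    images[[i]] <- scene$image
    stigs[[i]] <- scene$stigma_truth
    ovs[[i]] <- scene$ovary_truth
  }
  manifest <- data.frame(
    image_id = sprintf("carpel_%03d", seq_len(n)),
    cultivar = "SYN1",
    timepoint_days = draws$tp,
    fixation = ifelse(draws$fix, "fixed", "non_fixed"),
    mm_per_px = mm_per_px,
    seed = (seed * 1000 + seq_len(n)) %% 2147483647,
    stringsAsFactors = FALSE
  )
  list(images = images, stigma_truths = stigs, ovary_truths = ovs,
       manifest = manifest)
}
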