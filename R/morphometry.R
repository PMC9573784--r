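#' Stigma area from a binary mask
#'
#' The stigma area is the mask's pixel count scaled by the squared physical
#' pixel size — the area is extracted directly from the number of pixels,
#' with no boundary smoothing.
#'
#' @param mask binary matrix (stigma envelope).
#' @param mm_per_px physical scale, mm per pixel; must be > 0.
#' @return Area in mm^2, with attributes `px` (pixel count) and `flags`
#'   (character vector; contains `"empty_stigma"` when the mask is empty).
#' @export
stigma_area <- function(mask, mm_per_px) {
  assert_mask(mask)
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L || mm_per_px <= 0)
    stop("mm_per_px must be a single positive number", call. = FALSE)
  px <- sum(mask)
  area <- px * mm_per_px^2
  attr(area, "px") <- px
  attr(area, "flags") <- if (px == 0) "empty_stigma" else character(0)
  area
}

# Principal axis (unit vector, (row, col)) of a mask's second central moments.
mask_major_axis <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  ctr <- colMeans(idx)
  d <- sweep(idx, 2, ctr)
  cov <- crossprod(d) / nrow(d)
  ev <- eigen(cov, symmetric = TRUE)
  ev$vectors[, 1]
}

#' Ovary diameter by the centroid-perpendicular chord
#'
#' Implements the five-step diameter algorithm: (1) centroid of the stigma
#' mask; (2) centroid of the ovary mask; (3) the line through the ovary
#' centroid perpendicular to the centroid-centroid axis (the carpel's long
#' axis); (4) the two points where that line exits the ovary mask, found by
#' marching from the ovary centroid in both directions in 0.25-pixel steps
#' with nearest-pixel membership, taking the run of mask pixels containing
#' the centroid; (5) the Euclidean distance between the two exit points,
#' converted to mm.
#'
#' When the stigma mask is empty, or the two centroids are closer than one
#' pixel (fully deteriorated carpels where the stigma rests on the ovary),
#' the centroid axis is undefined; the ovary mask's major principal axis
#' stands in for it and the result carries a `fallback_axis` flag.
#'
#' @param ovary_mask binary matrix, non-empty (post-processed).
#' @param stigma_mask binary matrix; may be empty (triggers the fallback).
#' @param mm_per_px physical scale, mm per pixel.
#' @return A list: `diameter_mm`, `endpoints` (2 x 2 matrix of (row, col)
#'   measurement-segment endpoints, for overlay rendering), `flags`
#'   (subset of `"fallback_axis"`, `"off_edge"`, `"empty_stigma"`).
#' @export
ovary_diameter <- function(ovary_mask, stigma_mask, mm_per_px) {
  assert_mask(ovary_mask)
  assert_mask(stigma_mask)
  if (mm_per_px <= 0) stop("mm_per_px must be > 0", call. = FALSE)
  if (sum(ovary_mask) == 0)
    stop("ovary mask is empty; cannot measure a diameter", call. = FALSE)
  if (!all(dim(ovary_mask) == dim(stigma_mask)))
    stop("ovary and stigma masks must share dimensions", call. = FALSE)

  flags <- character(0)
  oc <- mask_centroid(ovary_mask)
  sc <- mask_centroid(stigma_mask)
  if (any(is.na(sc))) flags <- c(flags, "empty_stigma")

  if (any(is.na(sc)) || sqrt(sum((sc - oc)^2)) < 1) {
    axis <- mask_major_axis(ovary_mask)        # stands in for the centroid line
    flags <- c(flags, "fallback_axis")
  } else {
    axis <- (sc - oc) / sqrt(sum((sc - oc)^2))
  }
  perp <- c(-axis[2], axis[1])                  # measurement direction

  H <- nrow(ovary_mask); W <- ncol(ovary_mask)
  march <- function(dir) {
    pos <- oc; step <- 0.25
    last_inside <- oc
    repeat {
      nxt <- pos + step * dir
      # floor(x + 0.5), not round(): round-half-to-even would make pixel
      # membership depend on coordinate parity and break exact translation
      # invariance of the measurement
      r <- floor(nxt[1] + 0.5); cc <- floor(nxt[2] + 0.5)
      if (r < 1 || r > H || cc < 1 || cc > W) {
        flags <<- unique(c(flags, "off_edge"))
        return(last_inside)
      }
      if (ovary_mask[r, cc] == 0) return(last_inside)
      last_inside <- nxt
      pos <- nxt
    }
  }
  p1 <- march(perp)
  p2 <- march(-perp)
  diam <- sqrt(sum((p1 - p2)^2)) * mm_per_px
  list(diameter_mm = diam,
       endpoints = rbind(p1, p2),
       flags = flags)
}

#' Measure a batch of images
#'
#' Converts predicted masks into one measurement row per image, following the
#' manifest order. Rows with quality flags are retained (flagged, never
#' dropped) so the user's verification step can filter them; a missing or
#' invalid scale is recorded as a row-level error and processing continues.
#'
#' @param masks list, one element per image: `list(stigma = , ovary = )`
#'   binary matrices (ovary may be NULL if only stigma was segmented).
#' @param manifest data.frame with columns `image_id`, `cultivar`,
#'   `timepoint_days`, `fixation`, `mm_per_px` (one row per image, same order
#'   as `masks`).
#' @return A list with `measurements` (data.frame with the output CSV schema:
#'   image_id, cultivar, timepoint_days, fixation, stigma_area_mm2,
#'   ovary_diameter_mm, stigma_px, ovary_px, mm_per_px, flags) and `errors`
#'   (data.frame image_id, message).
#' @export
measure_batch <- function(masks, manifest) {
  stopifnot(is.data.frame(manifest), nrow(manifest) == length(masks))
  rows <- vector("list", nrow(manifest))
  errs <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$image_id[i]
    scale <- suppressWarnings(as.numeric(manifest$mm_per_px[i]))
    if (is.na(scale) || scale <= 0) {
      errs[[length(errs) + 1L]] <-
        data.frame(image_id = id,
                   message = "missing or non-positive mm_per_px",
                   stringsAsFactors = FALSE)
      next
    }
    sm <- masks[[i]]$stigma
    om <- masks[[i]]$ovary
    flags <- character(0)
    ar <- stigma_area(sm, scale)
    flags <- c(flags, attr(ar, "flags"))
    if (is.null(om) || sum(om) == 0) {
      dv <- NA_real_; opx <- if (is.null(om)) NA_integer_ else 0L
      if (!is.null(om)) flags <- c(flags, "empty_ovary")
    } else {
      dd <- ovary_diameter(om, sm, scale)
      dv <- dd$diameter_mm
      opx <- sum(om)
      flags <- c(flags, dd$flags)
    }
    rows[[i]] <- data.frame(
      image_id = id,
      cultivar = manifest$cultivar[i],
      timepoint_days = manifest$timepoint_days[i],
      fixation = manifest$fixation[i],
      stigma_area_mm2 = as.numeric(ar),
      ovary_diameter_mm = dv,
      stigma_px = attr(ar, "px"),
      ovary_px = opx,
      mm_per_px = scale,
      flags = paste(unique(flags), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  list(measurements = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       errors = if (length(errs)) do.call(rbind, errs) else
         data.frame(image_id = character(0), message = character(0)))
}
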