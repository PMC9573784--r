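# File readers/writers for the pipeline. All CSVs are UTF-8 with "."
# decimal separator; masks are single-channel PNGs with {0, 255}; images are
# 8-bit RGB PNGs (JPEG accepted on input).

MEASUREMENT_COLUMNS <- c("image_id", "cultivar", "timepoint_days", "fixation",
                         "stigma_area_mm2", "ovary_diameter_mm", "stigma_px",
                         "ovary_px", "mm_per_px", "flags")

#' Read a sample manifest
#'
#' Strict schema validation: required columns `image_id`, `cultivar`,
#' `timepoint_days`, `fixation`, `mm_per_px` (optional `seed`); duplicate
#' image ids and non-numeric scales are rejected with row numbers.
#'
#' @param path CSV path.
#' @return data.frame of manifest records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_id", "cultivar", "timepoint_days", "fixation",
                "mm_per_px")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- df$image_id[duplicated(df$image_id)]
  if (length(dup))
    stop("duplicate image_id in manifest: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  sc <- suppressWarnings(as.numeric(df$mm_per_px))
  bad <- which(is.na(sc) & !is.na(df$mm_per_px) | is.na(df$mm_per_px))
  if (length(bad))
    stop("non-numeric or missing mm_per_px at manifest row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  df$mm_per_px <- sc
  df
}

#' Read a daily temperature record
#'
#' Requires columns `date` (ISO, gap-free, strictly increasing) and
#' `mean_temp_C`; date gaps are reported with the offending dates.
#'
#' @param path CSV path.
#' @return A `temperature_series` (data.frame: date, daily_mean).
#' @export
read_temperature <- function(path) {
  if (!file.exists(path)) stop("temperature file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("date", "mean_temp_C"), names(df))
  if (length(miss))
    stop("temperature CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d <- as.Date(df$date)
  if (any(is.na(d)))
    stop("unparseable date(s) at row(s): ",
         paste(which(is.na(d)), collapse = ", "), call. = FALSE)
  gaps <- which(diff(as.integer(d)) != 1L)
  if (length(gaps))
    stop("temperature record has date gap(s) after: ",
         paste(format(d[gaps]), collapse = ", "), call. = FALSE)
  val <- suppressWarnings(as.numeric(df$mean_temp_C))
  if (any(is.na(val)))
    stop("non-numeric mean_temp_C at row(s): ",
         paste(which(is.na(val)), collapse = ", "), call. = FALSE)
  structure(data.frame(date = d, daily_mean = val),
            class = c("temperature_series", "data.frame"))
}

#' Write / read measurement CSVs
#'
#' The measurement CSV uses the fixed column set `image_id, cultivar,
#' timepoint_days, fixation, stigma_area_mm2, ovary_diameter_mm, stigma_px,
#' ovary_px, mm_per_px, flags`, in that order.
#'
#' @param measurements data.frame as produced by [measure_batch()].
#' @param path CSV path.
#' @export
write_measurements <- function(measurements, path) {
  miss <- setdiff(MEASUREMENT_COLUMNS, names(measurements))
  if (length(miss))
    stop("measurements are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  utils::write.csv(measurements[, MEASUREMENT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(flags = "character"))
  miss <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(miss))
    stop("measurement CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$flags[is.na(df$flags)] <- ""
  df
}

#' Image and mask I/O
#'
#' Images are read as RGB arrays in \[0,1\] (`carpel_image`); masks are
#' written as single-channel PNGs with values {0, 255} and binarised at
#' half-scale on reading.
#'
#' @param path image file (PNG or JPEG).
#' @param mm_per_px physical scale attached to the returned image.
#' @param id image identifier.
#' @return `read_carpel_image`: a `carpel_image`; `read_mask`: a binary
#'   matrix.
#' @export
read_carpel_image <- function(path, mm_per_px = NA_real_, id = basename(path)) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L)
    stop("grayscale image not supported (RGB required): ", path, call. = FALSE)
  a <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))   # EBImage is x,y -> row=y
  structure(list(img = a, mm_per_px = mm_per_px, id = id),
            class = "carpel_image")
}

#' @rdname read_carpel_image
#' @param image a `carpel_image` (or H x W x 3 array) to write.
#' @export
write_carpel_image <- function(image, path) {
  a <- carpel_pixels(image)
  EBImage::writeImage(EBImage::Image(aperm(a, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' @rdname read_carpel_image
#' @param mask binary matrix to write.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask)), path)
  invisible(path)
}

#' @rdname read_carpel_image
#' @export
read_mask <- function(path) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  (t(a) > 0.5) * 1
}

#' Read all masks in a directory
#'
#' @param dir directory containing `<image_id>_<tissue>.png` mask files.
#' @param tissue "stigma" or "ovary".
#' @return Named list (by image_id) of binary matrices.
#' @export
read_masks <- function(dir, tissue = c("stigma", "ovary")) {
  tissue <- match.arg(tissue)
  files <- list.files(dir, pattern = paste0("_", tissue, "\\.png$"),
                      full.names = TRUE)
  if (!length(files))
    stop("no *_", tissue, ".png masks found in ", dir, call. = FALSE)
  masks <- lapply(files, read_mask)
  names(masks) <- sub(paste0("_", tissue, "\\.png$"), "", basename(files))
  masks
}

#' Render a verification overlay
#'
#' Draws the stigma outline (yellow) and the ovary diameter segment (blue)
#' on the image, for the human verification step.
#'
#' @param image a `carpel_image` or H x W x 3 array.
#' @param stigma_mask binary matrix (outline drawn), or NULL.
#' @param endpoints 2 x 2 matrix of diameter segment endpoints (row, col),
#'   or NULL.
#' @param path output PNG path.
#' @export
write_overlay <- function(image, stigma_mask = NULL, endpoints = NULL, path) {
  a <- carpel_pixels(image)
  H <- dim(a)[1]; W <- dim(a)[2]
  if (!is.null(stigma_mask) && sum(stigma_mask) > 0) {
    # boundary = mask pixels with at least one 4-neighbour outside
    m <- stigma_mask
    er <- m
    er[2:(H - 1), 2:(W - 1)] <- m[2:(H - 1), 2:(W - 1)] *
      m[1:(H - 2), 2:(W - 1)] * m[3:H, 2:(W - 1)] *
      m[2:(H - 1), 1:(W - 2)] * m[2:(H - 1), 3:W]
    edge <- which(m == 1 & er == 0)
    for (ch in 1:3) {
      pl <- a[, , ch]
      pl[edge] <- c(1, 0.9, 0.1)[ch]
      a[, , ch] <- pl
    }
  }
  if (!is.null(endpoints)) {
    np <- max(2L, ceiling(2 * sqrt(sum((endpoints[1, ] - endpoints[2, ])^2))))
    tt <- seq(0, 1, length.out = np)
    pr <- round(endpoints[1, 1] + tt * (endpoints[2, 1] - endpoints[1, 1]))
    pc <- round(endpoints[1, 2] + tt * (endpoints[2, 2] - endpoints[1, 2]))
    ok <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
    ii <- cbind(pr[ok], pc[ok])
    for (ch in 1:3) {
      pl <- a[, , ch]
      pl[ii] <- c(0.15, 0.4, 1)[ch]
      a[, , ch] <- pl
    }
  }
  write_carpel_image(a, path)
}
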