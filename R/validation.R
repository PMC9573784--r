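#' Dice similarity coefficient
#'
#' Spatial overlap between two binary masks on the same grid:
#' \eqn{2|A \cap B| / (|A| + |B|)}. 0 means no overlap, 1 complete overlap.
#' Two empty masks score 1 by convention (the annotators agree that nothing
#' is present); empty versus non-empty scores 0.
#'
#' @param maskA,maskB binary matrices with identical dimensions.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(maskA, maskB) {
  assert_mask(maskA); assert_mask(maskB)
  if (!all(dim(maskA) == dim(maskB)))
    stop(sprintf("mask dimensions differ: %dx%d vs %dx%d",
                 nrow(maskA), ncol(maskA), nrow(maskB), ncol(maskB)),
         call. = FALSE)
  s <- sum(maskA) + sum(maskB)
  if (s == 0) return(1)
  2 * sum(maskA * maskB) / s
}

#' Cross-validate manual against automated annotation
#'
#' Mirrors the stage-by-fixation evaluation of a segmentation network against
#' a manual ground truth: Dice coefficients per image, summarised per
#' developmental stage (1 young, 2 fully developed, 3 deteriorated) crossed
#' with sampling method (fixed / non-fixed), plus paired measurement
#' differences (auto minus manual) for stigma area and ovary diameter.
#' Purely descriptive: no hypothesis testing.
#'
#' @param manual,auto lists with elements `masks` (named list image_id ->
#'   binary matrix for the tissue under evaluation) and, optionally,
#'   `measurements` (data.frame with image_id, stigma_area_mm2,
#'   ovary_diameter_mm).
#' @param stages named vector (by image_id) with values in 1:3.
#' @param fixation named vector (by image_id), "fixed" or "non_fixed".
#' @return An object of class `dice_report`: `per_image` (image_id, stage,
#'   fixation, dsc), `groups` (stage, fixation, n, dsc_mean, dsc_sd),
#'   `overall_mean`, and `paired` (per-group mean/sd difference and mean
#'   relative error per trait) when measurements were supplied.
#' @export
cross_validate <- function(manual, auto, stages, fixation) {
  ids_m <- names(manual$masks); ids_a <- names(auto$masks)
  only_m <- setdiff(ids_m, ids_a); only_a <- setdiff(ids_a, ids_m)
  if (length(only_m) || length(only_a))
    stop("image_id sets differ between annotation sources: ",
         paste(c(only_m, only_a), collapse = ", "), call. = FALSE)
  ids <- ids_m
  missing_lab <- setdiff(ids, intersect(names(stages), names(fixation)))
  if (length(missing_lab))
    stop("missing stage/fixation labels for: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)

  per_image <- data.frame(
    image_id = ids,
    stage = as.integer(stages[ids]),
    fixation = as.character(fixation[ids]),
    dsc = vapply(ids, function(id) dice(manual$masks[[id]], auto$masks[[id]]),
                 numeric(1)),
    stringsAsFactors = FALSE
  )
  groups <- do.call(rbind, lapply(
    split(per_image, list(per_image$stage, per_image$fixation), drop = TRUE),
    function(g) data.frame(stage = g$stage[1], fixation = g$fixation[1],
                           n = nrow(g), dsc_mean = mean(g$dsc),
                           dsc_sd = stats::sd(g$dsc))))
  rownames(groups) <- NULL
  groups <- groups[order(groups$stage, groups$fixation), ]

  paired <- NULL
  if (!is.null(manual$measurements) && !is.null(auto$measurements)) {
    mm <- manual$measurements; am <- auto$measurements
    mm <- mm[match(ids, mm$image_id), ]
    am <- am[match(ids, am$image_id), ]
    pr <- data.frame(image_id = ids,
                     stage = per_image$stage, fixation = per_image$fixation,
                     d_area = am$stigma_area_mm2 - mm$stigma_area_mm2,
                     rel_area = (am$stigma_area_mm2 - mm$stigma_area_mm2) /
                       ifelse(mm$stigma_area_mm2 == 0, NA, mm$stigma_area_mm2),
                     d_diam = am$ovary_diameter_mm - mm$ovary_diameter_mm,
                     rel_diam = (am$ovary_diameter_mm - mm$ovary_diameter_mm) /
                       ifelse(mm$ovary_diameter_mm == 0, NA,
                              mm$ovary_diameter_mm),
                     stringsAsFactors = FALSE)
    paired <- do.call(rbind, lapply(
      split(pr, list(pr$stage, pr$fixation), drop = TRUE),
      function(g) data.frame(
        stage = g$stage[1], fixation = g$fixation[1], n = nrow(g),
        mean_diff_area = mean(g$d_area), sd_diff_area = stats::sd(g$d_area),
        mean_rel_err_area = mean(abs(g$rel_area), na.rm = TRUE),
        mean_diff_diam = mean(g$d_diam, na.rm = TRUE),
        sd_diff_diam = stats::sd(g$d_diam, na.rm = TRUE),
        mean_rel_err_diam = mean(abs(g$rel_diam), na.rm = TRUE))))
    rownames(paired) <- NULL
  }
  structure(list(per_image = per_image, groups = groups,
                 overall_mean = mean(per_image$dsc), paired = paired),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice_report> %d images, overall mean DSC %.3f\n",
              nrow(x$per_image), x$overall_mean))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
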