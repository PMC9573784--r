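#' Pipeline configuration
#'
#' Bundles paths and analysis parameters for [run_pipeline()]. Any field can
#' be overridden; defaults mirror the package's study conditions.
#'
#' @param output_dir directory all artifacts are written under.
#' @param image_dir directory of input images (PNG/JPEG).
#' @param manifest_path sample manifest CSV.
#' @param temperature_path daily temperature CSV (date, mean_temp_C).
#' @param stigma_config,ovary_config [seg_config()] objects for the two
#'   networks.
#' @param span Loess span.
#' @param growth_frac,peak_drop,det_drop phase thresholds (0.85 / 0.15 /
#'   0.40).
#' @param grid_step evaluation grid step for smoothed curves, days.
#' @param iqr_k IQR fence multiplier.
#' @param n_synthetic number of images the `generate` step renders.
#' @param seed top-level seed; all randomness flows from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = "carpelseg_out",
                            image_dir = NULL,
                            manifest_path = NULL,
                            temperature_path = NULL,
                            stigma_config = seg_config(input_size = 128L,
                                                       n_output_channels = 1L),
                            ovary_config = seg_config(input_size = 128L,
                                                      n_output_channels = 2L),
                            span = 0.9, growth_frac = 0.85, peak_drop = 0.15,
                            det_drop = 0.40, grid_step = 0.1, iqr_k = 1.5,
                            n_synthetic = 60L, seed = 1L) {
  for (v in c(growth_frac, peak_drop, det_drop))
    if (v <= 0 || v >= 1) stop("phase thresholds must lie in (0,1)", call. = FALSE)
  structure(list(output_dir = output_dir, image_dir = image_dir,
                 manifest_path = manifest_path,
                 temperature_path = temperature_path,
                 stigma_config = stigma_config, ovary_config = ovary_config,
                 span = span, growth_frac = growth_frac,
                 peak_drop = peak_drop, det_drop = det_drop,
                 grid_step = grid_step, iqr_k = iqr_k,
                 n_synthetic = as.integer(n_synthetic),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys matching [pipeline_config()] arguments
#'   (segmentation configs under `stigma_config:` / `ovary_config:`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("stigma_config", "ovary_config"))]
  if (!is.null(y$stigma_config))
    args$stigma_config <- do.call(seg_config, y$stigma_config)
  if (!is.null(y$ovary_config))
    args$ovary_config <- do.call(seg_config, y$ovary_config)
  do.call(pipeline_config, args)
}

pipeline_paths <- function(config) {
  od <- config$output_dir
  list(images = file.path(od, "images"), masks = file.path(od, "masks"),
       truths = file.path(od, "truths"), overlays = file.path(od, "overlays"),
       models = file.path(od, "models"),
       manifest = file.path(od, "manifest.csv"),
       temperature = file.path(od, "temperature.csv"),
       measurements = file.path(od, "measurements.csv"),
       curves = file.path(od, "smoothed_curves.csv"),
       phases = file.path(od, "phases.csv"),
       ranking = file.path(od, "ranking.csv"),
       log = file.path(od, "run_log.json"))
}

write_run_log <- function(config, subcommand, artifacts, path) {
  existing <- Filter(function(p) file.exists(p) && !dir.exists(p),
                     unlist(artifacts, use.names = FALSE))
  log <- list(
    package = "carpelseg",
    version = as.character(utils::packageVersion("carpelseg")),
    subcommand = subcommand,
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config[setdiff(names(config),
                                    c("stigma_config", "ovary_config"))]),
    stigma_config = unclass(config$stigma_config),
    ovary_config = unclass(config$ovary_config),
    artifact_md5 = as.list(tools::md5sum(existing))
  )
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the phenotyping pipeline
#'
#' Executes one pipeline stage (or `all`): `generate` renders seeded
#' synthetic carpel images with ground-truth masks and a manifest; `train`
#' fits the stigma and ovary networks on the generated truths; `segment`
#' predicts and post-processes masks for every manifest image; `measure`
#' converts masks to the measurement CSV and verification overlays;
#' `validate` cross-checks predicted masks against the ground truths;
#' `phases` filters, smooths and classifies the time course per cultivar;
#' `rank` orders cultivars by developmental speed. Every stage writes its
#' artifacts under `config$output_dir` plus a JSON run log (config echo,
#' seed, artifact checksums); re-running with the same config and seed
#' reproduces identical CSVs.
#'
#' @param config a [pipeline_config()].
#' @param subcommand one of "generate", "train", "segment", "measure",
#'   "validate", "phases", "rank", "all".
#' @return (Invisibly) a named list of artifact paths written.
#' @export
run_pipeline <- function(config, subcommand = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  valid <- c("generate", "train", "segment", "measure", "validate",
             "phases", "rank", "all")
  if (!subcommand %in% valid)
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(valid, collapse = ", "), call. = FALSE)
  pp <- pipeline_paths(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  steps <- if (subcommand == "all")
    c("generate", "train", "segment", "measure", "validate", "phases", "rank")
  else subcommand
  written <- list()
  for (s in steps) written[[s]] <- switch(s,
    generate = pipeline_generate(config, pp),
    train = pipeline_train(config, pp),
    segment = pipeline_segment(config, pp),
    measure = pipeline_measure(config, pp),
    validate = pipeline_validate(config, pp),
    phases = pipeline_phases(config, pp),
    rank = pipeline_rank(config, pp))
  write_run_log(config, subcommand, written, pp$log)
  invisible(written)
}

pipeline_generate <- function(config, pp) {
  for (d in c(pp$images, pp$truths)) dir.create(d, showWarnings = FALSE,
                                                recursive = TRUE)
  sz <- config$stigma_config$input_size
  b <- generate_carpel_batch(config$n_synthetic, seed = config$seed,
                             image_size = c(sz, sz))
  for (i in seq_along(b$images)) {
    id <- b$manifest$image_id[i]
    write_carpel_image(b$images[[i]], file.path(pp$images, paste0(id, ".png")))
    write_mask(b$stigma_truths[[i]],
               file.path(pp$truths, paste0(id, "_stigma.png")))
    write_mask(b$ovary_truths[[i]],
               file.path(pp$truths, paste0(id, "_ovary.png")))
  }
  utils::write.csv(b$manifest, pp$manifest, row.names = FALSE, quote = FALSE)
  tser <- generate_temperature_series(40, seed = config$seed)
  utils::write.csv(data.frame(date = tser$date,
                              mean_temp_C = tser$daily_mean),
                   pp$temperature, row.names = FALSE, quote = FALSE)
  c(pp$manifest, pp$temperature)
}

load_pipeline_images <- function(config, pp) {
  manifest_path <- config$manifest_path %||% pp$manifest
  image_dir <- config$image_dir %||% pp$images
  if (!file.exists(manifest_path))
    stop("missing manifest (", manifest_path,
         "); run `generate` first or point manifest_path at your data",
         call. = FALSE)
  manifest <- read_manifest(manifest_path)
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(image_dir, paste0(manifest$image_id[i], ".png"))
    if (!file.exists(f))
      f <- file.path(image_dir, paste0(manifest$image_id[i], ".jpg"))
    if (!file.exists(f))
      stop("missing image for ", manifest$image_id[i], " in ", image_dir,
           call. = FALSE)
    read_carpel_image(f, mm_per_px = manifest$mm_per_px[i],
                      id = manifest$image_id[i])
  })
  list(manifest = manifest, images = images)
}

pipeline_train <- function(config, pp) {
  dir.create(pp$models, showWarnings = FALSE, recursive = TRUE)
  dat <- load_pipeline_images(config, pp)
  if (!dir.exists(pp$truths))
    stop("missing ground-truth masks (", pp$truths, "); run `generate` first",
         call. = FALSE)
  stig <- read_masks(pp$truths, "stigma")
  ov <- read_masks(pp$truths, "ovary")
  ids <- dat$manifest$image_id
  seg_s <- train_segmenter(dat$images, lapply(ids, function(id) stig[[id]]),
                           config$stigma_config)
  seg_o <- train_segmenter(dat$images,
                           lapply(ids, function(id) list(ov[[id]], stig[[id]])),
                           config$ovary_config)
  ps <- file.path(pp$models, "stigma_net.rds")
  po <- file.path(pp$models, "ovary_net.rds")
  save_segmenter(seg_s, ps); save_segmenter(seg_o, po)
  utils::write.csv(seg_s$training_log,
                   file.path(pp$models, "stigma_training_log.csv"),
                   row.names = FALSE)
  utils::write.csv(seg_o$training_log,
                   file.path(pp$models, "ovary_training_log.csv"),
                   row.names = FALSE)
  c(ps, po)
}

pipeline_segment <- function(config, pp) {
  dir.create(pp$masks, showWarnings = FALSE, recursive = TRUE)
  ps <- file.path(pp$models, "stigma_net.rds")
  po <- file.path(pp$models, "ovary_net.rds")
  if (!file.exists(ps) || !file.exists(po))
    stop("missing trained models under ", pp$models, "; run `train` first",
         call. = FALSE)
  seg_s <- load_segmenter(ps); seg_o <- load_segmenter(po)
  dat <- load_pipeline_images(config, pp)
  for (i in seq_along(dat$images)) {
    id <- dat$manifest$image_id[i]
    sm <- postprocess_mask(predict_masks(seg_s, dat$images[[i]])$stigma)
    om <- postprocess_mask(predict_masks(seg_o, dat$images[[i]])$ovary)
    write_mask(sm, file.path(pp$masks, paste0(id, "_stigma.png")))
    write_mask(om, file.path(pp$masks, paste0(id, "_ovary.png")))
  }
  pp$masks
}

pipeline_measure <- function(config, pp) {
  if (!dir.exists(pp$masks))
    stop("missing predicted masks (", pp$masks, "); run `segment` first",
         call. = FALSE)
  dat <- load_pipeline_images(config, pp)
  stig <- read_masks(pp$masks, "stigma")
  ov <- read_masks(pp$masks, "ovary")
  masks <- lapply(dat$manifest$image_id, function(id)
    list(stigma = stig[[id]], ovary = ov[[id]]))
  res <- measure_batch(masks, dat$manifest)
  write_measurements(res$measurements, pp$measurements)
  dir.create(pp$overlays, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dat$images)) {
    id <- dat$manifest$image_id[i]
    ep <- NULL
    if (sum(masks[[i]]$ovary) > 0)
      ep <- ovary_diameter(masks[[i]]$ovary, masks[[i]]$stigma,
                           dat$manifest$mm_per_px[i])$endpoints
    write_overlay(dat$images[[i]], masks[[i]]$stigma, ep,
                  file.path(pp$overlays, paste0(id, "_overlay.png")))
  }
  pp$measurements
}

pipeline_validate <- function(config, pp) {
  if (!dir.exists(pp$masks) || !dir.exists(pp$truths))
    stop("validation needs both predicted masks and ground truths; ",
         "run `generate`, `train` and `segment` first", call. = FALSE)
  manifest <- read_manifest(config$manifest_path %||% pp$manifest)
  auto <- list(masks = read_masks(pp$masks, "stigma"))
  manual <- list(masks = read_masks(pp$truths, "stigma"))
  # synthetic deterioration maps onto the three validation stages
  det <- seq(0, 1, length.out = nrow(manifest))
  stages <- stats::setNames(findInterval(rank(manifest$timepoint_days,
                                              ties.method = "first"),
                                         c(0, nrow(manifest) / 3,
                                           2 * nrow(manifest) / 3)),
                            manifest$image_id)
  fixation <- stats::setNames(manifest$fixation, manifest$image_id)
  rep <- cross_validate(manual, auto, stages, fixation)
  out <- file.path(config$output_dir, "dice_report.csv")
  utils::write.csv(rep$groups, out, row.names = FALSE)
  utils::write.csv(rep$per_image,
                   file.path(config$output_dir, "dice_per_image.csv"),
                   row.names = FALSE)
  out
}

pipeline_phases <- function(config, pp) {
  if (!file.exists(pp$measurements))
    stop("missing measurement CSV (", pp$measurements,
         "); run `measure` first", call. = FALSE)
  meas <- read_measurements(pp$measurements)
  tpath <- config$temperature_path %||% pp$temperature
  tser <- if (file.exists(tpath)) read_temperature(tpath) else NULL
  curves <- list(); reports <- list()
  for (cv in unique(meas$cultivar)) {
    d <- meas[meas$cultivar == cv, ]
    keepS <- iqr_filter(d$stigma_area_mm2, d$timepoint_days, k = config$iqr_k)$keep
    grid <- seq(0, max(d$timepoint_days), by = config$grid_step)
    sc <- loess_smooth(d$timepoint_days[keepS], d$stigma_area_mm2[keepS],
                       span = config$span, grid = grid)
    oc <- NULL
    okD <- !is.na(d$ovary_diameter_mm)
    if (sum(okD) >= 5) {
      keepD <- iqr_filter(d$ovary_diameter_mm[okD],
                          d$timepoint_days[okD], k = config$iqr_k)$keep
      oc <- loess_smooth(d$timepoint_days[okD][keepD],
                         d$ovary_diameter_mm[okD][keepD],
                         span = config$span, grid = grid)
    }
    reports[[cv]] <- classify_phases(sc, oc, tser,
                                     last_sampling = max(d$timepoint_days),
                                     cultivar = cv,
                                     growth_frac = config$growth_frac,
                                     peak_drop = config$peak_drop,
                                     det_drop = config$det_drop)
    curves[[cv]] <- rbind(
      data.frame(cultivar = cv, trait = "stigma_area_mm2", grid = sc$grid,
                 mean = sc$mean, ci_low = sc$ci_low, ci_high = sc$ci_high),
      if (!is.null(oc))
        data.frame(cultivar = cv, trait = "ovary_diameter_mm", grid = oc$grid,
                   mean = oc$mean, ci_low = oc$ci_low, ci_high = oc$ci_high))
  }
  utils::write.csv(do.call(rbind, curves), pp$curves, row.names = FALSE)
  ph <- do.call(rbind, lapply(reports, function(r) data.frame(
    cultivar = r$cultivar, growth_end = r$growth_end,
    peak_onset = r$peak_onset, peak_end = r$peak_end,
    deterioration_marker_40pct = r$deterioration_marker_40pct,
    last_sampling = r$last_sampling,
    growth_days = r$durations_days["growth"],
    peak_days = r$durations_days["peak"],
    deterioration_days = r$durations_days["deterioration"],
    growth_dd = (r$durations_degree_days %||% c(growth = NA))["growth"],
    peak_dd = (r$durations_degree_days %||% c(peak = NA))["peak"],
    deterioration_dd = (r$durations_degree_days %||%
                          c(deterioration = NA))["deterioration"],
    censored = paste(r$censored, collapse = ";"))))
  utils::write.csv(ph, pp$phases, row.names = FALSE)
  saveRDS(reports, file.path(config$output_dir, "phase_reports.rds"))
  pp$phases
}

pipeline_rank <- function(config, pp) {
  rp <- file.path(config$output_dir, "phase_reports.rds")
  if (!file.exists(rp))
    stop("missing phase reports; run `phases` first", call. = FALSE)
  reports <- readRDS(rp)
  if (length(reports) < 2L) {
    # single-cultivar runs cannot be ranked; note it in the CSV
    utils::write.csv(data.frame(cultivar = names(reports),
                                note = "single cultivar; ranking skipped"),
                     pp$ranking, row.names = FALSE)
    return(pp$ranking)
  }
  utils::write.csv(rank_cultivars(reports), pp$ranking, row.names = FALSE)
  pp$ranking
}
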