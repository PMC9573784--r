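#' Interquartile-range outlier filter
#'
#' Removes, within each group, values outside
#' \[Q1 - k IQR, Q3 + k IQR\] (Tukey fences, k = 1.5 by default). Quartiles
#' use linear interpolation between order statistics (`quantile` type 7).
#' Groups with fewer than 4 values pass through unfiltered.
#'
#' @param values numeric vector of measurements.
#' @param grouping NULL (one group), a vector, or a list of vectors (e.g.
#'   cultivar and timepoint) of the same length as `values`.
#' @param k fence multiplier.
#' @return A list: `keep` (logical, same length as `values`), `kept`,
#'   `removed` (the values), and `bounds` (per-group data.frame with the
#'   fences; NA for pass-through groups).
#' @export
iqr_filter <- function(values, grouping = NULL, k = 1.5) {
  n <- length(values)
  g <- if (is.null(grouping)) rep(1L, n) else interaction(grouping, drop = TRUE)
  if (length(g) != n) stop("grouping length must match values", call. = FALSE)
  keep <- rep(TRUE, n)
  bnds <- list()
  for (lv in levels(factor(g))) {
    idx <- which(g == lv)
    v <- values[idx]
    if (length(v) < 4L) {
      bnds[[lv]] <- data.frame(group = lv, n = length(v),
                               lower = NA_real_, upper = NA_real_)
      next
    }
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE,
                         na.rm = TRUE)
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr; hi <- q[2] + k * iqr
    keep[idx] <- !is.na(v) & v >= lo & v <= hi
    bnds[[lv]] <- data.frame(group = lv, n = length(v), lower = lo, upper = hi)
  }
  list(keep = keep, kept = values[keep], removed = values[!keep],
       bounds = do.call(rbind, bnds))
}

#' Loess smoothing of a trait time course
#'
#' Local quadratic regression with tricube weights (span 0.9, the width of
#' the moving window, by default) and a pointwise 95% confidence band from
#' the local fit's standard errors under a normal approximation.
#'
#' @param times sampling times (days or degree days).
#' @param values trait values.
#' @param span fraction of points in each local window, in (0, 1].
#' @param grid evaluation times; default a 0.1-step grid over the data range.
#' @param degree local polynomial degree (2 = quadratic).
#' @return An object of class `smoothed_curve`: `grid`, `mean`, `ci_low`,
#'   `ci_high`, `span`.
#' @export
loess_smooth <- function(times, values, span = 0.9, grid = NULL, degree = 2) {
  if (length(times) != length(values))
    stop("times and values must have the same length", call. = FALSE)
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(unique(times)) < 5L)
    stop("at least 5 distinct time values are required", call. = FALSE)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]", call. = FALSE)
  if (is.null(grid)) {
    grid <- seq(min(times), max(times), by = 0.1)
    if (grid[length(grid)] < max(times)) grid <- c(grid, max(times))
  }
  fit <- stats::loess(values ~ times, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(fit, newdata = data.frame(times = grid), se = TRUE)
  z <- stats::qnorm(0.975)
  se <- ifelse(is.finite(pr$se.fit), pr$se.fit, 0)
  structure(list(grid = grid, mean = as.numeric(pr$fit),
                 ci_low = as.numeric(pr$fit) - z * se,
                 ci_high = as.numeric(pr$fit) + z * se,
                 span = span),
            class = "smoothed_curve")
}

#' Cumulative degree days over an indexed window
#'
#' Thermal time with a 0 deg C base temperature: the sum of daily mean
#' temperatures, clamped below at 0, over days `i` to `j` of the series
#' (inclusive of both endpoints).
#'
#' @param series a `temperature_series` (or data.frame with `daily_mean`).
#' @param i,j start and end indices into the series, `i <= j`.
#' @return Degree days, deg C day.
#' @export
cumulative_degree_days <- function(series, i, j) {
  x <- series$daily_mean
  if (is.null(x)) stop("series must have a daily_mean column", call. = FALSE)
  if (i < 1 || j > length(x) || i > j)
    stop(sprintf("invalid window [%s, %s] for a series of %d days",
                 i, j, length(x)), call. = FALSE)
  sum(pmax(x[i:j], 0))
}

# Continuous thermal-time clock: degree days accumulated from day 0 (series
# index 1 = the W9.5 date) to fractional day t, by linear interpolation of
# the daily cumulative sum.
degree_day_clock <- function(series) {
  clamped <- pmax(series$daily_mean, 0)
  cum <- c(0, cumsum(clamped))
  n <- length(clamped)
  function(t) {
    if (any(t < 0 | t > n))
      stop("time outside the temperature record", call. = FALSE)
    f <- floor(t)
    frac <- t - f
    cum[f + 1] + frac * clamped[pmin(f + 1, n)]
  }
}

# First index at/after `from` where `x <= thr` (dir = "down") or `>= thr`
# (dir = "up"); crossing located by linear interpolation between grid points.
first_crossing <- function(grid, x, thr, from = 1L, dir = c("down", "up")) {
  dir <- match.arg(dir)
  hit <- if (dir == "down") x <= thr else x >= thr
  idx <- which(hit & seq_along(x) >= from)
  if (!length(idx)) return(NA_real_)
  j <- idx[1]
  if (j == from || j == 1L) return(grid[j])
  x0 <- x[j - 1]; x1 <- x[j]
  if (x1 == x0) return(grid[j])
  grid[j - 1] + (thr - x0) / (x1 - x0) * (grid[j] - grid[j - 1])
}

#' Classify growth, peak and deterioration phases
#'
#' Applies the stigma-area phase framework to a smoothed curve: with
#' \eqn{S_{max}} the curve maximum, the growth phase ends at the earliest
#' time the curve reaches 85% of \eqn{S_{max}} on the rise; the peak phase
#' starts at the time of the maximum and ends at a 15% drop below
#' \eqn{S_{max}}; a 40% drop marks progressed deterioration; the
#' deterioration phase ends at the last sampling point. Thresholds never
#' crossed within the sampled window are reported as censored. Boundaries
#' are located by linear interpolation between grid points. Durations are
#' reported in days and, when a temperature series is supplied, in
#' cumulative degree days (base 0 deg C; series day 1 = day 0 of the time
#' course).
#'
#' @param stigma_curve a `smoothed_curve` covering \[0, last_sampling\].
#' @param ovary_curve optional `smoothed_curve`; carried through for
#'   reporting, it plays no part in the boundary rules.
#' @param temperature optional `temperature_series` for degree-day durations.
#' @param last_sampling end of the observation window, days.
#' @param cultivar label carried into the report.
#' @param growth_frac fraction of the maximum defining the growth-phase end.
#' @param peak_drop fractional drop below the maximum ending the peak phase.
#' @param det_drop fractional drop marking progressed deterioration.
#' @return An object of class `phase_report`.
#' @export
classify_phases <- function(stigma_curve, ovary_curve = NULL,
                            temperature = NULL,
                            last_sampling = max(stigma_curve$grid),
                            cultivar = NA_character_,
                            growth_frac = 0.85, peak_drop = 0.15,
                            det_drop = 0.40) {
  stopifnot(inherits(stigma_curve, "smoothed_curve"))
  g <- stigma_curve$grid; S <- stigma_curve$mean
  if (!all(is.finite(S))) stop("non-finite smoothed values", call. = FALSE)
  if (min(g) > 0 || max(g) < last_sampling)
    stop("stigma curve must cover [0, last_sampling]", call. = FALSE)

  i_peak <- which.max(S)                       # earliest attainment of the max
  S_max <- S[i_peak]
  peak_onset <- g[i_peak]
  growth_end <- first_crossing(g, S, growth_frac * S_max, from = 1L,
                               dir = "up")
  peak_end <- first_crossing(g, S, (1 - peak_drop) * S_max, from = i_peak,
                             dir = "down")
  det_marker <- first_crossing(g, S, (1 - det_drop) * S_max, from = i_peak,
                               dir = "down")
  censored <- character(0)
  if (is.na(peak_end)) censored <- c(censored, "peak_end")
  if (is.na(det_marker)) censored <- c(censored, "deterioration_marker_40pct")

  durations_days <- c(
    growth = growth_end,
    peak = if (is.na(peak_end)) NA_real_ else peak_end - growth_end,
    deterioration = if (is.na(peak_end)) NA_real_ else last_sampling - peak_end
  )
  durations_dd <- NULL
  if (!is.null(temperature)) {
    clock <- degree_day_clock(temperature)
    dd <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else clock(b) - clock(a)
    durations_dd <- c(growth = dd(0, growth_end),
                      peak = dd(growth_end, peak_end),
                      deterioration = dd(peak_end, last_sampling))
  }
  structure(list(cultivar = cultivar,
                 growth_end = growth_end, peak_onset = peak_onset,
                 peak_end = peak_end,
                 deterioration_marker_40pct = det_marker,
                 last_sampling = last_sampling,
                 S_max = S_max,
                 durations_days = durations_days,
                 durations_degree_days = durations_dd,
                 censored = censored,
                 ovary_curve = ovary_curve),
            class = "phase_report")
}

#' @export
print.phase_report <- function(x, ...) {
  cat(sprintf("<phase_report> %s: growth end %.2f d, peak %.2f-%s d, 40%% drop %s d, end %.1f d\n",
              x$cultivar, x$growth_end, x$peak_onset,
              ifelse(is.na(x$peak_end), "censored", sprintf("%.2f", x$peak_end)),
              ifelse(is.na(x$deterioration_marker_40pct), "censored",
                     sprintf("%.2f", x$deterioration_marker_40pct)),
              x$last_sampling))
  if (length(x$censored))
    cat("  censored:", paste(x$censored, collapse = ", "), "\n")
  invisible(x)
}

#' Rank cultivars by developmental speed
#'
#' Orders cultivars by when their carpels reach the onset of the
#' deterioration phase (the end of the peak phase): the later the onset, the
#' slower the cultivar. Ties are broken by the 40%-drop marker, then by
#' label; censored boundaries rank slower than any observed value. With
#' three or more cultivars the extremes are labelled "slow" and "fast" and
#' the rest "moderate".
#'
#' @param reports list of `phase_report` objects.
#' @return data.frame: cultivar, peak_end, deterioration_marker_40pct,
#'   rank (1 = slowest), speed_class.
#' @export
rank_cultivars <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 phase reports", call. = FALSE)
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(cultivar = r$cultivar,
               peak_end = r$peak_end %||% NA_real_,
               deterioration_marker_40pct = r$deterioration_marker_40pct %||% NA_real_,
               stringsAsFactors = FALSE)))
  pe <- ifelse(is.na(df$peak_end), Inf, df$peak_end)
  dm <- ifelse(is.na(df$deterioration_marker_40pct), Inf,
               df$deterioration_marker_40pct)
  ord <- order(-pe, -dm, df$cultivar)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  n <- nrow(df)
  df$speed_class <- "moderate"
  df$speed_class[1] <- "slow"
  df$speed_class[n] <- "fast"
  rownames(df) <- NULL
  df
}
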