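#' Parameters for a synthetic measurement trajectory
#'
#' Describes the per-carpel stigma-area and ovary-diameter time course of one
#' cultivar: the stigma follows a bell-then-decline shape (logistic rise to
#' `A_max` at `t_peak`, then exponential decline), the ovary a saturating
#' rise to `D_max`. Defaults reflect the field sampling design the package
#' emulates: sampling at 0, 3, 7, 13 and 18 days after W9.5 with ~20 carpels
#' per timepoint, a stigma peak of a few mm^2 around a week after W9.5 and an
#' ovary plateau near 2 mm.
#'
#' @param cultivar_id label.
#' @param A_max peak stigma area, mm^2.
#' @param t_peak time of the stigma maximum, days after W9.5.
#' @param growth_rate logistic rise rate of the stigma, per day.
#' @param decline_rate exponential decline rate after the peak, per day.
#' @param D_max ovary plateau diameter, mm.
#' @param ovary_rate saturation rate of the ovary diameter, per day.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   per-carpel noise.
#' @param outlier_rate fraction of values replaced by contaminants displaced
#'   to Q3 + 3 IQR of the clean group values (must be < 0.5).
#' @param carpels_per_timepoint carpels sampled per timepoint.
#' @param timepoints strictly increasing sampling days; first must be 0.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(cultivar_id = "SYN1", A_max = 2.5, t_peak = 7,
                              growth_rate = 1.0, decline_rate = 0.1,
                              D_max = 2.0, ovary_rate = 0.3,
                              noise_cv = 0.1, outlier_rate = 0.05,
                              carpels_per_timepoint = 20L,
                              timepoints = c(0, 3, 7, 13, 18)) {
  p <- structure(list(cultivar_id = cultivar_id, A_max = A_max,
                      t_peak = t_peak, growth_rate = growth_rate,
                      decline_rate = decline_rate, D_max = D_max,
                      ovary_rate = ovary_rate, noise_cv = noise_cv,
                      outlier_rate = outlier_rate,
                      carpels_per_timepoint = as.integer(carpels_per_timepoint),
                      timepoints = as.numeric(timepoints)),
                 class = "trajectory_params")
  if (p$A_max <= 0 || p$D_max <= 0) stop("A_max and D_max must be > 0", call. = FALSE)
  if (p$growth_rate <= 0 || p$decline_rate <= 0 || p$ovary_rate <= 0)
    stop("rates must be > 0", call. = FALSE)
  if (p$outlier_rate < 0 || p$outlier_rate >= 0.5)
    stop("outlier_rate must lie in [0, 0.5)", call. = FALSE)
  if (length(p$timepoints) == 0) stop("timepoints must be non-empty", call. = FALSE)
  if (p$timepoints[1] != 0 || is.unsorted(p$timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing and start at 0", call. = FALSE)
  p
}

# Noiseless trait means. The logistic rise is centred 6/growth_rate before
# the peak so the rise is >99.7% complete at t_peak, making the closed-form
# decline crossings (e.g. the 40% drop at t_peak + ln(1/0.6)/decline_rate)
# hold to high accuracy.
stigma_mean_fn <- function(p) {
  ctr <- p$t_peak - 6 / p$growth_rate
  function(t) {
    g <- 1 / (1 + exp(-p$growth_rate * (t - ctr)))
    d <- ifelse(t <= p$t_peak, 1, exp(-p$decline_rate * (t - p$t_peak)))
    p$A_max * g * d
  }
}

ovary_mean_fn <- function(p) {
  function(t) p$D_max * (1 - exp(-p$ovary_rate * t))
}

# Phase boundaries of the noiseless stigma curve, evaluated with the same
# threshold rules the classifier uses, on a dense grid.
trajectory_truth <- function(p, step = 0.01) {
  grid <- seq(0, max(p$timepoints), by = step)
  S <- stigma_mean_fn(p)(grid)
  crv <- structure(list(grid = grid, mean = S, ci_low = S, ci_high = S,
                        span = NA_real_), class = "smoothed_curve")
  rep0 <- classify_phases(crv, last_sampling = max(p$timepoints),
                          cultivar = p$cultivar_id)
  list(grid = grid, stigma = S, ovary = ovary_mean_fn(p)(grid),
       boundaries = rep0)
}

#' Generate a synthetic trajectory set with known phase boundaries
#'
#' Draws per-carpel stigma-area and ovary-diameter values around the
#' noiseless cultivar means (multiplicative lognormal noise with the given
#' CV), optionally replaces a fraction of values per timepoint by
#' far-displaced contaminants (placed at Q3 + 3 IQR of the clean values, well
#' beyond the 1.5 IQR Tukey fences so the outlier filter's effect is
#' verifiable by construction), and returns the noiseless curves together
#' with their true phase boundaries.
#'
#' @param params a [trajectory_params()].
#' @param seed integer seed.
#' @return An object of class `trajectory_set`: `records` (data.frame:
#'   cultivar, plot, spike, timepoint_days, stigma_area_mm2,
#'   ovary_diameter_mm, stigma_outlier, ovary_outlier), `truth` (noiseless
#'   grid curves plus a `phase_report` of the true boundaries), `params`.
#' @export
generate_trajectory_set <- function(params, seed = 1L) {
  stopifnot(inherits(params, "trajectory_params"))
  Sfn <- stigma_mean_fn(params); Dfn <- ovary_mean_fn(params)
  ncar <- params$carpels_per_timepoint
  sigma <- sqrt(log(1 + params$noise_cv^2))

  records <- with_seed(seed, {
    out <- lapply(params$timepoints, function(tp) {
      mS <- Sfn(tp); mD <- Dfn(tp)
      noise <- function(n) {
        if (sigma == 0) rep(1, n) else exp(rnorm(n, 0, sigma) - sigma^2 / 2)
      }
      sv <- mS * noise(ncar)
      dv <- mD * noise(ncar)
      so <- rep(FALSE, ncar); oo <- rep(FALSE, ncar)
      n_out <- round(params$outlier_rate * ncar)
      if (n_out > 0) {
        contam <- function(v) {
          q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
          q[2] + 3 * (q[2] - q[1])
        }
        i1 <- sample(ncar, n_out); sv[i1] <- contam(sv); so[i1] <- TRUE
        i2 <- sample(ncar, n_out); dv[i2] <- contam(dv); oo[i2] <- TRUE
      }
      data.frame(cultivar = params$cultivar_id,
                 plot = rep(1:2, length.out = ncar),
                 spike = seq_len(ncar),
                 timepoint_days = tp,
                 stigma_area_mm2 = sv, ovary_diameter_mm = dv,
                 stigma_outlier = so, ovary_outlier = oo,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  structure(list(records = records, truth = trajectory_truth(params),
                 params = params),
            class = "trajectory_set")
}

#' Generate a synthetic daily temperature series
#'
#' Seasonal sinusoid plus AR(1) noise, standing in for a field data-logger
#' record. Day 1 of the series is the W9.5 date of the emulated time course.
#'
#' @param n_days number of days.
#' @param base_level seasonal mean, deg C.
#' @param amplitude seasonal sinusoid amplitude, deg C.
#' @param ar_coef AR(1) coefficient of the noise, |ar_coef| < 1.
#' @param seed integer seed.
#' @param start_date first calendar day.
#' @param innovation_sd sd of the AR(1) innovations, deg C; defaults to
#'   `0.4 * amplitude` so day-to-day scatter scales with the seasonal swing
#'   (and a flat season implies a noiseless record).
#' @return An object of class `temperature_series`: data.frame with `date`
#'   (gap-free, increasing) and `daily_mean` (deg C).
#' @export
generate_temperature_series <- function(n_days, base_level = 16,
                                        amplitude = 4, ar_coef = 0.6,
                                        seed = 1L,
                                        start_date = as.Date("2021-05-20"),
                                        innovation_sd = NULL) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  if (abs(ar_coef) >= 1) stop("|ar_coef| must be < 1", call. = FALSE)
  innovation_sd <- innovation_sd %||% (0.4 * amplitude)
  dates <- seq(as.Date(start_date), by = "day", length.out = n_days)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- base_level + amplitude * sin(2 * pi * (doy - 110) / 365)
  noise <- with_seed(seed, {
    e <- rnorm(n_days, 0, innovation_sd)
    x <- numeric(n_days)
    if (n_days >= 1) x[1] <- e[1]
    if (n_days >= 2)
      for (i in 2:n_days) x[i] <- ar_coef * x[i - 1] + e[i]
    x
  })
  structure(data.frame(date = dates, daily_mean = seasonal + noise),
            class = c("temperature_series", "data.frame"))
}
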