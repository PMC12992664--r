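#' Logarithmic-Gaussian numerosity tuning
#'
#' The neuronal response of a numerosity-tuned population to a presented
#' numerosity x is modelled as a Gaussian in logarithmic numerosity space,
#' `z = exp(-1/2 ((ln x - ln mu) / sigma_log)^2)`, peaking at 1 when
#' x equals the preferred numerosity `mu`.
#'
#' @param x Presented numerosity (> 0); vectorized.
#' @param mu Preferred numerosity (> 0).
#' @param sigma_log Tuning standard deviation in log-numerosity space (> 0).
#' @return Response in (0, 1].
#' @examples
#' tuning_response(3, mu = 3, sigma_log = 0.5) # 1 at the peak
#' tuning_response(exp(1), mu = 1, sigma_log = 1) # exp(-1/2)
#' @export
tuning_response <- function(x, mu, sigma_log) {
  if (any(x <= 0)) stop("numerosity x must be positive", call. = FALSE)
  stopifnot(all(mu > 0), all(sigma_log > 0))
  exp(-0.5 * ((log(x) - log(mu)) / sigma_log)^2)
}

#' Linear-Gaussian numerosity tuning (control model)
#'
#' Gaussian tuning in linear numerosity space,
#' `z = exp(-1/2 ((x - mu) / sigma_lin)^2)`.
#'
#' @param x Presented numerosity; vectorized.
#' @param mu Preferred numerosity.
#' @param sigma_lin Tuning standard deviation in linear numerosity space.
#' @export
tuning_response_linear <- function(x, mu, sigma_lin) {
  stopifnot(all(sigma_lin > 0))
  exp(-0.5 * ((x - mu) / sigma_lin)^2)
}

#' FWHM tuning width in linear numerosity space
#'
#' For log-Gaussian tuning the full width at half maximum on the linear
#' numerosity axis is
#' `omega = exp(ln mu + sqrt(2 ln 2) sigma_log) - exp(ln mu - sqrt(2 ln 2) sigma_log)`,
#' equivalently `2 mu sinh(sqrt(2 ln 2) sigma_log)`. For linear-Gaussian
#' tuning it is `2 sqrt(2 ln 2) sigma_lin`, independent of mu.
#'
#' @param mu Preferred numerosity (> 0).
#' @param sigma_log Log-space tuning SD (> 0).
#' @return FWHM in numerosity units.
#' @examples
#' round(fwhm_log(1, 0.05), 2) # 0.12
#' round(fwhm_log(5, 3.0), 1)  # 170.9
#' @export
fwhm_log <- function(mu, sigma_log) {
  stopifnot(all(mu > 0), all(sigma_log > 0))
  2 * mu * sinh(sqrt(2 * log(2)) * sigma_log)
}

#' @rdname fwhm_log
#' @param sigma_lin Linear-space tuning SD (> 0).
#' @export
fwhm_linear <- function(sigma_lin) {
  stopifnot(all(sigma_lin > 0))
  2 * sqrt(2 * log(2)) * sigma_lin
}

#' @rdname fwhm_log
#' @param omega FWHM in linear numerosity units (> 0); `sigma_log_from_fwhm()`
#'   inverts the log-space conversion.
#' @export
sigma_log_from_fwhm <- function(mu, omega) {
  stopifnot(all(mu > 0), all(omega > 0))
  asinh(omega / (2 * mu)) / sqrt(2 * log(2))
}

#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF: a gamma density peaking around 5 s minus a slower
#' undershoot gamma scaled by `1/ratio`, sampled on a regular grid and
#' normalized to peak amplitude 1. Defaults are the conventional canonical
#' parameters (peak delay 6 s, undershoot delay 16 s, unit dispersions,
#' peak:undershoot ratio 6, 32 s support).
#'
#' @param dt Sampling step in seconds.
#' @param peak_delay,undershoot_delay Delays (s) of response and undershoot.
#' @param peak_dispersion,undershoot_dispersion Dispersions (s).
#' @param ratio Peak to undershoot amplitude ratio.
#' @param duration Kernel length in seconds.
#' @return A tibble `time`, `value` with attributes `dt` and `params`,
#'   class `nprf_hrf`. First sample is at t = 0 (value 0).
#' @export
canonical_hrf <- function(dt = 0.1, peak_delay = 6, undershoot_delay = 16,
                          peak_dispersion = 1, undershoot_dispersion = 1,
                          ratio = 6, duration = 32) {
  stopifnot(dt > 0, duration > 0)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / peak_dispersion,
                     scale = peak_dispersion) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion,
                  scale = undershoot_dispersion) / ratio
  h <- h / max(h)
  structure(tibble::tibble(time = t, value = h),
            dt = dt,
            params = list(peak_delay = peak_delay,
                          undershoot_delay = undershoot_delay,
                          peak_dispersion = peak_dispersion,
                          undershoot_dispersion = undershoot_dispersion,
                          ratio = ratio, duration = duration),
            class = c("nprf_hrf", class(tibble::tibble())))
}

# causal convolution of a microtime course with the HRF kernel, scaled by
# dt so the result approximates the continuous convolution integral, then
# sampled at the slice-time-corrected volume times by linear interpolation
.convolve_decimate <- function(zfine, hrf, schedule) {
  dt <- attr(hrf, "dt")
  n <- length(zfine)
  full <- stats::convolve(zfine, rev(hrf$value), type = "open")
  sfine <- dt * full[seq_len(n)]
  tr <- attr(schedule, "tr")
  vol_t <- (seq_len(attr(schedule, "n_volumes")) - 1) * tr +
    attr(schedule, "slice_time_ref")
  tfine <- (seq_len(n) - 1) * dt
  stats::approx(tfine, sfine, xout = vol_t, rule = 2)$y
}

#' Predicted hemodynamic time course for one tuning parameter set
#'
#' Evaluates the neuronal tuning response on the microtime stimulus grid
#' (0 where no stimulus is scheduled), convolves it with the HRF, and
#' samples the result at the slice-time-corrected volume acquisition
#' times `k * tr + slice_time_ref`.
#'
#' @param schedule A `nprf_schedule`.
#' @param mu Preferred numerosity.
#' @param sigma Tuning SD: log-space for `space = "log"`, linear-space for
#'   `space = "linear"`.
#' @param hrf HRF kernel from [canonical_hrf()]; its `dt` is the microtime
#'   grid step and must divide the TR evenly.
#' @param space Tuning space, `"log"` (default) or `"linear"`.
#' @param event_level Use event-level rather than block-level boxcars.
#' @return A tibble `volume`, `time`, `value` (class `nprf_prediction`),
#'   one row per acquired volume.
#' @export
predict_timecourse <- function(schedule, mu, sigma, hrf = canonical_hrf(),
                               space = c("log", "linear"),
                               event_level = FALSE) {
  space <- match.arg(space)
  stopifnot(inherits(schedule, "nprf_schedule"), inherits(hrf, "nprf_hrf"))
  dt <- attr(hrf, "dt")
  tc <- numerosity_timecourse(schedule, dt = dt, event_level = event_level)
  z <- rep(0, nrow(tc))
  on <- !is.na(tc$numerosity)
  z[on] <- if (space == "log") {
    tuning_response(tc$numerosity[on], mu, sigma)
  } else {
    tuning_response_linear(tc$numerosity[on], mu, sigma)
  }
  vals <- .convolve_decimate(z, hrf, schedule)
  tr <- attr(schedule, "tr")
  structure(tibble::tibble(
    volume = seq_along(vals),
    time = (seq_along(vals) - 1) * tr + attr(schedule, "slice_time_ref"),
    value = vals),
    tr = tr, class = c("nprf_prediction", class(tibble::tibble())))
}

#' Condition regressors: one convolved boxcar per numerosity level
#'
#' For each distinct presented numerosity, builds the microtime indicator
#' of its blocks (or events), convolves it with the HRF and samples at
#' volume times. These regressors serve two purposes: they are the design
#' columns of the categorical control GLM, and -- because the tuned
#' neuronal response is a level-wise weighting of these indicators -- any
#' predicted tuning time course is their linear combination, which is what
#' makes exhaustive grid search over thousands of tuning parameter pairs
#' cheap.
#'
#' @inheritParams predict_timecourse
#' @return A matrix with one row per volume and one named column per
#'   numerosity level (ascending).
#' @export
condition_regressors <- function(schedule, hrf = canonical_hrf(),
                                 event_level = FALSE) {
  stopifnot(inherits(schedule, "nprf_schedule"), inherits(hrf, "nprf_hrf"))
  tc <- numerosity_timecourse(schedule, dt = attr(hrf, "dt"),
                              event_level = event_level)
  levels <- sort(unique(schedule$numerosity))
  C <- vapply(levels, function(lv) {
    .convolve_decimate(as.numeric(!is.na(tc$numerosity) &
                                    tc$numerosity == lv), hrf, schedule)
  }, numeric(attr(schedule, "n_volumes")))
  colnames(C) <- as.character(levels)
  C
}
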