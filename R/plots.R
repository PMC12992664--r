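#' Plot log-Gaussian tuning curves
#'
#' @param mu,sigma_log Vectors of tuning parameters (recycled pairwise).
#' @param xlim Numerosity axis range.
#' @return A ggplot (numerosity on a log axis).
#' @export
plot_tuning <- function(mu, sigma_log, xlim = c(0.5, 20)) {
  pars <- tibble::tibble(mu = mu, sigma_log = sigma_log)
  x <- exp(seq(log(xlim[1]), log(xlim[2]), length.out = 300))
  d <- purrr::pmap_dfr(pars, function(mu, sigma_log) {
    tibble::tibble(
      x = x, z = tuning_response(x, mu, sigma_log),
      curve = sprintf("mu = %.2f, fwhm = %.2f", mu,
                      fwhm_log(mu, sigma_log)))
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$z, colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10(breaks = c(1:5, 10, 20)) +
    ggplot2::labs(x = "numerosity", y = "neuronal response",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the block design of a run
#'
#' @param schedule A `nprf_schedule`.
#' @return A ggplot showing each block as a tile at its numerosity.
#' @export
plot_schedule <- function(schedule) {
  d <- schedule_events(schedule)
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$onset, xmax = .data$onset + .data$duration,
      ymin = 0, ymax = .data$numerosity, fill = factor(.data$numerosity))) +
    ggplot2::labs(x = "time (s)", y = "presented numerosity",
                  fill = "numerosity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nprf_prediction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "predicted signal") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nprf_fit <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$status <- ifelse(d$selected %in% TRUE, "selected", "rejected")
  ggplot2::ggplot(d, ggplot2::aes(.data$mu_hat, .data$cv_r2,
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "config")$r2_threshold,
                        linetype = 2) +
    ggplot2::labs(x = "preferred numerosity", y = "cross-validated R²",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nprf_geometry <- function(object, ...) {
  b <- object$bins
  d <- dplyr::bind_rows(
    tibble::tibble(bin_center = b$bin_center, value = b$area_sum,
                   se = NA_real_, panel = "summed area (mm²)"),
    tibble::tibble(bin_center = b$bin_center, value = b$fwhm_mean,
                   se = b$fwhm_se, panel = "mean FWHM"))
  ggplot2::ggplot(d, ggplot2::aes(.data$bin_center, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           width = 0.1, na.rm = TRUE) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "preferred numerosity (bin center)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nprf_coordfit <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$mu, .data$mu_pred)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(
      x = "estimated preferred numerosity",
      y = "predicted from coordinates",
      subtitle = sprintf("cv-r = %.3f, MAE = %.3f", object$cv_r,
                         object$mae)) +
    ggplot2::theme_minimal()
}
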