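#' Tidy a per-vertex pRF fit
#'
#' @param x A `nprf_fit`.
#' @param ... Unused.
#' @return The per-vertex tibble (one row per vertex).
#' @export
tidy.nprf_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a pRF fit
#'
#' @param x A `nprf_fit`.
#' @param ... Unused.
#' @return A tibble with vertex counts, the Bonferroni variance-explained
#'   threshold and the best cross-validated fit.
#' @export
glance.nprf_fit <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_vertices = nrow(x),
    n_selected = sum(x$selected, na.rm = TRUE),
    r2_threshold = cfg$r2_threshold,
    max_cv_r2 = suppressWarnings(max(x$cv_r2, na.rm = TRUE)),
    median_mu_selected = stats::median(x$mu_hat[x$selected %in% TRUE]),
    n_runs = cfg$n_runs, space = cfg$space
  )
}

#' @export
tidy.nprf_geometry <- function(x, ...) x$bins

#' @export
glance.nprf_geometry <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x$bins),
    area_r = x$area_r,
    area_slope = if (is.null(x$area_lm)) NA_real_
    else unname(stats::coef(x$area_lm)[2]),
    fwhm_r = x$fwhm_r,
    fwhm_slope = if (is.null(x$fwhm_lm)) NA_real_
    else unname(stats::coef(x$fwhm_lm)[2])
  )
}

#' @export
tidy.nprf_coordfit <- function(x, ...) x$predictions

#' @export
glance.nprf_coordfit <- function(x, ...) {
  tibble::tibble(cv_r = x$cv_r, mae = x$mae, order = x$order,
                 folds = x$folds, n = nrow(x$predictions))
}
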