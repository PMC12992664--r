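#' Default tuning parameter grid
#'
#' The exhaustive search grid: preferred numerosity mu from 0.8 to 5.2 in
#' steps of 0.05 (89 values) and tuning SD from 0.05 to 3.0 in steps of
#' 0.05 (60 values), giving 5340 combinations. The sigma upper bound 3.0
#' reproduces the FWHM extremes 0.12--34.17 at mu = 1 and 0.59--170.9 at
#' mu = 5. Rows are ordered mu-ascending then sigma-ascending; ties in the
#' search are broken towards the first row in this scan order.
#'
#' @param mu_min,mu_max,mu_step Preferred-numerosity grid bounds and step.
#' @param sigma_min,sigma_max,sigma_step Tuning-SD grid bounds and step
#'   (log-space SD for `space = "log"`, linear-space SD otherwise).
#' @param space `"log"` (default) or `"linear"` tuning.
#' @return A tibble `mu`, `sigma` with attribute `space`.
#' @export
default_grid <- function(mu_min = 0.8, mu_max = 5.2, mu_step = 0.05,
                         sigma_min = 0.05, sigma_max = 3.0, sigma_step = 0.05,
                         space = c("log", "linear")) {
  space <- match.arg(space)
  mu <- round(seq(mu_min, mu_max, by = mu_step), 10)
  sigma <- round(seq(sigma_min, sigma_max, by = sigma_step), 10)
  g <- tidyr::expand_grid(mu = mu, sigma = sigma)
  structure(g, space = space)
}

#' Grid of predicted time courses
#'
#' Predicted hemodynamic time courses for every grid point, computed as
#' the convolved per-level condition regressors weighted by the tuning
#' response at each presented numerosity level (see
#' [condition_regressors()]).
#'
#' @inheritParams predict_timecourse
#' @param grid Tibble `mu`, `sigma` from [default_grid()].
#' @return A list with `S` (matrix, volumes x grid points), `grid`, `C`
#'   (condition regressors) and `levels`.
#' @export
grid_predictions <- function(schedule, grid = default_grid(),
                             hrf = canonical_hrf(), event_level = FALSE) {
  space <- attr(grid, "space") %||% "log"
  C <- condition_regressors(schedule, hrf, event_level)
  levels <- as.numeric(colnames(C))
  Z <- vapply(seq_len(nrow(grid)), function(g) {
    if (space == "log") tuning_response(levels, grid$mu[g], grid$sigma[g])
    else tuning_response_linear(levels, grid$mu[g], grid$sigma[g])
  }, numeric(length(levels)))
  list(S = C %*% Z, grid = grid, C = C, levels = levels, space = space)
}

#' Least-squares scaling fit of one predicted time course
#'
#' Fits `y = beta * s + beta0` by ordinary least squares and returns the
#' Gaussian log-likelihood at the maximum-likelihood variance
#' `sigma^2 = RSS / n`:
#' `loglik = -n/2 * log(2 pi RSS / n) - n/2`.
#'
#' @param y Measured values (averaged run), length n.
#' @param s Predicted time course values, length n, non-constant.
#' @return A tibble with `beta`, `beta0`, `rss`, `loglik`.
#' @export
ols_scaling_fit <- function(y, s) {
  stopifnot(length(y) == length(s))
  n <- length(y)
  sc <- s - mean(s)
  ss <- sum(sc^2)
  if (ss < 1e-12)
    stop("degenerate regressor: predicted time course is constant",
         call. = FALSE)
  yc <- y - mean(y)
  beta <- sum(sc * yc) / ss
  beta0 <- mean(y) - beta * mean(s)
  rss <- sum(yc^2) - beta^2 * ss
  rss <- max(rss, 0)
  tibble::tibble(beta = beta, beta0 = beta0, rss = rss,
                 loglik = .loglik_gauss(rss, n))
}

.loglik_gauss <- function(rss, n) {
  ifelse(rss <= 0, Inf, -n / 2 * log(2 * pi * rss / n) - n / 2)
}

# core vectorized grid fit: Y [volume x vertex], gp from grid_predictions().
# For every vertex, evaluates the OLS fit of every grid column and returns
# the maximizer of the log-likelihood (equivalently the RSS minimizer).
# Ties go to the first grid row in (mu asc, sigma asc) order.
.grid_fit_matrix <- function(Y, gp, chunk = 2000L) {
  S <- gp$S
  n <- nrow(Y)
  sbar <- colMeans(S)
  Sc <- sweep(S, 2, sbar)
  ss <- colSums(Sc^2)
  degen <- ss < 1e-12
  ss_safe <- ifelse(degen, 1, ss)
  V <- ncol(Y)
  idx <- integer(V); beta <- numeric(V); rss <- numeric(V); ties <- 0L
  ybar_all <- colMeans(Y)
  for (lo in seq(1, V, by = chunk)) {
    hi <- min(lo + chunk - 1L, V)
    Yc <- sweep(Y[, lo:hi, drop = FALSE], 2, ybar_all[lo:hi])
    yss <- colSums(Yc^2)
    CP <- crossprod(Sc, Yc)                    # grid x vertices
    RED <- CP^2 / ss_safe                      # explained sum of squares
    if (any(degen)) RED[degen, ] <- -Inf
    gi <- max.col(t(RED), ties.method = "first")
    best <- RED[cbind(gi, seq_along(gi))]
    ties <- ties + sum(colSums(RED == rep(best, each = nrow(RED))) > 1L)
    idx[lo:hi] <- gi
    beta[lo:hi] <- CP[cbind(gi, seq_along(gi))] / ss_safe[gi]
    rss[lo:hi] <- pmax(yss - best, 0)
  }
  if (ties > 0)
    message(ties, " vertex/vertices had exact log-likelihood ties; ",
            "first grid point in scan order kept")
  tibble::tibble(
    grid_index = idx,
    mu_hat = gp$grid$mu[idx],
    sigma_hat = gp$grid$sigma[idx],
    beta_hat = beta,
    beta0_hat = ybar_all - beta * sbar[idx],
    rss = rss,
    loglik = .loglik_gauss(rss, n)
  )
}

#' Exhaustive grid-search estimation for one vertex
#'
#' Evaluates the ordinary-least-squares fit of every (mu, sigma) grid
#' combination to an averaged, conditioned run and returns the
#' log-likelihood maximizer. Under i.i.d. Gaussian errors this is the
#' maximum-likelihood estimate and equals the residual-sum-of-squares
#' minimizer.
#'
#' @param y Averaged run values (one per volume), conditioned.
#' @param schedule A `nprf_schedule`.
#' @param grid Tibble from [default_grid()].
#' @param hrf HRF kernel.
#' @param event_level Use event-level boxcars.
#' @return One-row tibble: `mu_hat`, `sigma_hat`, `omega_hat`, `beta_hat`,
#'   `beta0_hat`, `rss`, `loglik`.
#' @export
grid_search <- function(y, schedule, grid = default_grid(),
                        hrf = canonical_hrf(), event_level = FALSE) {
  if (all(is.na(y))) stop("all-NaN vertex: nothing to fit", call. = FALSE)
  gp <- grid_predictions(schedule, grid, hrf, event_level)
  fit <- .grid_fit_matrix(matrix(y, ncol = 1), gp)
  fit$omega_hat <- if (gp$space == "log") {
    fwhm_log(fit$mu_hat, fit$sigma_hat)
  } else fwhm_linear(fit$sigma_hat)
  fit[, c("mu_hat", "sigma_hat", "omega_hat", "beta_hat", "beta0_hat",
          "rss", "loglik")]
}

#' F-statistic for (cross-validated) variance explained
#'
#' `F = (R^2 / (p - 1)) / ((1 - R^2) / (n - p))` with p - 1 numerator and
#' n - p denominator degrees of freedom. Negative R-squared values map to
#' a negative F through the same monotone expression; p-values come from
#' the upper tail of the F distribution.
#'
#' @param r2 Coefficient of determination (< 1).
#' @param n Volumes per averaged run.
#' @param p Free parameters of the scaling model (default 2: beta0, beta;
#'   the tuning parameters are estimated from independent data).
#' @return `f_from_r2()`: the F statistic. `r2_p_value()`: its p-value.
#' @examples
#' f_from_r2(0.5, n = 145, p = 2) # 143
#' @export
f_from_r2 <- function(r2, n = 145, p = 2) {
  stopifnot(all(r2 <= 1, na.rm = TRUE), n > p, p >= 2)
  (r2 / (p - 1)) / ((1 - r2) / (n - p))   # r2 = 1 gives F = Inf, p = 0
}

#' @rdname f_from_r2
#' @export
r2_p_value <- function(r2, n = 145, p = 2) {
  stats::pf(f_from_r2(r2, n, p), p - 1, n - p, lower.tail = FALSE)
}

#' Bonferroni-corrected variance-explained threshold
#'
#' The R-squared whose F statistic attains `p = alpha / n_vertices`,
#' obtained by inverting the F quantile: `r2 = F / (F + n - p)`. With the
#' default n = 145, p = 2, alpha = 0.05 and 100,000 vertices this is
#' 0.1625.
#'
#' @inheritParams f_from_r2
#' @param alpha Significance level before correction.
#' @param n_vertices Number of vertices corrected for.
#' @return The minimal significant R-squared.
#' @export
r2_threshold <- function(n = 145, p = 2, alpha = 0.05, n_vertices = 1) {
  stopifnot(n_vertices >= 1, alpha > 0, alpha < 1)
  f <- stats::qf(alpha / n_vertices, p - 1, n - p, lower.tail = FALSE)
  f / (f + n - p)
}

#' Split-half cross-validated variance explained
#'
#' Partitions the runs into odd (1st, 3rd, ...) and even halves by their
#' position in sorted run order. Tuning parameters are estimated by grid
#' search on one half's average; the implied predicted time course is then
#' fit to the other half's average by OLS (re-estimating baseline and
#' scaling, the model's two free parameters), yielding an out-of-sample
#' R-squared. cvR-squared is the mean of the two directions.
#'
#' @param data Long conditioned tibble (`vertex`, `run`, `volume`, `value`)
#'   with at least two runs.
#' @inheritParams grid_search
#' @return A tibble per vertex: `vertex`, `r2_odd_train`, `r2_even_train`,
#'   `cv_r2`, plus the odd- and even-trained parameter estimates.
#' @export
split_half_cv <- function(data, schedule, grid = default_grid(),
                          hrf = canonical_hrf(), event_level = FALSE) {
  cube <- .as_run_cube(data)
  if (length(cube$runs) < 2)
    stop("split-half cross-validation needs at least 2 runs", call. = FALSE)
  odd <- seq(1, length(cube$runs), by = 2)
  even <- seq(2, length(cube$runs), by = 2)
  gp <- grid_predictions(schedule, grid, hrf, event_level)
  .split_half_core(cube, odd, even, gp)
}

# shared core so fit_prf() can reuse an existing prediction grid
.split_half_core <- function(cube, odd, even, gp) {
  Y_odd <- .average_matrix(cube, odd)
  Y_even <- .average_matrix(cube, even)
  fit_o <- .grid_fit_matrix(Y_odd, gp)
  fit_e <- .grid_fit_matrix(Y_even, gp)
  r2_oos <- function(gi, Ytest) {
    Sc <- sweep(gp$S[, gi, drop = FALSE], 2, colMeans(gp$S)[gi])
    ss <- colSums(Sc^2)
    Yc <- sweep(Ytest, 2, colMeans(Ytest))
    yss <- colSums(Yc^2)
    cp <- colSums(Sc * Yc)
    out <- ifelse(ss < 1e-12 | yss < 1e-300, 0, cp^2 / (ss * yss))
    out
  }
  tibble::tibble(
    vertex = cube$vertices,
    mu_odd = fit_o$mu_hat, sigma_odd = fit_o$sigma_hat,
    mu_even = fit_e$mu_hat, sigma_even = fit_e$sigma_hat,
    r2_odd_train = r2_oos(fit_o$grid_index, Y_even),
    r2_even_train = r2_oos(fit_e$grid_index, Y_odd),
    cv_r2 = (r2_odd_train + r2_even_train) / 2
  )
}

#' Fit numerosity pRF models to all vertices
#'
#' The full single-subject estimation: averages the conditioned runs,
#' grid-searches tuning parameters per vertex, computes split-half
#' cross-validated variance explained, derives F statistics and
#' Bonferroni-corrected p-values, and flags selected vertices (positive
#' scaling, preferred numerosity within the presented range 1--5,
#' significant cvR-squared).
#'
#' Reported tuning parameters come from the fit to the all-run average;
#' cvR-squared and significance come from the split-half procedure.
#'
#' @param data Long conditioned tibble: `vertex`, `run`, `volume`, `value`.
#' @inheritParams grid_search
#' @param alpha Significance level (default 0.05).
#' @param n_comparisons Bonferroni correction count; defaults to the
#'   number of vertices in `data`. Use the hemisphere vertex count when
#'   fitting a subset.
#' @param cv Run split-half cross-validation (default `TRUE`; requires at
#'   least two runs). With `cv = FALSE`, cvR-squared and selection are NA.
#' @return A `nprf_fit` tibble, one row per vertex: `vertex`, `mu_hat`,
#'   `sigma_hat`, `omega_hat`, `beta_hat`, `beta0_hat`, `loglik`, `cv_r2`,
#'   `f_stat`, `p_value`, `selected`. Attributes carry the test
#'   configuration (`config`) and per-criterion selection counts
#'   (`selection_counts`).
#' @export
fit_prf <- function(data, schedule, grid = default_grid(),
                    hrf = canonical_hrf(), event_level = FALSE,
                    alpha = 0.05, n_comparisons = NULL, cv = TRUE) {
  cube <- .as_run_cube(data)
  gp <- grid_predictions(schedule, grid, hrf, event_level)
  n <- cube$n_volumes
  Y_all <- .average_matrix(cube, seq_along(cube$runs))
  fit <- .grid_fit_matrix(Y_all, gp)
  out <- tibble::tibble(
    vertex = cube$vertices,
    mu_hat = fit$mu_hat, sigma_hat = fit$sigma_hat,
    omega_hat = if (gp$space == "log") fwhm_log(fit$mu_hat, fit$sigma_hat)
    else fwhm_linear(fit$sigma_hat),
    beta_hat = fit$beta_hat, beta0_hat = fit$beta0_hat,
    loglik = fit$loglik
  )
  if (cv && length(cube$runs) >= 2) {
    odd <- seq(1, length(cube$runs), by = 2)
    even <- seq(2, length(cube$runs), by = 2)
    cvr <- .split_half_core(cube, odd, even, gp)
    out$cv_r2 <- cvr$cv_r2
  } else {
    if (cv) warning("fewer than 2 runs: cross-validation skipped")
    out$cv_r2 <- NA_real_
  }
  out$f_stat <- ifelse(is.na(out$cv_r2), NA_real_,
                       f_from_r2(out$cv_r2, n, 2))
  out$p_value <- ifelse(is.na(out$cv_r2), NA_real_,
                        r2_p_value(out$cv_r2, n, 2))
  n_comparisons <- n_comparisons %||% length(cube$vertices)
  out <- select_vertices(out, alpha = alpha, n_comparisons = n_comparisons)
  attr(out, "config") <- list(
    n = n, p = 2, alpha = alpha, n_comparisons = n_comparisons,
    r2_threshold = r2_threshold(n, 2, alpha, n_comparisons),
    space = gp$space, n_grid = nrow(gp$grid), n_runs = length(cube$runs)
  )
  class(out) <- c("nprf_fit", class(tibble::tibble()))
  out
}

#' Apply the vertex selection criteria
#'
#' A vertex is selected when its scaling factor is positive
#' (`beta_hat > 0`), its preferred numerosity lies inside the presented
#' stimulus range (`1 <= mu_hat <= 5`) and its cross-validated variance
#' explained is significant at the Bonferroni-corrected level.
#'
#' @param fits Tibble with columns `beta_hat`, `mu_hat`, `p_value`.
#' @param alpha Significance level before correction.
#' @param n_comparisons Bonferroni correction count.
#' @return `fits` with a logical `selected` column; attribute
#'   `selection_counts` logs how many vertices pass each criterion.
#' @export
select_vertices <- function(fits, alpha = 0.05, n_comparisons = 1) {
  pos <- fits$beta_hat > 0
  in_range <- fits$mu_hat >= 1 & fits$mu_hat <= 5
  sig <- !is.na(fits$p_value) & fits$p_value < alpha / n_comparisons
  fits$selected <- pos & in_range & sig
  attr(fits, "selection_counts") <- c(
    n_vertices = nrow(fits), beta_positive = sum(pos),
    mu_in_range = sum(in_range), significant = sum(sig),
    selected = sum(fits$selected)
  )
  fits
}

#' Write a per-vertex fit table as TSV
#'
#' @param fit A `nprf_fit` tibble.
#' @param path Output file.
#' @export
write_fit_tsv <- function(fit, path) {
  utils::write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
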