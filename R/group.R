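#' Participant count map
#'
#' Counts, per standard-space vertex, how many subjects show numerosity
#' selectivity under the variance-explained criterion.
#'
#' @param masks Long tibble with columns `subject`, `vertex`, `selected`
#'   (logical). Every subject must cover the same vertex set.
#' @return A tibble `vertex`, `count`.
#' @export
participant_count_map <- function(masks) {
  stopifnot(all(c("subject", "vertex", "selected") %in% names(masks)))
  sets <- tapply(masks$vertex, masks$subject,
                 function(v) paste(sort(v), collapse = ","))
  if (length(unique(sets)) != 1)
    stop("subjects do not share one vertex index space", call. = FALSE)
  masks |>
    dplyr::group_by(.data$vertex) |>
    dplyr::summarise(count = sum(.data$selected), .groups = "drop")
}

#' Linear mixed-effects model of tuning geometry
#'
#' Fits `dependent ~ hemisphere + hemisphere:mu + (1 | subject)` by REML:
#' a random intercept per subject, a hemisphere main effect (R vs the L
#' reference) and hemisphere-specific slopes of binned preferred
#' numerosity. This parameterization yields one hemisphere row plus
#' per-hemisphere mu slopes (`mu [L]`, `mu [R]`). Wald z statistics,
#' two-sided normal p-values and 95 percent CIs are reported. If the
#' random-effects fit is singular or fails, a pooled ordinary regression
#' is used instead, with a warning.
#'
#' @param table Tibble with columns `subject`, `hemi` (`"L"`/`"R"`), `mu`
#'   (bin center), and the dependent variable column.
#' @param dependent `"area"` or `"fwhm"` (must be a column of `table`).
#' @return A tibble: `term` (`hemi`, `mu [L]`, `mu [R]`), `estimate`,
#'   `se`, `z`, `p_value`, `conf.low`, `conf.high`; attribute `method`
#'   records `"lmer"` or `"lm"`.
#' @export
mixed_effects_geometry <- function(table, dependent = c("area", "fwhm")) {
  dependent <- match.arg(dependent)
  stopifnot(all(c("subject", "hemi", "mu", dependent) %in% names(table)),
            length(unique(table$subject)) >= 2)
  if (!all(c("L", "R") %in% table$hemi))
    stop("both hemispheres must be present", call. = FALSE)
  d <- data.frame(y = table[[dependent]],
                  hemi = factor(table$hemi, levels = c("L", "R")),
                  mu = table$mu,
                  subject = factor(table$subject))
  method <- "lmer"
  fit <- tryCatch({
    m <- lme4::lmer(y ~ hemi + hemi:mu + (1 | subject), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
    if (lme4::isSingular(m, tol = 1e-5)) NULL else m
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("singular or failed random-effects fit: ",
            "falling back to pooled regression")
    method <- "lm"
    fit <- stats::lm(y ~ hemi + hemi:mu, data = d)
    cf <- summary(fit)$coefficients[, 1:2]
  } else {
    cf <- summary(fit)$coefficients[, 1:2, drop = FALSE]
  }
  want <- c(hemiR = "hemi", `hemiL:mu` = "mu [L]", `hemiR:mu` = "mu [R]")
  est <- cf[names(want), 1]
  se <- cf[names(want), 2]
  z <- est / se
  out <- tibble::tibble(
    term = unname(want), estimate = unname(est), se = unname(se),
    z = unname(z), p_value = 2 * stats::pnorm(-abs(unname(z))),
    conf.low = unname(est - stats::qnorm(0.975) * se),
    conf.high = unname(est + stats::qnorm(0.975) * se))
  attr(out, "method") <- method
  out
}

#' Categorical GLM contrast against the large-numerosity baseline
#'
#' The control analysis for a categorical (non-tuned) numerosity effect:
#' an OLS GLM with one convolved boxcar regressor per presented numerosity
#' (1, 2, 3, 4, 5, 20) plus optional confound columns, fitted to the
#' averaged conditioned run of each vertex. The default contrast
#' "1-5 minus 20" uses weights (1/5, ..., 1/5, -1), which sum to zero.
#'
#' @param data Long conditioned tibble: `vertex`, `run`, `volume`, `value`.
#' @param schedule A `nprf_schedule`.
#' @param confounds Optional confound data frame (one row per volume).
#' @param weights Contrast weights over the ascending numerosity levels;
#'   must sum to 0.
#' @param hrf HRF kernel.
#' @return A tibble per vertex: `vertex`, `contrast`, `se`, `t_stat`.
#' @export
categorical_glm_contrast <- function(data, schedule, confounds = NULL,
                                     weights = c(rep(1 / 5, 5), -1),
                                     hrf = canonical_hrf()) {
  if (abs(sum(weights)) > 1e-10)
    stop("contrast weights must sum to 0", call. = FALSE)
  cube <- .as_run_cube(data)
  Y <- .average_matrix(cube, seq_along(cube$runs))
  C <- condition_regressors(schedule, hrf)
  if (length(weights) != ncol(C))
    stop("need one weight per numerosity level (", ncol(C), ")",
         call. = FALSE)
  X <- cbind(`(intercept)` = 1, C)
  if (!is.null(confounds)) {
    cf <- as.matrix(confounds[, !(colnames(confounds) %in%
                                    c("run", "volume")), drop = FALSE])
    X <- cbind(X, cf)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient GLM design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qx, Y)                       # coefficients x vertices
  R <- Y - X %*% B
  df <- nrow(X) - qx$rank
  sigma2 <- colSums(R^2) / df
  w_full <- c(0, weights, rep(0, ncol(X) - 1 - length(weights)))
  xtx_inv <- chol2inv(chol(crossprod(X)))
  wvar <- as.numeric(t(w_full) %*% xtx_inv %*% w_full)
  cval <- as.numeric(t(w_full) %*% B)
  se <- sqrt(wvar * sigma2)
  tibble::tibble(vertex = cube$vertices, contrast = cval, se = se,
                 t_stat = cval / se)
}

#' Group-level one-sample t-test of contrast maps
#'
#' Tests, per vertex, whether the subject contrast values differ from
#' zero, reporting both one-sided tails: positive (small numerosities
#' above baseline) and negative (baseline above small numerosities).
#'
#' @param data Tibble with columns `vertex`, `subject`, `contrast`
#'   (at least 2 subjects).
#' @return A tibble per vertex: `vertex`, `n`, `mean`, `t_stat`,
#'   `p_positive`, `p_negative`, `zero_variance` (t undefined when the
#'   subject values have no spread).
#' @export
group_t_test <- function(data) {
  stopifnot(all(c("vertex", "subject", "contrast") %in% names(data)))
  if (length(unique(data$subject)) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  data |>
    dplyr::group_by(.data$vertex) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$contrast),
      sd = stats::sd(.data$contrast),
      .groups = "drop") |>
    dplyr::mutate(
      zero_variance = .data$sd < 1e-300,
      t_stat = ifelse(.data$zero_variance, NA_real_,
                      .data$mean / (.data$sd / sqrt(.data$n))),
      p_positive = stats::pt(.data$t_stat, .data$n - 1, lower.tail = FALSE),
      p_negative = stats::pt(.data$t_stat, .data$n - 1, lower.tail = TRUE)
    ) |>
    dplyr::select("vertex", "n", "mean", "t_stat", "p_positive",
                  "p_negative", "zero_variance")
}
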