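#' Simulate runs for one vertex with known tuning
#'
#' Generates `y_t = beta * s_t + beta0 + e_t` per run, where `s_t` is the
#' forward-model prediction for the given tuning parameters and `e_t` is
#' Gaussian noise in percent-signal-change units, independent across runs
#' (optionally AR(1) within a run).
#'
#' @param schedule A `nprf_schedule`.
#' @param mu,sigma_log Tuning parameters; `mu = NA` (or `beta = 0`)
#'   simulates a null vertex (noise only).
#' @param beta,beta0 Scaling (PSC per unit response) and baseline.
#' @param noise_sd Noise SD in PSC units (> 0).
#' @param n_runs Number of runs (default 8).
#' @param ar1_rho Optional AR(1) coefficient of the noise (default 0,
#'   i.i.d.); the marginal SD stays `noise_sd`.
#' @param seed Optional integer seed; same seed, same data.
#' @param hrf HRF kernel.
#' @return Long tibble `run`, `volume`, `value`.
#' @export
simulate_vertex <- function(schedule, mu, sigma_log, beta = 1, beta0 = 0,
                            noise_sd = 0.5, n_runs = 8, ar1_rho = 0,
                            seed = NULL, hrf = canonical_hrf()) {
  stopifnot(n_runs >= 1, noise_sd > 0)
  truth <- tibble::tibble(vertex = 1L, mu = mu, sigma_log = sigma_log,
                          beta = beta, beta0 = beta0, noise_sd = noise_sd,
                          ar1_rho = ar1_rho)
  out <- simulate_vertices(schedule, truth, n_runs = n_runs, seed = seed,
                           hrf = hrf)
  out[, c("run", "volume", "value")]
}

#' Simulate many vertices with known ground truth
#'
#' Vectorized generative model for a table of vertices. Null vertices
#' (`beta = 0` or `mu` NA) receive pure noise.
#'
#' @param schedule A `nprf_schedule`.
#' @param truth Tibble with columns `vertex`, `mu`, `sigma_log`, `beta`,
#'   `beta0`, `noise_sd` and optionally `ar1_rho`.
#' @param n_runs Number of runs.
#' @param seed Optional integer seed.
#' @param hrf HRF kernel.
#' @return Long tibble `vertex`, `run`, `volume`, `value`.
#' @export
simulate_vertices <- function(schedule, truth, n_runs = 8, seed = NULL,
                              hrf = canonical_hrf()) {
  stopifnot(all(c("vertex", "mu", "sigma_log", "beta", "beta0",
                  "noise_sd") %in% names(truth)),
            all(truth$noise_sd > 0))
  if (!is.null(seed)) set.seed(seed)
  C <- condition_regressors(schedule, hrf)
  levels <- as.numeric(colnames(C))
  V <- nrow(truth)
  tuned <- !is.na(truth$mu) & truth$beta != 0
  Z <- matrix(0, length(levels), V)
  if (any(tuned)) {
    Z[, tuned] <- vapply(which(tuned), function(v) {
      truth$beta[v] * tuning_response(levels, truth$mu[v], truth$sigma_log[v])
    }, numeric(length(levels)))
  }
  P <- C %*% Z                               # volumes x vertices
  P <- sweep(P, 2, truth$beta0, "+")
  n <- attr(schedule, "n_volumes")
  rho <- if ("ar1_rho" %in% names(truth)) truth$ar1_rho else rep(0, V)
  rho[is.na(rho)] <- 0
  vals <- lapply(seq_len(n_runs), function(r) {
    E <- matrix(stats::rnorm(n * V), n, V)
    if (any(rho != 0)) {
      j <- which(rho != 0)
      E[, j] <- vapply(j, function(v) {
        e <- as.numeric(stats::filter(E[, v] * sqrt(1 - rho[v]^2), rho[v],
                                      method = "recursive"))
        e
      }, numeric(n))
    }
    P + sweep(E, 2, truth$noise_sd, "*")
  })
  tibble::tibble(
    vertex = rep(rep(truth$vertex, each = n), n_runs),
    run = rep(seq_len(n_runs), each = n * V),
    volume = rep(seq_len(n), V * n_runs),
    value = as.numeric(do.call(cbind, vals))
  )
}

#' Regular planar grid mesh
#'
#' A flat `nx` x `ny` vertex grid in the z = 0 plane, triangulated into
#' 2 (nx-1)(ny-1) right triangles with analytically known areas
#' (`spacing^2 / 2` each) -- convenient for exact area checks.
#'
#' @param nx,ny Grid dimensions (vertices).
#' @param spacing Grid spacing in mm.
#' @return A `nprf_mesh`. Vertex `(i, j)` has id `(j - 1) * nx + i`.
#' @export
make_grid_mesh <- function(nx, ny, spacing = 1) {
  co <- cbind(x = rep(seq_len(nx) - 1, ny) * spacing,
              y = rep(seq_len(ny) - 1, each = nx) * spacing,
              z = 0)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  tris <- rbind(cbind(id(i, j), id(i + 1L, j), id(i, j + 1L)),
                cbind(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  surface_mesh(co, tris)
}

#' Simulate a synthetic subject with a planted numerotopic map
#'
#' Builds a planar grid mesh carrying one contiguous numerosity-tuned
#' patch. Within the patch, true preferred numerosity increases smoothly
#' along the x axis over `mu_range`; the map's FWHM increases with mu
#' (`fwhm = fwhm_intercept + fwhm_slope * mu`), emulating the empirically
#' observed width gradient. With `area_profile = "shrinking"` the mu
#' gradient is convex in x, so successive numerosity bins occupy
#' geometrically shrinking surface bands and binned area decreases with
#' preferred numerosity. Vertices outside the patch are null (noise only).
#'
#' @param schedule A `nprf_schedule`.
#' @param nx,ny Mesh grid dimensions (default 40 x 25 = 1000 vertices).
#' @param spacing Mesh spacing in mm.
#' @param map_fraction Fraction of the x extent covered by the tuned
#'   patch, from the low-x edge (default 0.5).
#' @param mu_range True preferred-numerosity range across the patch.
#' @param beta True scaling in PSC units (default 1, a visual-like
#'   signal change).
#' @param beta0 True baseline.
#' @param noise_sd Noise SD in PSC units (default 0.5).
#' @param n_runs Number of runs (default 8).
#' @param area_profile `"shrinking"` (default) or `"uniform"` mu gradient.
#' @param fwhm_intercept,fwhm_slope Linear FWHM-versus-mu rule used to set
#'   the true tuning widths.
#' @param seed Optional integer seed.
#' @param hrf HRF kernel.
#' @return A `nprf_subject` list: `mesh`, `truth` (per-vertex tibble with
#'   `vertex`, `mu`, `sigma_log`, `omega`, `beta`, `beta0`, `noise_sd`,
#'   `tuned`), `data` (long run tibble), `seed`.
#' @export
simulate_subject <- function(schedule, nx = 40, ny = 25, spacing = 1,
                             map_fraction = 0.5, mu_range = c(1, 5),
                             beta = 1, beta0 = 0, noise_sd = 0.5,
                             n_runs = 8,
                             area_profile = c("shrinking", "uniform"),
                             fwhm_intercept = 1, fwhm_slope = 1,
                             seed = NULL, hrf = canonical_hrf()) {
  area_profile <- match.arg(area_profile)
  stopifnot(map_fraction > 0, map_fraction < 1)
  mesh <- make_grid_mesh(nx, ny, spacing)
  x <- mesh$coordinates[, 1]
  x_cut <- min(x) + map_fraction * (max(x) - min(x))
  tuned <- x <= x_cut + 1e-9
  x_hi <- max(x[tuned])                      # gradient spans the patch
  u <- (x - min(x)) / (x_hi - min(x))
  u <- pmin(pmax(u, 0), 1)
  g <- if (area_profile == "shrinking") {
    a <- 1.5                                  # convexity of the gradient
    (exp(a * u) - 1) / (exp(a) - 1)
  } else u
  mu <- mu_range[1] + g * (mu_range[2] - mu_range[1])
  omega <- fwhm_intercept + fwhm_slope * mu
  sl <- rep(NA_real_, length(mu))
  sl[tuned] <- sigma_log_from_fwhm(mu[tuned], omega[tuned])
  truth <- tibble::tibble(
    vertex = seq_len(nrow(mesh$coordinates)),
    mu = ifelse(tuned, mu, NA_real_),
    sigma_log = sl,
    omega = ifelse(tuned, omega, NA_real_),
    beta = ifelse(tuned, beta, 0),
    beta0 = beta0, noise_sd = noise_sd, tuned = tuned)
  data <- simulate_vertices(schedule, truth, n_runs = n_runs, seed = seed,
                            hrf = hrf)
  structure(list(mesh = mesh, truth = truth, data = data, seed = seed),
            class = "nprf_subject")
}

#' @exportS3Method base::print
print.nprf_subject <- function(x, ...) {
  cat("<nprf_subject> ", nrow(x$truth), " vertices (",
      sum(x$truth$tuned), " tuned), ", length(unique(x$data$run)),
      " runs\n", sep = "")
  invisible(x)
}

#' Score parameter recovery against ground truth
#'
#' Joins a fitted vertex table with its generating truth and reports
#' detection and estimation quality: sensitivity (selected among truly
#' tuned), specificity (not selected among null), and -- over selected
#' truly tuned vertices -- the bias and RMSE of preferred numerosity and
#' the RMSE of FWHM.
#'
#' @param fit A `nprf_fit` tibble (columns `vertex`, `mu_hat`,
#'   `omega_hat`, `selected`).
#' @param truth Truth tibble (columns `vertex`, `mu`, `omega` or
#'   `sigma_log`, `beta`), e.g. from [simulate_subject()]. An optional
#'   `stratum` column yields one report row per stratum.
#' @return A tibble with `n_tuned`, `n_null`, `sensitivity`,
#'   `specificity`, `mu_bias`, `mu_rmse`, `omega_rmse` (NA when a stratum
#'   has no members for the metric).
#' @export
recovery_report <- function(fit, truth) {
  stopifnot(all(c("vertex", "mu_hat", "selected") %in% names(fit)))
  if (!"omega" %in% names(truth) && "sigma_log" %in% names(truth)) {
    om <- rep(NA_real_, nrow(truth))
    ok <- !is.na(truth$mu) & !is.na(truth$sigma_log)
    om[ok] <- fwhm_log(truth$mu[ok], truth$sigma_log[ok])
    truth$omega <- om
  }
  d <- dplyr::inner_join(fit, truth, by = "vertex",
                         suffix = c("_hat", "_true"))
  d$tuned <- !is.na(d$mu) & d$beta != 0
  if (!"stratum" %in% names(d)) d$stratum <- "all"
  one <- function(g) {
    sel_tuned <- g$tuned & g$selected
    tibble::tibble(
      n_tuned = sum(g$tuned), n_null = sum(!g$tuned),
      sensitivity = if (any(g$tuned)) mean(g$selected[g$tuned]) else NA_real_,
      specificity = if (any(!g$tuned)) mean(!g$selected[!g$tuned])
      else NA_real_,
      mu_bias = if (any(sel_tuned))
        mean(g$mu_hat[sel_tuned] - g$mu[sel_tuned]) else NA_real_,
      mu_rmse = if (any(sel_tuned))
        sqrt(mean((g$mu_hat[sel_tuned] - g$mu[sel_tuned])^2)) else NA_real_,
      omega_rmse = if (any(sel_tuned) && "omega" %in% names(g))
        sqrt(mean((g$omega_hat[sel_tuned] - g$omega[sel_tuned])^2))
      else NA_real_)
  }
  sp <- split(d, d$stratum)
  dplyr::bind_cols(tibble::tibble(stratum = names(sp)),
                   dplyr::bind_rows(lapply(sp, one)))
}

#' Write / read a ground-truth table as TSV
#'
#' @param truth Truth tibble from [simulate_subject()].
#' @param path File path.
#' @return `read_truth_tsv()` returns the tibble.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(as.data.frame(truth[, setdiff(names(truth),
                                                   "outliers")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t"))
}
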