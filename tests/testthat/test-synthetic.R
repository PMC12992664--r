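test_that("simulation is deterministic under a seed", {
  a <- simulate_vertex(sched_vis, 2.5, 0.5, seed = 123, n_runs = 2)
  b <- simulate_vertex(sched_vis, 2.5, 0.5, seed = 123, n_runs = 2)
  expect_identical(a, b)
  c <- simulate_vertex(sched_vis, 2.5, 0.5, seed = 124, n_runs = 2)
  expect_false(identical(a$value, c$value))
  s1 <- simulate_subject(sched_vis, nx = 10, ny = 6, n_runs = 2, seed = 9)
  s2 <- simulate_subject(sched_vis, nx = 10, ny = 6, n_runs = 2, seed = 9)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
})

test_that("null-vertex noise has the requested marginal SD and AR(1) option", {
  d <- simulate_vertex(sched_vis, mu = NA, sigma_log = NA, beta = 0,
                       noise_sd = 0.7, n_runs = 8, seed = 5)
  expect_equal(sd(d$value), 0.7, tolerance = 0.05)     # 145 x 8 samples
  dar <- simulate_vertex(sched_vis, mu = NA, sigma_log = NA, beta = 0,
                         noise_sd = 0.7, n_runs = 8, ar1_rho = 0.6,
                         seed = 5)
  expect_equal(sd(dar$value), 0.7, tolerance = 0.07)
  r1 <- dar$value[dar$run == 1]
  expect_gt(cor(r1[-1], r1[-length(r1)]), 0.4)         # serial correlation
})

test_that("noiseless simulated vertices are identified exactly", {
  d <- simulate_vertex(sched_vis, mu = 3.2, sigma_log = 0.6, beta = 2,
                       beta0 = -1, noise_sd = 1e-9, n_runs = 2, seed = 1)
  d$vertex <- 1L
  fit <- fit_prf(d, sched_vis, n_comparisons = 1)
  expect_equal(fit$mu_hat, 3.2)
  expect_equal(fit$sigma_hat, 0.6)
  expect_equal(fit$beta_hat, 2, tolerance = 1e-6)
  expect_equal(fit$beta0_hat, -1, tolerance = 1e-6)
  expect_true(fit$selected)
})

test_that("a synthetic subject carries the planted numerotopic structure", {
  sub <- simulate_subject(sched_vis, nx = 30, ny = 15, noise_sd = 0.05,
                          n_runs = 4, seed = 33)
  expect_s3_class(sub$mesh, "nprf_mesh")
  expect_equal(nrow(sub$truth), 450)
  # tuned patch is contiguous and mu covers the requested range
  expect_equal(range(sub$truth$mu[sub$truth$tuned]), c(1, 5))
  # planted FWHM increases with mu
  tt <- sub$truth[sub$truth$tuned, ]
  expect_true(all(diff(tt$omega[order(tt$mu)]) >= 0))
  fit <- fit_prf(sub$data, sched_vis, n_comparisons = 1e5)
  sel <- fit$selected
  # polynomial coordinate model recovers the (near-noiseless) gradient
  co <- sub$mesh$coordinates[fit$vertex[sel], ]
  cd <- tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3],
                       mu = fit$mu_hat[sel])
  cfit <- coordinate_polynomial_model(cd, seed = 2)
  expect_gt(cfit$cv_r, 0.99)
  # shrinking-band profile: binned area decreases, FWHM increases with mu
  geo <- geometry_correlations(tibble::tibble(
    mu = fit$mu_hat[sel], fwhm = fit$omega_hat[sel],
    area = vertex_areas(sub$mesh)[fit$vertex[sel]]))
  expect_lt(geo$area_r, 0)
  expect_gt(geo$fwhm_r, 0)
})

test_that("a null-only subject yields no surviving clusters", {
  truth <- make_truth(450, mu = NA, sigma_log = NA, beta = 0, noise_sd = 0.5)
  d <- simulate_vertices(sched_vis, truth, n_runs = 8, seed = 44)
  fit <- fit_prf(d, sched_vis, n_comparisons = 1e5)
  mesh <- make_grid_mesh(30, 15)
  memb <- connected_clusters(mesh, fit$vertex[fit$selected])
  surviving <- if (nrow(memb) == 0) 0 else {
    sum(cluster_summary(mesh, memb)$area_mm2 >= 50)
  }
  expect_equal(surviving, 0)
})

test_that("recovery reports score detection and estimation quality", {
  truth <- make_truth(6, mu = c(1.5, 2, 3, 4, NA, NA),
                      sigma_log = c(rep(0.5, 4), NA, NA),
                      beta = c(rep(1, 4), 0, 0))
  truth$omega <- c(fwhm_log(c(1.5, 2, 3, 4), 0.5), NA, NA)
  perfect <- tibble::tibble(
    vertex = 1:6, mu_hat = c(truth$mu[1:4], 2, 3),
    omega_hat = c(truth$omega[1:4], 1, 1),
    selected = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  rep1 <- recovery_report(perfect, truth)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  expect_equal(rep1$mu_rmse, 0)
  expect_equal(rep1$omega_rmse, 0)
  # empty stratum metrics are missing, not fabricated
  none <- recovery_report(perfect[0, ] |>
                            dplyr::bind_rows(perfect[5:6, ]), truth[5:6, ])
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity, 1)
})

test_that("preferred numerosity outside the stimulus range is filtered out", {
  # a population preferring 6 items, with the tuning width the empirical
  # width-versus-numerosity gradient implies out there (FWHM ~ 10)
  truth <- make_truth(100, mu = 6, sigma_log = sigma_log_from_fwhm(6, 10),
                      noise_sd = 0.5)
  d <- simulate_vertices(sched_vis, truth, n_runs = 8, seed = 60)
  fit <- fit_prf(d, sched_vis, n_comparisons = 1e5)
  expect_gte(mean(!fit$selected), 0.95)
})

test_that("high-SNR preferred numerosity estimates are nearly unbiased", {
  set.seed(70)
  truth <- make_truth(150, mu = runif(150, 1.5, 4.5),
                      sigma_log = runif(150, 0.3, 0.8), noise_sd = 0.25)
  d <- simulate_vertices(sched_vis, truth, n_runs = 8, seed = 71)
  fit <- fit_prf(d, sched_vis, n_comparisons = 1e5)
  rep1 <- recovery_report(fit, truth)
  expect_lt(abs(rep1$mu_bias), 0.15)
})

test_that("the full synthetic pipeline is reproducible end to end", {
  run_once <- function() {
    sub <- simulate_subject(sched_vis, nx = 12, ny = 8, n_runs = 4,
                            seed = 202)
    fit <- fit_prf(sub$data, sched_vis, n_comparisons = 1e4)
    list(sel = fit$vertex[fit$selected], mu = fit$mu_hat)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$sel, b$sel)
  expect_identical(a$mu, b$mu)
})

test_that("truth tables round-trip through TSV", {
  sub <- simulate_subject(sched_vis, nx = 8, ny = 5, n_runs = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(sub$truth, path)
  back <- read_truth_tsv(path)
  expect_equal(back$mu, sub$truth$mu)
  expect_equal(back$beta, sub$truth$beta)
})
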