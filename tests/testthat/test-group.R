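test_that("participant count maps count selections per vertex", {
  masks <- tidyr::expand_grid(subject = 1:12, vertex = 1:5)
  masks$selected <- TRUE
  masks$selected[masks$vertex == 3] <- FALSE
  masks$selected[masks$vertex == 2] <- masks$subject[masks$vertex == 2] <= 4
  cm <- participant_count_map(masks)
  expect_equal(cm$count[cm$vertex == 1], 12)
  expect_equal(cm$count[cm$vertex == 3], 0)
  expect_equal(cm$count[cm$vertex == 2], 4)
  expect_equal(sum(cm$count), sum(masks$selected))   # counting identity
  bad <- masks[!(masks$subject == 2 & masks$vertex == 5), ]
  expect_error(participant_count_map(bad), "index space")
})

# synthetic geometry table with known per-hemisphere slopes and a
# subject-level random intercept
sim_geometry_table <- function(n_subj = 8, slope_l = -100, slope_r = -70,
                               subj_sd = 20, resid_sd = 10, hemi_eff = -30) {
  centers <- seq(1.25, 4.75, by = 0.5)
  g <- tidyr::expand_grid(subject = seq_len(n_subj), hemi = c("L", "R"),
                          mu = centers)
  u <- rnorm(n_subj, 0, subj_sd)
  slope <- ifelse(g$hemi == "L", slope_l, slope_r)
  g$area <- 600 + hemi_eff * (g$hemi == "R") + slope * g$mu +
    u[g$subject] + rnorm(nrow(g), 0, resid_sd)
  g$fwhm <- 2 + 3 * g$mu + 0.1 * u[g$subject] + rnorm(nrow(g), 0, 0.5)
  g
}

test_that("mixed model recovers planted hemisphere-specific slopes", {
  set.seed(101)
  hits <- 0L
  for (i in 1:100) {
    tab <- sim_geometry_table()
    res <- suppressWarnings(mixed_effects_geometry(tab, "area"))
    covered <-
      (res$conf.low[res$term == "mu [L]"] <= -100 &
         res$conf.high[res$term == "mu [L]"] >= -100) &&
      (res$conf.low[res$term == "mu [R]"] <= -70 &
         res$conf.high[res$term == "mu [R]"] >= -70)
    hits <- hits + covered
  }
  expect_gte(hits, 90)
})

test_that("with no between-subject variance the mixed model matches OLS", {
  set.seed(55)
  tab <- sim_geometry_table(subj_sd = 0)
  res <- suppressWarnings(mixed_effects_geometry(tab, "area"))
  d <- data.frame(y = tab$area, hemi = factor(tab$hemi), mu = tab$mu)
  cf <- coef(stats::lm(y ~ hemi + hemi:mu, data = d))
  expect_equal(res$estimate,
               unname(cf[c("hemiR", "hemiL:mu", "hemiR:mu")]),
               tolerance = 1e-3)
})

test_that("mixed model output is invariant to row order and subject labels", {
  set.seed(77)
  tab <- sim_geometry_table(n_subj = 6)
  r1 <- suppressWarnings(mixed_effects_geometry(tab, "fwhm"))
  tab2 <- tab[sample(nrow(tab)), ]
  tab2$subject <- paste0("subj_", rev(LETTERS)[tab2$subject])
  r2 <- suppressWarnings(mixed_effects_geometry(tab2, "fwhm"))
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-6)
  expect_equal(r1$z, r2$z, tolerance = 1e-5)
})

test_that("categorical GLM contrast behaves under planted amplitudes", {
  C <- condition_regressors(sched_vis, hrf_default)
  conf <- make_confounds(145, seed = 3)
  cfm <- as.matrix(conf[, setdiff(names(conf), c("run", "volume"))])
  set.seed(42)
  n_vert <- 40
  mk_data <- function(amps) {
    vals <- as.numeric(C %*% amps) +
      matrix(rnorm(145 * n_vert, sd = 0.3), 145)
    tibble::tibble(vertex = rep(seq_len(n_vert), each = 145),
                   run = 1L, volume = rep(1:145, n_vert),
                   value = as.numeric(vals))
  }
  # equal amplitudes for all six conditions: contrast consistent with 0
  flat <- categorical_glm_contrast(mk_data(rep(1, 6)), sched_vis, conf)
  expect_true(all(abs(flat$contrast) < 3 * flat$se))
  # amplitudes (1,1,1,1,1,0): contrast recovers the mean small-number scale
  act <- categorical_glm_contrast(mk_data(c(1, 1, 1, 1, 1, 0)), sched_vis,
                                  conf)
  expect_equal(mean(act$contrast), 1, tolerance = 0.1)
  # betas match a general-purpose least-squares oracle on a one-cycle toy
  toy <- build_run("visual", n_cycles = 1, n_volumes = 40)
  Ct <- condition_regressors(toy, hrf_default)
  set.seed(7)
  y <- as.numeric(Ct %*% c(2, 1, 0.5, 0.2, 0.1, 0)) + rnorm(40, sd = 0.1)
  d1 <- tibble::tibble(vertex = 1L, run = 1L, volume = 1:40, value = y)
  got <- categorical_glm_contrast(d1, toy)
  cf <- coef(stats::lm(y ~ Ct))
  expect_equal(got$contrast,
               sum(c(rep(1 / 5, 5), -1) * cf[-1]), tolerance = 1e-8)
  expect_error(categorical_glm_contrast(d1, toy, weights = c(1, 1)),
               "sum to 0")
  # collinear design rejected with a diagnostic
  bad_conf <- data.frame(dup = as.numeric(Ct[, 1]))
  expect_error(categorical_glm_contrast(d1, toy, bad_conf), "collinear")
})

test_that("group t-test reports both tails and flags zero variance", {
  d <- tidyr::expand_grid(vertex = 1:3, subject = 1:6)
  vals <- c(2.1, 1.8, 2.4, 2.0, 1.7, 2.2)
  d$contrast <- ifelse(d$vertex == 1, 1.5,              # zero variance
                       ifelse(d$vertex == 2, rep(c(-1, 1), 3)[d$subject],
                              vals[d$subject]))
  out <- group_t_test(d)
  expect_true(out$zero_variance[out$vertex == 1])
  expect_true(is.na(out$t_stat[out$vertex == 1]))
  expect_equal(out$t_stat[out$vertex == 2], 0)
  # hand t formula on the printed toy vector
  t_hand <- mean(vals) / (sd(vals) / sqrt(6))
  expect_equal(out$t_stat[out$vertex == 3], t_hand)
  expect_equal(out$p_positive[out$vertex == 3],
               pt(t_hand, 5, lower.tail = FALSE))
  expect_error(group_t_test(d[d$subject == 1, ]), "2 subjects")
})
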