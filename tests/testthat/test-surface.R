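test_that("mesh construction, ASCII round trip and validation", {
  mesh <- make_grid_mesh(4, 3, spacing = 2)
  expect_equal(nrow(mesh$coordinates), 12)
  expect_equal(nrow(mesh$triangles), 12)
  path <- withr::local_tempfile(fileext = ".asc")
  write_surface_ascii(mesh, path)
  back <- read_surface_ascii(path)
  expect_equal(back$coordinates, mesh$coordinates, ignore_attr = TRUE)
  expect_equal(back$triangles, mesh$triangles)
  expect_error(surface_mesh(mesh$coordinates, matrix(c(1, 2, 99), 1)),
               "out of range")
})

test_that("clusters are edge-connected components matching a BFS oracle", {
  mesh <- make_grid_mesh(10, 5)
  # two patches sharing no edge
  sel <- c(1, 2, 11, 25, 35)                  # block vs separated pair
  memb <- connected_clusters(mesh, sel)
  expect_equal(length(unique(memb$cluster[memb$vertex %in% c(1, 2, 11)])), 1)
  expect_true(memb$cluster[memb$vertex == 25] !=
                memb$cluster[memb$vertex == 1])
  # isolated vertex forms a singleton
  single <- connected_clusters(mesh, 50)
  expect_equal(nrow(single), 1)
  expect_equal(connected_clusters(mesh, logical(50)),
               tibble::tibble(vertex = integer(), cluster = integer()))
  # random meshes against the independent breadth-first-search oracle
  set.seed(99)
  for (rep in 1:20) {
    nv <- 500
    co <- matrix(rnorm(nv * 3), ncol = 3)
    tris <- matrix(sample(nv, 600, replace = TRUE), ncol = 3)
    tris <- tris[tris[, 1] != tris[, 2] & tris[, 2] != tris[, 3] &
                   tris[, 1] != tris[, 3], , drop = FALSE]
    m <- surface_mesh(co, tris)
    ids <- sort(sample(nv, 120))
    got <- connected_clusters(m, ids)
    e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(1, 3)])
    e <- e[e[, 1] %in% ids & e[, 2] %in% ids, , drop = FALSE]
    want <- bfs_components(e, ids)
    got_sets <- unname(lapply(split(got$vertex, got$cluster), sort))
    expect_equal(got_sets[order(vapply(got_sets, min, numeric(1)))], want)
    # partition property: disjoint, union equals the selection
    expect_equal(sort(got$vertex), ids)
  }
})

test_that("cluster area sums fully-interior triangles only", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  tri <- rbind(c(1, 2, 3))
  m <- surface_mesh(co, tri)
  expect_equal(cluster_surface_area(m, 1:3), 0.5)    # unit right triangle
  expect_equal(cluster_surface_area(m, 1:2), 0)      # one vertex excluded
  sq <- surface_mesh(co, rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_equal(cluster_surface_area(sq, 1:4), 1.0)
  # halves of a split cluster lose the boundary triangles
  mesh <- make_grid_mesh(6, 6)
  whole <- cluster_surface_area(mesh, 1:36)
  left <- cluster_surface_area(mesh, which(mesh$coordinates[, 1] <= 2))
  right <- cluster_surface_area(mesh, which(mesh$coordinates[, 1] > 2))
  expect_lte(left + right, whole)
  # vertex area shares sum to the total surface
  expect_equal(sum(vertex_areas(mesh)), whole)
})

test_that("clusters are assigned to the nearest reference center under rules", {
  mesh <- make_grid_mesh(30, 10)               # 29 x 9 mm sheet, z = 0
  centers <- tibble::tibble(map = c("NPO", "NPC1"),
                            x = c(0, 40), y = c(5, 5), z = c(0, 0))
  memb <- connected_clusters(mesh, seq_len(300))
  big <- assign_maps(memb, mesh, centers, a_min = 50, d_max = 25)
  expect_equal(big$map, "NPO")                 # nearest eligible center
  # a small cluster fails the area rule
  small <- connected_clusters(mesh, c(1, 2))
  expect_equal(assign_maps(small, mesh, centers, a_min = 50,
                           d_max = 25)$map, "unassigned")
  # too far from every center
  far <- tibble::tibble(map = "NF", x = 500, y = 0, z = 0)
  expect_equal(assign_maps(memb, mesh, far, a_min = 50, d_max = 25)$map,
               "unassigned")
  # equidistant centers: deterministic tie-break to the earlier table row
  tie <- tibble::tibble(map = c("A", "B"), x = c(-5, 34), y = c(4.5, 4.5),
                        z = c(0, 0))
  expect_equal(assign_maps(memb, mesh, tie, a_min = 1, d_max = 25)$map, "A")
  expect_warning(out <- assign_maps(memb, mesh, NULL), "skipped")
  expect_true(is.na(out$map))
})

test_that("preferred numerosity bins are half-open with a closed top edge", {
  b <- bin_preferred_numerosity(c(1.25, 1.5, 5.0, 1.0, 4.99))
  expect_equal(as.integer(b), c(1L, 2L, 8L, 1L, 8L))
  expect_equal(attr(b, "centers"),
               c(1.25, 1.75, 2.25, 2.75, 3.25, 3.75, 4.25, 4.75))
  expect_length(attr(b, "centers"), 8)
  expect_error(bin_preferred_numerosity(0.9), "outside")
})

test_that("binned geometry correlations recover exact linear relationships", {
  centers <- c(1.25, 1.75, 2.25, 2.75, 3.25, 3.75, 4.25, 4.75)
  d <- tibble::tibble(mu = centers,
                      fwhm = 2 + 3 * centers,       # increasing
                      area = 10 - centers)          # decreasing
  geo <- geometry_correlations(d)
  expect_equal(geo$area_r, -1)
  expect_equal(geo$fwhm_r, 1)
  expect_equal(nrow(geo$bins), 8)
  # hand-coded covariance-formula oracle
  x <- geo$bins$bin_center; y <- geo$bins$area_sum
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(geo$area_r, r_hand, tolerance = 1e-12)
  expect_warning(geometry_correlations(d[1:2, ]), "fewer than 3")
  g <- glance(geo)
  expect_lt(g$area_slope, 0)
  expect_equal(g$fwhm_slope, 3)
})

test_that("the order-5 coordinate model predicts planted topography", {
  set.seed(31)
  n <- 200
  d <- tibble::tibble(x = runif(n, 0, 30), y = runif(n, 0, 20),
                      z = rnorm(n))
  d$mu <- 1 + 4 * (d$x - min(d$x)) / diff(range(d$x))  # noiseless linear
  fit <- coordinate_polynomial_model(d, seed = 1)
  expect_gt(fit$cv_r, 0.99)
  expect_lt(fit$mae, 0.05)
  expect_equal(glance(fit)$order, 5)
  # 1 + 3 * 5 = 16 design columns: 16 vertices are too few, 17 are enough
  expect_error(coordinate_polynomial_model(d[1:16, ], seed = 1),
               "too small")
  expect_s3_class(coordinate_polynomial_model(d[1:17, ], folds = 3,
                                              seed = 1), "nprf_coordfit")
  # invariance to rigid translation of the coordinates
  d2 <- dplyr::mutate(d, x = x + 100, y = y - 55, z = z + 7)
  fit2 <- coordinate_polynomial_model(d2, seed = 1)
  expect_equal(fit2$predictions$mu_pred, fit$predictions$mu_pred,
               tolerance = 1e-8)
  # constant outcome has no defined correlation
  dc <- dplyr::mutate(d, mu = 2)
  expect_true(is.na(coordinate_polynomial_model(dc, seed = 1)$cv_r))
})

test_that("numerosity ranges use the 1.5 IQR whisker convention", {
  r <- numerosity_range(tibble::tibble(map = "NPO", mu = c(1, 2, 3, 4, 5)))
  expect_equal(r$median, 3)
  expect_equal(r$iqr, 2)
  expect_equal(r$n_outliers, 0)
  same <- numerosity_range(tibble::tibble(map = "NaT", mu = rep(2.5, 9)))
  expect_equal(same$iqr, 0)
  expect_equal(same$n_outliers, 0)
  d <- tibble::tibble(map = "NTO", mu = c(rep(2, 10), rep(3, 10),
                                          rep(4, 10), 10))
  out <- numerosity_range(d)
  expect_equal(out$n_outliers, 1)              # 10 > q3 + 1.5 IQR
  expect_equal(out$outliers[[1]], 10)
  expect_equal(out$whisker_high, 4)
})
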