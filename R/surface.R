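#' Cortical surface mesh
#'
#' A minimal triangulated surface: per-vertex coordinates in mm and a
#' triangle index matrix (1-based).
#'
#' @param coordinates Numeric matrix, vertices x 3 (x, y, z in mm).
#' @param triangles Integer matrix, triangles x 3 of vertex indices.
#' @return A `nprf_mesh` (list with `coordinates`, `triangles`).
#' @export
surface_mesh <- function(coordinates, triangles) {
  coordinates <- as.matrix(coordinates)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(coordinates) == 3, ncol(triangles) == 3)
  if (min(triangles) < 1 || max(triangles) > nrow(coordinates))
    stop("triangle indices out of range", call. = FALSE)
  structure(list(coordinates = coordinates, triangles = triangles),
            class = "nprf_mesh")
}

#' @exportS3Method base::print
print.nprf_mesh <- function(x, ...) {
  cat("<nprf_mesh> ", nrow(x$coordinates), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

#' Read / write a surface mesh in plain ASCII format
#'
#' Format: a header line `n_vertices n_triangles`, then one `x y z` line
#' per vertex, then one `i j k` line (1-based indices) per triangle.
#'
#' @param path File path.
#' @param mesh A `nprf_mesh`.
#' @return `read_surface_ascii()` returns a `nprf_mesh`.
#' @export
read_surface_ascii <- function(path) {
  head <- scan(path, integer(), n = 2, quiet = TRUE)
  dat <- scan(path, numeric(), skip = 1, quiet = TRUE)
  nv <- head[1]; nt <- head[2]
  coords <- matrix(dat[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  tris <- matrix(as.integer(dat[3 * nv + seq_len(3 * nt)]), ncol = 3,
                 byrow = TRUE)
  surface_mesh(coords, tris)
}

#' @rdname read_surface_ascii
#' @export
write_surface_ascii <- function(mesh, path) {
  stopifnot(inherits(mesh, "nprf_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(mesh$coordinates), nrow(mesh$triangles)), con)
  utils::write.table(mesh$coordinates, con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(mesh$triangles, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# undirected edge list (2-column matrix) of a mesh
.mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Connected supra-threshold clusters on a mesh
#'
#' Partitions the selected vertices into maximal components connected by
#' mesh edges (edge distance at most 1: vertices must be directly
#' connected to share a cluster). Cluster labels are deterministic:
#' clusters are numbered by their smallest member vertex index.
#'
#' @param mesh A `nprf_mesh`.
#' @param selected Logical mask over vertices, or a vector of vertex ids.
#' @return A tibble `vertex`, `cluster` (empty if nothing is selected).
#' @export
connected_clusters <- function(mesh, selected) {
  stopifnot(inherits(mesh, "nprf_mesh"))
  nv <- nrow(mesh$coordinates)
  ids <- if (is.logical(selected)) {
    stopifnot(length(selected) == nv)
    which(selected)
  } else sort(unique(as.integer(selected)))
  if (length(ids) == 0)
    return(tibble::tibble(vertex = integer(), cluster = integer()))
  e <- .mesh_edges(mesh)
  keep <- e[, 1] %in% ids & e[, 2] %in% ids
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e[keep, 1]),
               to = as.character(e[keep, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)$membership
  vert <- as.integer(names(comp))
  # renumber components by smallest vertex id for determinism
  first <- tapply(vert, comp, min)
  relab <- match(comp, names(sort(first)))
  out <- tibble::tibble(vertex = vert, cluster = as.integer(relab))
  dplyr::arrange(out, .data$cluster, .data$vertex)
}

# areas of all triangles (cross-product formula), vectorized
.triangle_areas <- function(mesh) {
  co <- mesh$coordinates
  tr <- mesh$triangles
  a <- co[tr[, 2], , drop = FALSE] - co[tr[, 1], , drop = FALSE]
  b <- co[tr[, 3], , drop = FALSE] - co[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Cortical surface area of a vertex set
#'
#' Summed area of all mesh triangles whose three nodes all belong to the
#' set; boundary triangles with any node outside contribute nothing.
#'
#' @param mesh A `nprf_mesh`.
#' @param vertices Vertex ids of the cluster.
#' @return Area in mm^2.
#' @export
cluster_surface_area <- function(mesh, vertices) {
  stopifnot(inherits(mesh, "nprf_mesh"))
  tr <- mesh$triangles
  inside <- matrix(tr %in% vertices, ncol = 3)
  sum(.triangle_areas(mesh)[rowSums(inside) == 3L])
}

#' Per-vertex surface area shares
#'
#' Each triangle contributes one third of its area to each of its three
#' vertices -- the standard vertex-area convention, used when summing
#' "area devoted to" a set of vertices binned by preferred numerosity.
#'
#' @param mesh A `nprf_mesh`.
#' @return Numeric vector, one area (mm^2) per vertex.
#' @export
vertex_areas <- function(mesh) {
  ar <- .triangle_areas(mesh) / 3
  out <- numeric(nrow(mesh$coordinates))
  for (j in 1:3) {
    s <- tapply(ar, mesh$triangles[, j], sum)
    out[as.integer(names(s))] <- out[as.integer(names(s))] + s
  }
  out
}

#' Summarize clusters: size, area, center
#'
#' @param mesh A `nprf_mesh`.
#' @param membership Tibble `vertex`, `cluster` from [connected_clusters()].
#' @return A tibble per cluster: `cluster`, `n_vertices`, `area_mm2`,
#'   `cx`, `cy`, `cz` (mean coordinate).
#' @export
cluster_summary <- function(mesh, membership) {
  sp <- split(membership$vertex, membership$cluster)
  tibble::tibble(
    cluster = as.integer(names(sp)),
    n_vertices = unname(lengths(sp)),
    area_mm2 = vapply(sp, function(v) cluster_surface_area(mesh, v),
                      numeric(1), USE.NAMES = FALSE),
    cx = vapply(sp, function(v) mean(mesh$coordinates[v, 1]), numeric(1),
                USE.NAMES = FALSE),
    cy = vapply(sp, function(v) mean(mesh$coordinates[v, 2]), numeric(1),
                USE.NAMES = FALSE),
    cz = vapply(sp, function(v) mean(mesh$coordinates[v, 3]), numeric(1),
                USE.NAMES = FALSE)
  )
}

#' Assign clusters to numerotopic maps
#'
#' A cluster is assigned to a reference map when its surface area exceeds
#' `a_min` and at least one of its vertices lies within `d_max` mm of that
#' map's reported center; among eligible centers the closest one wins
#' (cluster-to-center distance = minimum over cluster vertices). Exact
#' distance ties go to the earlier row of `centers`. Clusters failing the
#' area or distance rule are labelled `"unassigned"`.
#'
#' The default thresholds are the visual-session values (`a_min` 50 mm^2,
#' `d_max` 25 mm); auditory sessions use 25 mm^2 and 50 mm.
#'
#' @param membership Tibble `vertex`, `cluster` from [connected_clusters()],
#'   with vertices indexed into `mesh` (standard space for assignment).
#' @param mesh A `nprf_mesh` supplying vertex coordinates.
#' @param centers Data frame with columns `map`, `x`, `y`, `z`, or `NULL`
#'   to skip assignment with a warning.
#' @param a_min Minimum cluster area in mm^2.
#' @param d_max Maximum center distance in mm.
#' @param areas Optional per-cluster areas (mm^2) overriding areas computed
#'   from `mesh` -- used when areas come from the native-space surface but
#'   assignment happens in standard space.
#' @return The [cluster_summary()] tibble plus `map` and `dist_mm`.
#' @export
assign_maps <- function(membership, mesh, centers, a_min = 50, d_max = 25,
                        areas = NULL) {
  stopifnot(a_min > 0, d_max > 0)
  summ <- cluster_summary(mesh, membership)
  if (!is.null(areas)) summ$area_mm2 <- areas
  if (is.null(centers)) {
    warning("no reference center table supplied: map assignment skipped")
    summ$map <- NA_character_
    summ$dist_mm <- NA_real_
    return(summ)
  }
  stopifnot(all(c("map", "x", "y", "z") %in% names(centers)))
  cm <- as.matrix(centers[, c("x", "y", "z")])
  sp <- split(membership$vertex, membership$cluster)
  dist_to <- t(vapply(sp, function(v) {
    co <- mesh$coordinates[v, , drop = FALSE]
    vapply(seq_len(nrow(cm)), function(ci) {
      sqrt(min(colSums((t(co) - cm[ci, ])^2)))
    }, numeric(1))
  }, numeric(nrow(cm))))
  best <- unname(apply(dist_to, 1, which.min))  # earliest row wins ties
  bestd <- unname(dist_to[cbind(seq_along(best), best)])
  summ$map <- ifelse(summ$area_mm2 >= a_min & bestd <= d_max,
                     as.character(centers$map[best]), "unassigned")
  summ$dist_mm <- bestd
  summ
}

#' Bin preferred numerosities
#'
#' Left-closed, right-open bins of width 0.5 spanning 1 to 5, with the
#' last bin closed at 5: eight bins with centers 1.25, 1.75, ..., 4.75.
#'
#' @param mu Preferred numerosities, all within `[lower, upper]`.
#' @param width Bin width (default 0.5).
#' @param lower,upper Range (defaults 1 and 5).
#' @return Integer bin index per value, with attribute `centers`.
#' @export
bin_preferred_numerosity <- function(mu, width = 0.5, lower = 1, upper = 5) {
  if (any(mu < lower | mu > upper))
    stop("preferred numerosity outside [", lower, ", ", upper,
         "]: filter vertices first", call. = FALSE)
  n_bins <- round((upper - lower) / width)
  b <- pmin(floor((mu - lower) / width) + 1L, n_bins)
  structure(as.integer(b),
            centers = lower + width * (seq_len(n_bins) - 0.5))
}

#' Binned relationships of preferred numerosity with area and tuning width
#'
#' Bins vertices by preferred numerosity, sums the surface area and
#' averages the FWHM per bin, and correlates both against the bin centers
#' (Pearson). Simple linear fits are reported for both, plus a quadratic
#' fit for area.
#'
#' @param data Per-vertex tibble with columns `mu`, `fwhm`, `area`
#'   (typically selected vertices, `area` from [vertex_areas()]).
#' @param width,lower,upper Binning parameters, see
#'   [bin_preferred_numerosity()].
#' @return A `nprf_geometry` list: `bins` (tibble with `bin_center`, `n`,
#'   `area_sum`, `fwhm_mean`, `fwhm_se`), `area_r`, `fwhm_r`, `area_lm`,
#'   `area_quad`, `fwhm_lm`. Correlations are `NA` (with a warning) when
#'   fewer than 3 bins are occupied.
#' @export
geometry_correlations <- function(data, width = 0.5, lower = 1, upper = 5) {
  stopifnot(all(c("mu", "fwhm", "area") %in% names(data)))
  b <- bin_preferred_numerosity(data$mu, width, lower, upper)
  centers <- attr(b, "centers")
  bins <- data |>
    dplyr::mutate(bin = as.integer(b)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      area_sum = sum(.data$area),
      fwhm_mean = mean(.data$fwhm),
      fwhm_se = stats::sd(.data$fwhm) / sqrt(dplyr::n()),
      .groups = "drop") |>
    dplyr::mutate(bin_center = centers[.data$bin]) |>
    dplyr::relocate("bin_center")
  if (nrow(bins) < 3) {
    warning("fewer than 3 occupied bins: correlations undefined")
    area_r <- fwhm_r <- NA_real_
    area_lm <- area_quad <- fwhm_lm <- NULL
  } else {
    area_r <- stats::cor(bins$bin_center, bins$area_sum)
    fwhm_r <- stats::cor(bins$bin_center, bins$fwhm_mean)
    area_lm <- stats::lm(area_sum ~ bin_center, data = bins)
    area_quad <- stats::lm(area_sum ~ bin_center + I(bin_center^2),
                           data = bins)
    fwhm_lm <- stats::lm(fwhm_mean ~ bin_center, data = bins)
  }
  structure(list(bins = bins, area_r = area_r, fwhm_r = fwhm_r,
                 area_lm = area_lm, area_quad = area_quad,
                 fwhm_lm = fwhm_lm),
            class = "nprf_geometry")
}

#' @exportS3Method base::print
print.nprf_geometry <- function(x, ...) {
  cat("<nprf_geometry> ", nrow(x$bins), " occupied bins\n", sep = "")
  cat("  area  ~ preferred numerosity: r =", format(x$area_r, digits = 3), "\n")
  cat("  FWHM  ~ preferred numerosity: r =", format(x$fwhm_r, digits = 3), "\n")
  invisible(x)
}

#' Polynomial coordinate model of preferred numerosity
#'
#' Fits preferred numerosity as a pure-power polynomial of the
#' mean-centered pial coordinates,
#' `mu = b0 + sum_k (bx_k x^k + by_k y^k + bz_k z^k)`, k = 1..order
#' (no cross terms; 1 + 3 * order design columns), estimated with k-fold
#' cross-validation over a seeded random partition of vertices. Reports
#' the Pearson correlation between cross-validated predictions and
#' observed numerosities (cv-r) and the mean absolute error.
#'
#' @param data Tibble with columns `x`, `y`, `z`, `mu` (one row per
#'   cluster vertex). Needs more rows than design columns.
#' @param order Polynomial order (default 5).
#' @param folds Number of CV folds (default 10).
#' @param seed Optional integer seed for the fold partition.
#' @return A `nprf_coordfit` list: `predictions` (tibble with `mu`,
#'   `mu_pred`, `fold`), `cv_r`, `mae`, `order`, `folds`. `cv_r` is `NA`
#'   when `mu` has zero variance.
#' @export
coordinate_polynomial_model <- function(data, order = 5, folds = 10,
                                        seed = NULL) {
  stopifnot(all(c("x", "y", "z", "mu") %in% names(data)))
  n <- nrow(data)
  ncols <- 1 + 3 * order
  if (n <= ncols)
    stop("cluster too small: ", n, " vertices for ", ncols,
         " design columns", call. = FALSE)
  co <- scale(as.matrix(data[, c("x", "y", "z")]), scale = FALSE)
  X <- do.call(cbind, lapply(seq_len(order), function(k) co^k))
  colnames(X) <- paste0(rep(c("x", "y", "z"), order),
                        rep(seq_len(order), each = 3))
  # standardize columns for numerical stability; predictions are invariant
  sds <- apply(X, 2, stats::sd)
  sds[sds < 1e-12] <- 1
  X <- sweep(X, 2, sds, "/")
  X <- cbind(`(intercept)` = 1, X)
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    te <- fold == f
    cf <- stats::lm.fit(X[!te, , drop = FALSE], data$mu[!te])$coefficients
    cf[is.na(cf)] <- 0
    pred[te] <- X[te, , drop = FALSE] %*% cf
  }
  cv_r <- if (stats::sd(data$mu) < 1e-12 || stats::sd(pred) < 1e-12) {
    NA_real_
  } else stats::cor(data$mu, pred)
  structure(list(
    predictions = tibble::tibble(mu = data$mu, mu_pred = pred, fold = fold),
    cv_r = cv_r, mae = mean(abs(data$mu - pred)),
    order = order, folds = folds),
    class = "nprf_coordfit")
}

#' @exportS3Method base::print
print.nprf_coordfit <- function(x, ...) {
  cat("<nprf_coordfit> order-", x$order, " coordinate model, ",
      x$folds, "-fold CV\n", sep = "")
  cat("  cv-r =", format(x$cv_r, digits = 3),
      " MAE =", format(x$mae, digits = 3), "\n")
  invisible(x)
}

#' Represented numerosity range per map
#'
#' Five-number boxplot summaries of preferred numerosity per numerotopic
#' map: median, quartiles (linear-interpolation convention), whiskers at
#' the most extreme points within 1.5 IQR of the box, and outliers beyond.
#'
#' @param data Tibble with columns `map`, `mu`.
#' @return A tibble per map: `map`, `n`, `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high`, `n_outliers`, `outliers` (list).
#' @export
numerosity_range <- function(data) {
  stopifnot(all(c("map", "mu") %in% names(data)))
  one <- function(mu) {
    q1 <- stats::quantile(mu, 0.25, names = FALSE)
    q3 <- stats::quantile(mu, 0.75, names = FALSE)
    iqr <- q3 - q1
    wl <- min(mu[mu >= q1 - 1.5 * iqr])
    wh <- max(mu[mu <= q3 + 1.5 * iqr])
    out <- mu[mu < wl | mu > wh]
    tibble::tibble(n = length(mu), median = stats::median(mu),
                   q1 = q1, q3 = q3, iqr = iqr,
                   whisker_low = wl, whisker_high = wh,
                   n_outliers = length(out), outliers = list(out))
  }
  sp <- split(data$mu, data$map)
  dplyr::bind_cols(tibble::tibble(map = names(sp)),
                   dplyr::bind_rows(lapply(sp, one)))
}
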