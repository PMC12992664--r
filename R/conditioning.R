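#' Convert a run to percent signal change
#'
#' Each value is expressed relative to the run mean:
#' `100 * (value / mean - 1)`. The output has mean zero by construction.
#'
#' @param y Numeric vector, one value per volume.
#' @return Numeric vector in percent-signal-change units.
#' @export
percent_signal_change <- function(y) {
  stopifnot(is.numeric(y), !anyNA(y))
  m <- mean(y)
  if (abs(m) < 1e-12 * max(stats::sd(y), 1e-12) || m == 0)
    stop("degenerate run: mean signal is zero, cannot form percent signal change",
         call. = FALSE)
  100 * (y / m - 1)
}

#' Discrete-cosine drift basis
#'
#' The lowest non-constant terms of a DCT-II basis, the standard high-pass
#' drift model for fMRI runs. Three terms on a ~300 s run capture drifts
#' slower than about 1.5 cycles per run.
#'
#' @param n_volumes Number of volumes.
#' @param n_terms Number of cosine terms (default 3).
#' @return A matrix `n_volumes` x `n_terms` with columns `cosine01`, ...
#' @export
cosine_drift_basis <- function(n_volumes, n_terms = 3) {
  stopifnot(n_volumes > 1, n_terms >= 1)
  i <- seq_len(n_volumes)
  B <- vapply(seq_len(n_terms), function(k) {
    sqrt(2 / n_volumes) * cos(pi * (2 * i - 1) * k / (2 * n_volumes))
  }, numeric(n_volumes))
  colnames(B) <- sprintf("cosine%02d", seq_len(n_terms) - 1L)
  B
}

# design matrix [intercept | confounds] with a rank check that names
# the offending collinear columns
.confound_design <- function(confounds, n) {
  X <- as.matrix(confounds[, !(colnames(confounds) %in% c("run", "volume")),
                           drop = FALSE])
  storage.mode(X) <- "double"
  if (nrow(X) != n)
    stop("confound matrix has ", nrow(X), " rows but the run has ", n,
         " volumes", call. = FALSE)
  X <- cbind(`(intercept)` = 1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("confound design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  qx
}

#' Regress confounds out of a run
#'
#' Ordinary-least-squares residual of the run on an intercept plus the
#' confound columns. The residual keeps zero mean (the intercept is
#' removed, not added back); the pRF baseline parameter absorbs offsets.
#'
#' @param y Numeric vector, one value per volume.
#' @param confounds Data frame or matrix of confound regressors (columns
#'   named `run`/`volume` are ignored). Must be full column rank together
#'   with the intercept.
#' @return Residual vector, orthogonal to every confound column.
#' @export
regress_confounds <- function(y, confounds) {
  stopifnot(is.numeric(y), !anyNA(y))
  qx <- .confound_design(confounds, length(y))
  as.numeric(qr.resid(qx, y))
}

#' Condition vertex time series: percent signal change and confound removal
#'
#' Applies the standardization pipeline run by run: each (vertex, run)
#' series is converted to percent signal change, then the confound
#' regressors are removed by OLS. The pipeline order (PSC, then confound
#' regression, then any averaging) is fixed.
#'
#' @param data Long tibble with columns `vertex`, `run`, `volume`, `value`;
#'   complete (every vertex observed at every volume of every run).
#' @param confounds `NULL` (skip), a single data frame applied to every
#'   run, or a data frame with a `run` column holding per-run regressors.
#' @param psc Convert to percent signal change first (default `TRUE`;
#'   set `FALSE` if the input is already in PSC units).
#' @return The input tibble with `value` replaced by the conditioned
#'   signal, ordered by (run, vertex, volume).
#' @export
condition_timeseries <- function(data, confounds = NULL, psc = TRUE) {
  cube <- .as_run_cube(data)
  out <- lapply(seq_along(cube$runs), function(ri) {
    Y <- cube$mats[[ri]]
    if (psc) {
      m <- colMeans(Y)
      if (any(abs(m) < 1e-12))
        stop("degenerate run: zero-mean vertex series in run ",
             cube$runs[ri], call. = FALSE)
      Y <- 100 * sweep(Y, 2, m, "/") - 100
    }
    if (!is.null(confounds)) {
      cf <- confounds
      if (!is.null(cf$run)) cf <- cf[cf$run == cube$runs[ri], , drop = FALSE]
      qx <- .confound_design(cf, nrow(Y))
      Y <- qr.resid(qx, Y)
    }
    Y
  })
  tibble::tibble(
    vertex = rep(rep(cube$vertices, each = cube$n_volumes), length(cube$runs)),
    run = rep(cube$runs, each = cube$n_volumes * length(cube$vertices)),
    volume = rep(seq_len(cube$n_volumes),
                 length(cube$vertices) * length(cube$runs)),
    value = as.numeric(do.call(cbind, out))
  )[, c("vertex", "run", "volume", "value")]
}

#' Average runs pointwise
#'
#' Pointwise mean of the selected runs, per vertex and volume. Signals are
#' averaged across runs but not across stimulation cycles.
#'
#' @param data Long tibble with columns `vertex`, `run`, `volume`, `value`.
#' @param runs Run identifiers to average; `NULL` (default) averages all.
#' @return A tibble `vertex`, `volume`, `value`.
#' @export
average_runs <- function(data, runs = NULL) {
  cube <- .as_run_cube(data)
  sel <- if (is.null(runs)) seq_along(cube$runs) else match(runs, cube$runs)
  if (length(sel) == 0 || anyNA(sel))
    stop("requested runs not present in the data", call. = FALSE)
  Y <- Reduce(`+`, cube$mats[sel]) / length(sel)
  tibble::tibble(
    vertex = rep(cube$vertices, each = cube$n_volumes),
    volume = rep(seq_len(cube$n_volumes), length(cube$vertices)),
    value = as.numeric(Y)
  )
}

# internal: long (vertex, run, volume, value) -> per-run matrices
# [volume x vertex], with completeness checks
.as_run_cube <- function(data) {
  need <- c("vertex", "run", "volume", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns vertex, run, volume, value", call. = FALSE)
  if (anyNA(data$value)) stop("missing values in time series", call. = FALSE)
  runs <- sort(unique(data$run))
  vertices <- sort(unique(data$vertex))
  vols <- sort(unique(data$volume))
  nv <- length(vols)
  if (nrow(data) != nv * length(vertices) * length(runs))
    stop("time series are incomplete or of unequal length across runs",
         call. = FALSE)
  o <- order(match(data$run, runs), match(data$vertex, vertices), data$volume)
  vals <- data$value[o]
  mats <- lapply(seq_along(runs), function(ri) {
    matrix(vals[((ri - 1) * nv * length(vertices) + 1):(ri * nv * length(vertices))],
           nrow = nv, ncol = length(vertices))
  })
  list(mats = mats, runs = runs, vertices = vertices, n_volumes = nv)
}

# internal: averaged-run matrix [volume x vertex] over a run subset
.average_matrix <- function(cube, sel) {
  Reduce(`+`, cube$mats[sel]) / length(sel)
}

#' Synthetic confound regressors
#'
#' Generates an fMRIPrep-style 12-column confound table for testing: six
#' slow random-walk motion parameters, white-matter / CSF / global-signal
#' nuisance series, and the three lowest cosine drift terms.
#'
#' @param n_volumes Number of volumes.
#' @param n_runs Number of runs; the output has a `run` column.
#' @param seed Optional integer seed.
#' @return A tibble with columns `run`, `volume` and 12 named regressors.
#' @export
make_confounds <- function(n_volumes = 145, n_runs = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dct <- cosine_drift_basis(n_volumes, 3)
  one <- function(r) {
    motion <- vapply(1:6, function(i) cumsum(stats::rnorm(n_volumes, 0, 0.02)),
                     numeric(n_volumes))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    tiss <- vapply(1:3, function(i) {
      as.numeric(stats::filter(stats::rnorm(n_volumes), 0.7,
                               method = "recursive"))
    }, numeric(n_volumes))
    colnames(tiss) <- c("white_matter", "csf", "global_signal")
    tibble::as_tibble(cbind(run = r, volume = seq_len(n_volumes),
                            motion, tiss, dct))
  }
  dplyr::bind_rows(lapply(seq_len(n_runs), one))
}

#' Read an fMRIPrep-style confounds TSV
#'
#' @param path TSV file with named confound columns.
#' @param columns Columns to keep; defaults to the 12-regressor set
#'   (six motion parameters, white matter, CSF, global signal, three
#'   cosine drift terms).
#' @return A tibble of the selected columns.
#' @export
read_confounds_tsv <- function(path,
                               columns = c("trans_x", "trans_y", "trans_z",
                                           "rot_x", "rot_y", "rot_z",
                                           "white_matter", "csf",
                                           "global_signal", "cosine00",
                                           "cosine01", "cosine02")) {
  tab <- utils::read.delim(path, sep = "\t", na.strings = c("NA", "n/a"))
  miss <- setdiff(columns, names(tab))
  if (length(miss))
    stop("confounds file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tibble::as_tibble(tab[, columns, drop = FALSE])
}
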