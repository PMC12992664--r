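#' Build one stimulation cycle of the numerosity block design
#'
#' One cycle presents numerosities 1--5 in ascending order, a block of
#' twenty items, the numerosities in descending order, and a second block
#' of twenty items: 1-2-3-4-5-20-5-4-3-2-1-20. Small-numerosity blocks
#' contain six stimulus events; visual events show a dot array for 300 ms
#' followed by 400 ms of background, auditory events play a tone sequence
#' for 500 ms followed by 200 ms of silence, so every small block lasts
#' 4.2 s. Twenty-item baseline blocks last 16.8 s (24 events visual,
#' 8 events auditory).
#'
#' @param modality `"visual"` or `"auditory"`.
#' @return A tibble with one row per block: `numerosity`, `onset` (seconds
#'   from cycle start), `duration`, `n_events`, `event_on`, `event_off`.
#' @examples
#' build_cycle("visual")
#' sum(build_cycle("auditory")$duration) # 75.6 s
#' @export
build_cycle <- function(modality = c("visual", "auditory")) {
  modality <- match.arg(modality)
  order <- c(1, 2, 3, 4, 5, 20, 5, 4, 3, 2, 1, 20)
  if (modality == "visual") {
    on_small <- 0.3; off_small <- 0.4
    n_twenty <- 24L; on_twenty <- 0.3; off_twenty <- 0.4
  } else {
    on_small <- 0.5; off_small <- 0.2
    # eight repetitions of a twenty-tone sequence fill the 16.8 s baseline;
    # each repetition occupies 2.1 s (2.0 s of tones, 0.1 s gap)
    n_twenty <- 8L; on_twenty <- 2.0; off_twenty <- 0.1
  }
  blocks <- tibble::tibble(
    numerosity = order,
    n_events   = ifelse(order == 20, n_twenty, 6L),
    event_on   = ifelse(order == 20, on_twenty, on_small),
    event_off  = ifelse(order == 20, off_twenty, off_small)
  )
  blocks$duration <- round(blocks$n_events * (blocks$event_on + blocks$event_off), 10)
  blocks$onset <- round(cumsum(c(0, blocks$duration[-nrow(blocks)])), 10)
  blocks[, c("numerosity", "onset", "duration", "n_events", "event_on", "event_off")]
}

#' Build a full run of the numerosity block design
#'
#' Concatenates `n_cycles` stimulation cycles contiguously from t = 0.
#' Any remaining acquisition time after the last block is stimulus-free
#' padding. The default parameters reproduce the mapping protocol: four
#' cycles of 75.6 s each within 145 volumes at TR 2.1 s (304.5 s).
#'
#' @param modality `"visual"` or `"auditory"`.
#' @param n_cycles Number of stimulation cycles (default 4).
#' @param tr Repetition time in seconds (default 2.1).
#' @param n_volumes Number of acquired volumes per run (default 145).
#' @param slice_time_ref Reference time (s) within each TR to which volumes
#'   are slice-time aligned (default 1.025).
#' @return A `nprf_schedule`: a block tibble (as [build_cycle()]) with
#'   attributes `modality`, `tr`, `n_volumes`, `n_cycles`, `slice_time_ref`.
#' @examples
#' sched <- build_run("visual")
#' attr(sched, "n_volumes") * attr(sched, "tr") # 304.5 s
#' @export
build_run <- function(modality = c("visual", "auditory"), n_cycles = 4L,
                      tr = 2.1, n_volumes = 145L, slice_time_ref = 1.025) {
  modality <- match.arg(modality)
  stopifnot(n_cycles >= 1, tr > 0, n_volumes >= 1)
  cycle <- build_cycle(modality)
  cycle_dur <- sum(cycle$duration)
  if (n_volumes * tr < n_cycles * cycle_dur - 1e-9) {
    stop("run too short: ", n_cycles, " cycles need ",
         n_cycles * cycle_dur, " s but ", n_volumes, " volumes at TR ",
         tr, " s span only ", n_volumes * tr, " s", call. = FALSE)
  }
  blocks <- dplyr::bind_rows(lapply(seq_len(n_cycles) - 1L, function(k) {
    b <- cycle
    b$onset <- b$onset + k * cycle_dur
    b
  }))
  structure(blocks,
            modality = modality, tr = tr, n_volumes = as.integer(n_volumes),
            n_cycles = as.integer(n_cycles), slice_time_ref = slice_time_ref,
            class = c("nprf_schedule", class(tibble::tibble())))
}

#' Numerosity-versus-time function on a fine time grid
#'
#' Samples the presented numerosity x(t) on a regular microtime grid.
#' In block-level mode (default) the value equals the block numerosity
#' throughout each block; sub-second event gaps are ignored, since BOLD
#' cannot resolve them. In event-level mode the value is set only during
#' the `event_on` window of each stimulus event. Times with no scheduled
#' stimulus (gaps, run-end padding) are `NA`.
#'
#' @param schedule A `nprf_schedule` from [build_run()].
#' @param dt Grid step in seconds; must divide the TR evenly.
#' @param event_level Resolve individual stimulus events (default `FALSE`).
#' @return A tibble `time`, `numerosity` (NA where no stimulus), with
#'   attribute `dt`; one row per grid point covering the full run.
#' @export
numerosity_timecourse <- function(schedule, dt = 0.1, event_level = FALSE) {
  stopifnot(inherits(schedule, "nprf_schedule"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a positive scalar", call. = FALSE)
  tr <- attr(schedule, "tr")
  if (abs(tr / dt - round(tr / dt)) > 1e-8)
    stop("dt = ", dt, " does not divide the TR (", tr, " s) evenly",
         call. = FALSE)
  run_dur <- attr(schedule, "n_volumes") * tr
  n <- ceiling(run_dur / dt - 1e-9)
  tgrid <- (seq_len(n) - 1) * dt
  val <- rep(NA_real_, n)
  b <- findInterval(tgrid + 1e-9, schedule$onset)
  inb <- b > 0
  inb[inb] <- tgrid[inb] < schedule$onset[b[inb]] + schedule$duration[b[inb]] - 1e-9
  if (!event_level) {
    val[inb] <- schedule$numerosity[b[inb]]
  } else {
    bi <- b[inb]
    tt <- tgrid[inb] - schedule$onset[bi]
    period <- schedule$event_on[bi] + schedule$event_off[bi]
    pos <- tt - floor((tt + 1e-6) / period) * period  # wrap float drift
    on <- pos < schedule$event_on[bi] - 1e-6
    idx <- which(inb)[on]
    val[idx] <- schedule$numerosity[b[idx]]
  }
  structure(tibble::tibble(time = tgrid, numerosity = val),
            dt = dt, class = c("nprf_timecourse", class(tibble::tibble())))
}

#' Export a schedule as a BIDS-style events table
#'
#' @param schedule A `nprf_schedule`.
#' @return A tibble with columns `onset`, `duration`, `numerosity`.
#' @export
schedule_events <- function(schedule) {
  stopifnot(inherits(schedule, "nprf_schedule"))
  tibble::tibble(onset = schedule$onset, duration = schedule$duration,
                 numerosity = schedule$numerosity)
}

#' Write / read a schedule events table as TSV
#'
#' `write_events_tsv()` writes the three-column (onset, duration,
#' numerosity) events table; `read_events_tsv()` reads one back.
#'
#' @param schedule A `nprf_schedule`.
#' @param path File path.
#' @return `read_events_tsv()` returns the events tibble.
#' @export
write_events_tsv <- function(schedule, path) {
  utils::write.table(schedule_events(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t"))
}
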