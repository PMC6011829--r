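#' Classify bound frames from an RMSD series
#'
#' A frame is bound when its guest RMSD (after host superposition) is
#' strictly below the threshold; 5 Angstrom separates the bound cluster from
#' excursions out of the cavity.
#'
#' @param rmsd_series Numeric RMSD vector (Angstrom), or the tibble returned
#'   by [guest_rmsd()].
#' @param threshold Bound-state RMSD cutoff, Angstrom (strict `<`).
#' @param frame_interval Time between frames, ps (taken from the tibble
#'   attribute-free default 20 when a bare vector is given).
#' @return A list of class `residence_series` with logical `bound` flags and
#'   `frame_interval` (ps).
#' @export
classify_bound <- function(rmsd_series, threshold = 5, frame_interval = 20) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (is.data.frame(rmsd_series)) {
    if (!"rmsd" %in% names(rmsd_series)) {
      stop("data frame input needs an `rmsd` column", call. = FALSE)
    }
    if ("time_ps" %in% names(rmsd_series) && nrow(rmsd_series) > 1L) {
      frame_interval <- rmsd_series$time_ps[2] - rmsd_series$time_ps[1]
    }
    rmsd_series <- rmsd_series$rmsd
  }
  residence_series(rmsd_series < threshold, frame_interval)
}

#' Construct a residence series from bound flags
#' @param bound Logical per-frame bound flags.
#' @param frame_interval Time between frames, ps.
#' @return A list of class `residence_series`.
#' @export
residence_series <- function(bound, frame_interval = 20) {
  bound <- as.logical(bound)
  if (!length(bound) || anyNA(bound)) {
    stop("bound flags must be a non-empty logical vector without NA",
         call. = FALSE)
  }
  if (frame_interval <= 0) stop("frame_interval must be > 0 ps", call. = FALSE)
  structure(list(bound = bound, frame_interval = as.numeric(frame_interval)),
            class = "residence_series")
}

#' Occupancy and dwell-time summary of a residence series
#'
#' Occupancy is 100 x bound frames / total frames.  Dwell times are the
#' durations of maximal contiguous bound runs, converted to ns with the
#' frame interval; `max_dwell_ns` is 0 when the guest never binds.
#'
#' @param series A [residence_series()] (or output of [classify_bound()]).
#' @return A list of class `residence_summary` with `occupancy_percent`,
#'   `dwell_times_ns`, `max_dwell_ns`, `n_frames`, `n_bound`,
#'   `frame_interval`.
#' @export
residence_summary <- function(series) {
  stopifnot(inherits(series, "residence_series"))
  b <- series$bound
  runs <- rle(b)
  dwell_frames <- runs$lengths[runs$values]
  dwell_ns <- dwell_frames * series$frame_interval / 1000
  structure(list(
    occupancy_percent = 100 * sum(b) / length(b),
    dwell_times_ns = dwell_ns,
    max_dwell_ns = if (length(dwell_ns)) max(dwell_ns) else 0,
    n_frames = length(b),
    n_bound = sum(b),
    frame_interval = series$frame_interval
  ), class = "residence_summary")
}

#' @export
print.residence_summary <- function(x, ...) {
  cat(sprintf(
    "<residence_summary> occupancy %.1f%% (%d/%d frames), max dwell %.2f ns, %d dwells\n",
    x$occupancy_percent, x$n_bound, x$n_frames, x$max_dwell_ns,
    length(x$dwell_times_ns)))
  invisible(x)
}

#' @rdname residence_summary
#' @param x A `residence_summary`.
#' @param ... Unused.
#' @return `glance()`: a one-row tibble with the summary statistics.
#' @export
glance.residence_summary <- function(x, ...) {
  tibble::tibble(
    occupancy_percent = x$occupancy_percent,
    n_frames = x$n_frames,
    n_bound = x$n_bound,
    n_dwells = length(x$dwell_times_ns),
    mean_dwell_ns = if (length(x$dwell_times_ns)) mean(x$dwell_times_ns)
                    else 0,
    max_dwell_ns = x$max_dwell_ns
  )
}

#' @rdname residence_summary
#' @return `tidy()`: one row per dwell with its duration.
#' @export
tidy.residence_summary <- function(x, ...) {
  tibble::tibble(dwell = seq_along(x$dwell_times_ns),
                 dwell_ns = x$dwell_times_ns)
}
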