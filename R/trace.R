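#' Binarize an intensity trace into bound intervals
#'
#' Automated surrogate for manual inspection of fluorescence peaks: maximal
#' runs of frames with intensity above `threshold`, with dark gaps of at
#' most `gap_merge` frames bridged, are mapped to time intervals through
#' the frame schedule. A run of frames `i..j` becomes the half-open
#' interval `[i * interval, (j + 1) * interval)`: the temporal resolution
#' is one frame interval, so a run of k present frames has duration
#' `k * interval` seconds.
#'
#' @param trace Either the data frame returned by [frame_sample()] or a
#'   numeric vector of per-frame intensities (frame 0 first).
#' @param schedule A [frame_schedule()].
#' @param threshold Detection threshold; frames with intensity strictly
#'   above it are "present". Default 0.5, the midpoint of the background
#'   and single-fluorophore levels on the package's unit intensity scale.
#' @param gap_merge Number of consecutive dark frames to bridge (default 0;
#'   exposed because published records do not state whether single dark
#'   frames inside an event were merged during manual inspection).
#' @return Data frame of intervals with columns `start_s`, `end_s`.
#' @examples
#' fs <- frame_schedule()
#' x <- numeric(fs$n_frames); x[4:11] <- 1  # frames 3..10 (0-based)
#' binarize_trace(x, fs) # [15, 55)
#' @export
binarize_trace <- function(trace, schedule = frame_schedule(), threshold = 0.5,
                           gap_merge = 0) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (gap_merge < 0) stop("gap_merge must be >= 0")
  intensity <- if (is.data.frame(trace)) trace$intensity else as.numeric(trace)
  if (length(intensity) == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  present <- intensity > threshold
  runs <- .runs_of_true(present)
  if (nrow(runs) == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  if (gap_merge > 0 && nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$first[i] - merged$last[nrow(merged)] - 1
      if (gap <= gap_merge) {
        merged$last[nrow(merged)] <- runs$last[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  data.frame(
    start_s = runs$first * schedule$interval,
    end_s = (runs$last + 1) * schedule$interval
  )
}

# maximal runs of TRUE as 0-based first/last frame indices
.runs_of_true <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(first = starts[keep] - 1L, last = ends[keep] - 1L)
}

#' Extract dwell observations with truncation flags
#'
#' Turns a molecule's bound intervals into dwell observations, flagging
#' events in contact with the record boundaries: an interval touching the
#' record start is `left_truncated` (the event was already in progress) and
#' one touching the record end is `right_truncated` (still in progress).
#' Truncated dwells are excluded from density fitting, which normalizes on
#' the observable window and therefore models completed dwells only.
#'
#' @param intervals Data frame with columns `start_s`, `end_s` (sorted,
#'   disjoint), and optionally `molecule_id` and `channel`.
#' @param schedule A [frame_schedule()] or record length in seconds.
#' @return Data frame of dwell observations: `molecule_id`, `channel`,
#'   `start_s`, `duration_s`, `left_truncated`, `right_truncated`.
#' @export
extract_dwells <- function(intervals, schedule = frame_schedule()) {
  record_length <- if (inherits(schedule, "frame_schedule")) schedule$record_length else as.numeric(schedule)
  n <- nrow(intervals)
  if (n > 0 && (any(intervals$start_s < 0) || any(intervals$end_s > record_length))) {
    stop("interval outside record window")
  }
  if (n > 1 && any(diff(intervals$start_s) < 0)) stop("intervals must be sorted")
  data.frame(
    molecule_id = if ("molecule_id" %in% names(intervals)) intervals$molecule_id else rep(NA_integer_, n),
    channel = if ("channel" %in% names(intervals)) intervals$channel else rep(NA_character_, n),
    start_s = intervals$start_s,
    duration_s = intervals$end_s - intervals$start_s,
    left_truncated = intervals$start_s <= 0,
    right_truncated = intervals$end_s >= record_length,
    stringsAsFactors = FALSE
  )
}

# durations usable for fitting: completed dwells only
.fit_durations <- function(dwells) {
  if (is.data.frame(dwells)) {
    keep <- !(dwells$left_truncated | dwells$right_truncated)
    dwells$duration_s[keep]
  } else {
    as.numeric(dwells)
  }
}

#' Count discrete fluorophore appearance levels in a trace
#'
#' Estimates how many fluorophores were simultaneously present at the peak
#' of a trace by quantizing positive intensities against the
#' single-fluorophore level. The unit level is estimated as the median of
#' positive intensities within 50% of the smallest positive plateau, so
#' traces that step 0 -> 1 -> 2 units are read as two occupancies; this is
#' the check that recordings recruit only a single U1 and a single BBP
#' molecule at a time.
#'
#' @param intensity Numeric vector of per-frame intensities.
#' @param threshold Frames above this are considered occupied (default 0.5).
#' @return Integer: maximum number of simultaneous appearance levels
#'   (0 for an all-dark trace).
#' @examples
#' count_steps(c(0, 1, 0, 1, 1, 0))       # 1
#' count_steps(c(0, 1, 2, 2, 1, 0))       # 2
#' @export
count_steps <- function(intensity, threshold = 0.5) {
  if (length(intensity) == 0) stop("series must be non-empty")
  pos <- intensity[intensity > threshold]
  if (length(pos) == 0) return(0L)
  unit <- stats::median(pos[pos <= min(pos) * 1.5])
  as.integer(max(round(pos / unit)))
}
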