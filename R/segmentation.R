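# Route-event segmentation: maps event positions (fractions of the route)
# onto half-open time intervals. Two schemes are used downstream: a
# 4-segment smooth/unexpected partition for the EEG indices, and three
# equal-length event windows (smooth / deer / kid) for movement and blinks.

#' Ride layout
#'
#' Geometry of one ride: total duration and the positions of the two
#' unexpected obstacles (a deer dummy at about 50% of the route and a
#' child-shaped pedestrian dummy at about 90%), plus the anticipation
#' window placed before each encounter.
#'
#' @param total_duration ride length in seconds.
#' @param deer_frac position of the deer encounter as a fraction of the
#'   route (default 0.5).
#' @param kid_frac position of the pedestrian encounter (default 0.9).
#' @param pre_window seconds included before each encounter (default 5,
#'   i.e. 1000 samples at the 200 Hz EEG rate — roughly when the dummy
#'   enters the visual field).
#' @return object of class `ride_layout`.
#' @export
ride_layout <- function(total_duration, deer_frac = 0.5, kid_frac = 0.9,
                        pre_window = 5) {
  stopifnot(total_duration > 0, deer_frac > 0, deer_frac < kid_frac,
            kid_frac < 1, pre_window >= 0)
  if (pre_window >= (kid_frac - deer_frac) * total_duration)
    stop("pre_window too long: anticipation windows would overlap events")
  structure(list(total_duration = total_duration, deer_frac = deer_frac,
                 kid_frac = kid_frac, pre_window = pre_window),
            class = "ride_layout")
}

#' Four-segment EEG partition of the ride
#'
#' Segment 1 runs from ride start to `pre_window` seconds before the deer;
#' segment 2 from there to 60% of the ride; segment 3 from 60% to
#' `pre_window` seconds before the pedestrian; segment 4 from there to the
#' end. Segments 1 and 3 are labelled "smooth", 2 and 4 "unexpected".
#' Intervals are half-open \[start, end); they partition \[0, T) exactly.
#'
#' @param layout a [ride_layout()].
#' @return data.frame with columns segment, start, end, label.
#' @export
eeg_segments <- function(layout) {
  stopifnot(inherits(layout, "ride_layout"))
  T <- layout$total_duration
  d <- layout$deer_frac * T
  k <- layout$kid_frac * T
  w <- layout$pre_window
  b <- c(0, d - w, 0.6 * T, k - w, T)
  if (any(diff(b) <= 0)) stop("degenerate layout: a segment collapsed")
  data.frame(segment = 1:4, start = b[1:4], end = b[2:5],
             label = c("smooth", "unexpected", "smooth", "unexpected"))
}

#' Three equal-length event windows
#'
#' Windows used for the movement and blink measures: "deer" and "kid"
#' windows start `pre_window` seconds before the respective encounter; the
#' "smooth" window is the interval of the same length immediately preceding
#' the deer window, which keeps it inside the uneventful first stretch while
#' maximising separation from both encounters. The window length is a
#' required parameter, not a default.
#'
#' @param layout a [ride_layout()].
#' @param window_length window length in seconds.
#' @return data.frame with columns event, start, end.
#' @export
event_windows <- function(layout, window_length) {
  stopifnot(inherits(layout, "ride_layout"), window_length > 0)
  T <- layout$total_duration
  d <- layout$deer_frac * T
  k <- layout$kid_frac * T
  w <- layout$pre_window
  deer <- c(d - w, d - w + window_length)
  kid  <- c(k - w, k - w + window_length)
  smooth <- c(d - w - window_length, d - w)
  win <- data.frame(event = c("smooth", "deer", "kid"),
                    start = c(smooth[1], deer[1], kid[1]),
                    end   = c(smooth[2], deer[2], kid[2]))
  if (smooth[1] < 0 || deer[2] > kid[1] || kid[2] > T)
    stop("window_length too long: event windows overlap or leave the ride")
  win
}

#' Assign time points to labelled intervals
#'
#' @param t numeric vector of times (seconds).
#' @param intervals data.frame with `start`, `end` and a label column.
#' @param label name of the label column (default the second non-time col).
#' @return character vector: interval label per time point, NA outside.
#' @export
assign_interval <- function(t, intervals, label = NULL) {
  if (is.null(label))
    label <- setdiff(names(intervals), c("start", "end"))[1]
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(intervals))) {
    hit <- t >= intervals$start[i] & t < intervals$end[i]
    out[hit] <- as.character(intervals[[label]][i])
  }
  out
}
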