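#' A stylus trace
#'
#' Raw reproduction samples from the graphics tablet: time, x, y.
#'
#' @param t sample times, s, strictly increasing.
#' @param x,y stylus position, cm.
#' @param sample_rate nominal tablet rate, Hz (informational).
#' @return a data frame of class `stylus_trace`.
#' @export
stylus_trace <- function(t, x, y, sample_rate = NULL) {
  if (length(t) < 2L) stop_input("a stylus trace needs >= 2 samples")
  if (any(diff(t) <= 0)) stop_input("trace times must be strictly increasing")
  if (length(x) != length(t) || length(y) != length(t))
    stop_input("t, x, y must have equal length")
  tr <- data.frame(t = t, x = x, y = y)
  attr(tr, "sample_rate") <- sample_rate
  class(tr) <- c("stylus_trace", "data.frame")
  tr
}

#' Read / write a stylus trace as CSV
#'
#' Plain CSV with header `t,x,y` (seconds, cm).
#' @param path file path.
#' @param trace a `stylus_trace` (for writing).
#' @return `read_trace_csv` returns a `stylus_trace`.
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  stylus_trace(d$t, d$x, d$y)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(t = trace$t, x = trace$x, y = trace$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' Segmentation parameters for stylus reproductions
#'
#' Thresholds for the two cut criteria: a pause (speed below
#' `pause_speed_threshold` sustained for at least `pause_min_duration`)
#' or an abrupt direction change (smoothed heading turning by at least
#' `turn_angle_threshold`).  Defaults are set relative to the 2 cm/s
#' nominal stimulus speed and the 0.40 s inter-segment pause: a pause is
#' flagged below one fifth of the nominal speed held for 0.15 s, and
#' fragments shorter than `min_segment_length` (0.2 cm, one fifth of a
#' stimulus segment) are merged into their temporally nearer neighbor.
#'
#' @param pause_speed_threshold cm/s.
#' @param pause_min_duration s.
#' @param turn_angle_threshold degrees (< 180).
#' @param min_segment_length cm.
#' @param heading_window samples in the moving window used to smooth
#'   headings before turn detection.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(pause_speed_threshold = 0.4,
                                pause_min_duration = 0.15,
                                turn_angle_threshold = 35,
                                min_segment_length = 0.2,
                                heading_window = 5L) {
  vals <- c(pause_speed_threshold, pause_min_duration,
            turn_angle_threshold, min_segment_length)
  if (any(vals <= 0)) stop_input("all segmentation thresholds must be > 0")
  if (turn_angle_threshold >= 180)
    stop_input("turn_angle_threshold must be < 180")
  structure(list(pause_speed_threshold = pause_speed_threshold,
                 pause_min_duration = pause_min_duration,
                 turn_angle_threshold = turn_angle_threshold,
                 min_segment_length = min_segment_length,
                 heading_window = as.integer(heading_window)),
            class = "segmentation_params")
}

#' Direction of a stroke from its endpoints
#'
#' The direction of each reproduced segment is estimated by the line
#' through its beginning and end points, i.e. the vector from the first
#' to the last sample, respecting travel order.  A total-least-squares
#' alternative (principal axis of all points, oriented by the endpoint
#' vector) is available behind `method = "tls"` but is not the default.
#'
#' @param points two-column matrix or data frame of (x, y), in travel
#'   order; at least two rows, with distinct first and last points.
#' @param method "endpoint" (default) or "tls".
#' @return direction in degrees, counter-clockwise from +x, in [0, 360).
#' @export
fit_segment_direction <- function(points, method = c("endpoint", "tls")) {
  method <- match.arg(method)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 2L) stop_input("need >= 2 points")
  d <- pts[nrow(pts), ] - pts[1L, ]
  if (all(abs(d) < 1e-12))
    stop_input("degenerate segment: coincident endpoints")
  if (method == "endpoint")
    return(wrap360(atan2(d[2], d[1]) * 180 / pi))
  ctr <- sweep(pts, 2L, colMeans(pts))
  ev <- eigen(crossprod(ctr), symmetric = TRUE)$vectors[, 1L]
  if (sum(ev * d) < 0) ev <- -ev   # orient along travel
  wrap360(atan2(ev[2], ev[1]) * 180 / pi)
}

# Instantaneous speed (cm/s) and heading (deg) per inter-sample interval.
trace_kinematics <- function(trace) {
  dt <- diff(trace$t)
  dx <- diff(trace$x)
  dy <- diff(trace$y)
  list(speed = sqrt(dx^2 + dy^2) / dt,
       heading = wrap360(atan2(dy, dx) * 180 / pi),
       dx = dx, dy = dy, dt = dt)
}

# Circular moving-average of headings over a window of k intervals.
smooth_heading <- function(dx, dy, k) {
  n <- length(dx)
  if (n == 0L) return(numeric(0))
  k <- max(1L, min(k, n))
  kern <- rep(1, k)
  sx <- stats::filter(dx, kern, sides = 2)
  sy <- stats::filter(dy, kern, sides = 2)
  sx[is.na(sx)] <- dx[is.na(sx)]
  sy[is.na(sy)] <- dy[is.na(sy)]
  wrap360(atan2(as.numeric(sy), as.numeric(sx)) * 180 / pi)
}

#' Divide a stylus reproduction into motion segments
#'
#' The first step of the two-step scoring algorithm.  Cut points are
#' placed where the stylus pauses (speed below threshold sustained for
#' the minimum duration) or where the smoothed heading changes by at
#' least the turn threshold; fragments shorter than
#' `min_segment_length` are merged into the temporally nearer neighbor.
#' Each resulting segment's direction is fitted from its endpoints.
#'
#' @param trace a [stylus_trace()].
#' @param params a [segmentation_params()] object.
#' @param expected_segments optional exemplar segment count; when given,
#'   the `valid` flag is TRUE iff the segmentation found exactly that
#'   many segments.
#' @param method direction-fit method, see [fit_segment_direction()].
#' @return an object of class `repro_segmentation`: list with
#'   `segments` (data frame: start_index, end_index, fitted_direction)
#'   and `valid`.
#' @export
segment_trace <- function(trace, params = segmentation_params(),
                          expected_segments = NULL,
                          method = c("endpoint", "tls")) {
  method <- match.arg(method)
  if (!inherits(trace, "stylus_trace"))
    trace <- stylus_trace(trace$t, trace$x, trace$y)
  kin <- trace_kinematics(trace)
  n_int <- length(kin$speed)      # intervals; samples = n_int + 1

  # --- pause detection: runs of sub-threshold speed lasting long enough
  slow <- kin$speed < params$pause_speed_threshold
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pause_runs <- which(r$values)
  is_pause <- logical(n_int)
  for (k in pause_runs) {
    dur <- trace$t[ends[k] + 1L] - trace$t[starts[k]]
    if (dur >= params$pause_min_duration)
      is_pause[starts[k]:ends[k]] <- TRUE
  }

  # strokes = maximal runs of moving intervals
  mv <- rle(!is_pause)
  mends <- cumsum(mv$lengths)
  mstarts <- mends - mv$lengths + 1L
  strokes <- cbind(mstarts[mv$values], mends[mv$values])
  if (nrow(strokes) == 0L)
    stop_input("no movement detected in trace")

  # --- turn detection within each stroke: cut where the smoothed
  # heading departs from the running anchor by >= the turn threshold
  segs <- list()
  for (s in seq_len(nrow(strokes))) {
    i0 <- strokes[s, 1L]; i1 <- strokes[s, 2L]
    idx <- i0:i1
    h <- smooth_heading(kin$dx[idx], kin$dy[idx], params$heading_window)
    cuts <- integer(0)
    anchor <- h[1L]
    for (i in seq_along(h)) {
      if (angular_error(h[i], anchor) >= params$turn_angle_threshold) {
        cuts <- c(cuts, idx[i])   # new segment starts at this interval
        anchor <- h[i]
      }
    }
    bounds <- c(i0, cuts, i1 + 1L)  # interval-start boundaries
    for (b in seq_len(length(bounds) - 1L))
      segs[[length(segs) + 1L]] <- c(bounds[b], bounds[b + 1L])
  }
  # seg rows are [first interval, one-past-last interval) ->
  # sample range [first, last+1]
  seg_mat <- do.call(rbind, segs)
  seg_df <- data.frame(start_index = seg_mat[, 1L],
                       end_index = seg_mat[, 2L])  # end sample index

  # --- merge fragments shorter than min_segment_length (endpoint chord)
  chord <- function(a, b) sqrt((trace$x[b] - trace$x[a])^2 +
                               (trace$y[b] - trace$y[a])^2)
  repeat {
    if (nrow(seg_df) <= 1L) break
    lens <- mapply(chord, seg_df$start_index, seg_df$end_index)
    short <- which(lens < params$min_segment_length)
    if (length(short) == 0L) break
    i <- short[1L]
    # merge into the temporally nearer neighbor (by gap duration)
    gap_prev <- if (i > 1L)
      trace$t[seg_df$start_index[i]] - trace$t[seg_df$end_index[i - 1L]]
      else Inf
    gap_next <- if (i < nrow(seg_df))
      trace$t[seg_df$start_index[i + 1L]] - trace$t[seg_df$end_index[i]]
      else Inf
    if (gap_prev <= gap_next) {
      seg_df$end_index[i - 1L] <- seg_df$end_index[i]
      seg_df <- seg_df[-i, , drop = FALSE]
    } else {
      seg_df$start_index[i + 1L] <- seg_df$start_index[i]
      seg_df <- seg_df[-i, , drop = FALSE]
    }
  }
  rownames(seg_df) <- NULL

  seg_df$fitted_direction <- vapply(seq_len(nrow(seg_df)), function(i) {
    pts <- cbind(trace$x[seg_df$start_index[i]:seg_df$end_index[i]],
                 trace$y[seg_df$start_index[i]:seg_df$end_index[i]])
    fit_segment_direction(pts, method = method)
  }, numeric(1))

  valid <- if (is.null(expected_segments)) NA
           else nrow(seg_df) == expected_segments
  structure(list(segments = seg_df, valid = valid), class = "repro_segmentation")
}

#' Score a segmented reproduction against its stimulus
#'
#' When the reproduction divides into the same number of segments as the
#' exemplar, segments are matched by position and each is scored by
#' directional error (unsigned angular difference, [angular_error()]).
#' A count mismatch marks the reproduction invalid and yields no errors.
#'
#' @param seg a `repro_segmentation` from [segment_trace()].
#' @param stimulus the exemplar `motion_sequence`.
#' @return list with `valid` (logical) and `errors` (degrees per
#'   segment, or NULL when invalid).
#' @export
score_reproduction <- function(seg, stimulus) {
  stopifnot(inherits(seg, "repro_segmentation"),
            inherits(stimulus, "motion_sequence"))
  n_stim <- length(stimulus$directions)
  if (nrow(seg$segments) != n_stim)
    return(list(valid = FALSE, errors = NULL))
  list(valid = TRUE,
       errors = angular_error(seg$segments$fitted_direction,
                              stimulus$directions))
}

#' Morey within-subject standard errors
#'
#' Error bars for repeated-measures condition means: each subject's mean
#' is removed (and the grand mean restored), the per-condition standard
#' error of the centered values is computed, and the result is inflated
#' by `sqrt(M / (M - 1))` for M conditions to correct the bias of the
#' centering step.
#'
#' @param table numeric matrix, subjects x conditions, complete (no NA).
#' @return named vector of per-condition standard errors.
#' @export
morey_within_subject_se <- function(table) {
  x <- as.matrix(table)
  if (any(is.na(x))) stop_input("table has missing cells; no imputation")
  n <- nrow(x); m <- ncol(x)
  if (n < 2L || m < 2L) stop_input("need >= 2 subjects and >= 2 conditions")
  centered <- x - rowMeans(x) + mean(x)
  se <- apply(centered, 2L, stats::sd) / sqrt(n)
  se * sqrt(m / (m - 1))
}

#' Score a cohort of reproductions into a tidy table
#'
#' Convenience wrapper producing the long score table used by the
#' behavioral analyses: one row per (subject, trial, presentation,
#' segment) with the directional error and validity flag.
#'
#' @param traces nested list: `traces[[subject]][[trial]][[presentation]]`
#'   is a `stylus_trace`.
#' @param stimuli list of `motion_sequence`, one per trial.
#' @param conditions character vector per trial ("Congruent"/"Flip").
#' @param params a [segmentation_params()] object.
#' @return data frame with columns subject, trial, condition,
#'   presentation, segment, error_deg, valid.
#' @export
score_cohort <- function(traces, stimuli, conditions,
                         params = segmentation_params()) {
  rows <- list()
  for (s in seq_along(traces)) {
    for (tr in seq_along(traces[[s]])) {
      stim <- stimuli[[tr]]
      n_seg <- length(stim$directions)
      for (p in seq_along(traces[[s]][[tr]])) {
        seg <- segment_trace(traces[[s]][[tr]][[p]], params,
                             expected_segments = n_seg)
        sc <- score_reproduction(seg, stim)
        err <- if (sc$valid) sc$errors else rep(NA_real_, n_seg)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, trial = tr, condition = conditions[tr],
          presentation = p, segment = seq_len(n_seg),
          error_deg = err, valid = sc$valid)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
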