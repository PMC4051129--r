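#' Parameters of a motion-sequence stimulus
#'
#' A stimulus is a path of `n_segments` connected linear motion segments
#' traversed at constant speed, with a brief pause at every corner.  The
#' defaults describe 1 cm segments (about 1 degree of visual angle)
#' traversed at 2 cm/s with a 0.40 s pause, corner turns between 30 and
#' 150 degrees, and a safety margin of half a segment length between
#' non-adjacent segments.
#'
#' @param n_segments number of linear segments (default 5).
#' @param segment_length segment length, cm (default 1).
#' @param speed disk speed, cm/s (default 2).
#' @param pause pause at each corner, s (default 0.40).
#' @param corner_min,corner_max bounds on the unsigned direction change
#'   at each corner, degrees.  `corner_min == corner_max` is allowed and
#'   forces every turn to that exact angle.
#' @param margin_fraction minimum clearance between non-adjacent
#'   segments, as a fraction of `segment_length`.
#' @param display_halfwidth,display_halfheight half-extents of the
#'   display bounding box, cm; the path starts at its center.
#' @return an object of class `sequence_params`.
#' @export
sequence_params <- function(n_segments = 5L, segment_length = 1, speed = 2,
                            pause = 0.40, corner_min = 30, corner_max = 150,
                            margin_fraction = 0.5,
                            display_halfwidth = 10, display_halfheight = 10) {
  if (n_segments < 1) stop_input("n_segments must be >= 1")
  if (segment_length <= 0) stop_input("segment_length must be > 0")
  if (speed <= 0) stop_input("speed must be > 0")
  if (!(corner_min > 0 && corner_min <= corner_max && corner_max < 180))
    stop_input("need 0 < corner_min <= corner_max < 180")
  if (margin_fraction < 0) stop_input("margin_fraction must be >= 0")
  if (display_halfwidth <= 0 || display_halfheight <= 0)
    stop_input("display half-extents must be > 0")
  structure(list(n_segments = as.integer(n_segments),
                 segment_length = segment_length, speed = speed, pause = pause,
                 corner_min = corner_min, corner_max = corner_max,
                 margin_fraction = margin_fraction,
                 display_halfwidth = display_halfwidth,
                 display_halfheight = display_halfheight),
            class = "sequence_params")
}

#' Duration of one segment traversal
#' @param params a [sequence_params()] object.
#' @return seconds per segment (`segment_length / speed`).
#' @export
segment_duration <- function(params = sequence_params()) {
  params$segment_length / params$speed
}

new_motion_sequence <- function(directions, params, flipped_segment = NULL) {
  structure(list(directions = wrap360(directions),
                 vertices = directions_to_vertices(directions, params),
                 params = params,
                 flipped_segment = flipped_segment),
            class = "motion_sequence")
}

directions_to_vertices <- function(directions, params) {
  n <- length(directions)
  rad <- directions * pi / 180
  v <- matrix(0, n + 1L, 2L)
  v[-1L, ] <- params$segment_length * cbind(cumsum(cos(rad)), cumsum(sin(rad)))
  colnames(v) <- c("x", "y")
  v
}

in_box <- function(v, params) {
  abs(v[, 1]) <= params$display_halfwidth + 1e-12 &
    abs(v[, 2]) <= params$display_halfheight + 1e-12
}

#' Generate a constrained motion sequence
#'
#' Draws a pseudo-random path of connected linear segments by rejection
#' sampling.  The first direction is uniform on [0, 360); every
#' subsequent corner turn has magnitude uniform in
#' `[corner_min, corner_max]` and clockwise or counter-clockwise sign
#' with equal probability.  A candidate segment is rejected when it
#' leaves the display box, intersects a non-adjacent segment, or comes
#' within `margin_fraction * segment_length` of one; after repeated
#' local failures the whole path is restarted.
#'
#' @param rng_seed integer seed; equal seeds give identical sequences.
#' @param params a [sequence_params()] object.
#' @param max_attempts total candidate-segment draws allowed before
#'   giving up with a diagnostic (guards degenerate parameter sets such
#'   as a display box too small to hold a legal path).
#' @return a `motion_sequence`: list with `directions` (degrees,
#'   counter-clockwise from +x), `vertices` ((n+1) x 2 matrix, cm,
#'   starting at the origin), `params`, and `flipped_segment` (NULL for
#'   an intact stimulus).
#' @seealso [validate_sequence()], [apply_flip()]
#' @export
generate_sequence <- function(rng_seed, params = sequence_params(),
                              max_attempts = 10000L) {
  set.seed(as.integer(rng_seed))
  L <- params$segment_length
  margin <- params$margin_fraction * L
  attempts <- 0L
  repeat {
    directions <- numeric(params$n_segments)
    verts <- matrix(0, params$n_segments + 1L, 2L)
    i <- 1L
    restart <- FALSE
    while (i <= params$n_segments) {
      local_try <- 0L
      placed <- FALSE
      while (local_try < 50L) {
        attempts <- attempts + 1L
        local_try <- local_try + 1L
        if (attempts > max_attempts)
          stop_input("generate_sequence: no legal trajectory after ",
                     max_attempts, " candidate segments; ",
                     "check display box and corner/margin parameters")
        if (i == 1L) {
          cand <- stats::runif(1, 0, 360)
        } else {
          mag <- stats::runif(1, params$corner_min, params$corner_max)
          sgn <- if (stats::runif(1) < 0.5) -1 else 1
          cand <- wrap360(directions[i - 1L] + sgn * mag)
        }
        rad <- cand * pi / 180
        vnew <- verts[i, ] + L * c(cos(rad), sin(rad))
        if (!all(in_box(rbind(vnew), params))) next
        ok <- TRUE
        if (i >= 3L) {
          for (j in seq_len(i - 2L)) {  # non-adjacent earlier segments
            d <- segment_distance(verts[i, ], vnew, verts[j, ], verts[j + 1L, ])
            if (d < margin || d == 0) { ok <- FALSE; break }
          }
        }
        if (!ok) next
        directions[i] <- cand
        verts[i + 1L, ] <- vnew
        placed <- TRUE
        break
      }
      if (!placed) { restart <- TRUE; break }
      i <- i + 1L
    }
    if (!restart) break
  }
  new_motion_sequence(directions, params)
}

#' Check a motion sequence against all geometric constraints
#'
#' @param seq a `motion_sequence`.
#' @return a data frame of violations with columns `rule`, `indices`,
#'   `detail`; zero rows when every constraint holds.  Rules checked:
#'   segment lengths, corner-turn bounds, non-adjacent segment
#'   intersection, the clearance margin, and the display bounding box.
#' @export
validate_sequence <- function(seq) {
  stopifnot(inherits(seq, "motion_sequence"))
  p <- seq$params
  n <- length(seq$directions)
  if (n < 2L) stop_input("validate_sequence needs >= 2 segments")
  rule <- character(); idx <- character(); detail <- character()
  add <- function(r, i, d) {
    rule <<- c(rule, r); idx <<- c(idx, i); detail <<- c(detail, d)
  }
  v <- seq$vertices
  lens <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-(n + 1L), , drop = FALSE])^2))
  bad <- which(abs(lens - p$segment_length) > 1e-9)
  for (i in bad)
    add("segment_length", as.character(i),
        sprintf("length %.6f != %.6f", lens[i], p$segment_length))
  turns <- angular_error(seq$directions[-1L], seq$directions[-n])
  for (k in which(turns < p$corner_min - 1e-9))
    add("corner_below_min", as.character(k + 1L),
        sprintf("turn %.3f < %.3f", turns[k], p$corner_min))
  for (k in which(turns > p$corner_max + 1e-9))
    add("corner_above_max", as.character(k + 1L),
        sprintf("turn %.3f > %.3f", turns[k], p$corner_max))
  margin <- p$margin_fraction * p$segment_length
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) for (j in seq(i + 2L, n)) {
      d <- segment_distance(v[i, ], v[i + 1L, ], v[j, ], v[j + 1L, ])
      if (d == 0)
        add("intersection", paste(i, j, sep = ","),
            sprintf("segments %d and %d intersect", i, j))
      else if (d < margin - 1e-9)
        add("margin", paste(i, j, sep = ","),
            sprintf("distance %.6f < margin %.6f", d, margin))
    }
  }
  out_v <- which(!in_box(v, p))
  for (i in out_v)
    add("bounds", as.character(i),
        sprintf("vertex (%.3f, %.3f) outside display box", v[i, 1], v[i, 2]))
  data.frame(rule = rule, indices = idx, detail = detail,
             stringsAsFactors = FALSE)
}

#' Unsigned corner turns of a sequence
#' @param seq a `motion_sequence`.
#' @return degrees, length `n_segments - 1`.
#' @export
corner_turns <- function(seq) {
  n <- length(seq$directions)
  angular_error(seq$directions[-1L], seq$directions[-n])
}

#' Produce the deviant ("flip") variant of a sequence
#'
#' Replaces one segment's direction of motion with the direction exactly
#' 180 degrees opposed and recomputes the vertices from that corner
#' onward.  The deviant is deliberately NOT re-validated against the
#' geometric constraints: keeping the flip exact at 180 degrees takes
#' precedence over the intersection/boundary rules, and the flip is
#' recorded in the `flipped_segment` field.  Flipping the same segment
#' twice restores the original sequence.
#'
#' @param seq a `motion_sequence`.
#' @param segment_index 1-based segment to flip; defaults to the final
#'   segment, as in the experimental design.
#' @return a new `motion_sequence` with `flipped_segment` set (or
#'   cleared, when the flip undoes a previous one).
#' @export
apply_flip <- function(seq, segment_index = length(seq$directions)) {
  stopifnot(inherits(seq, "motion_sequence"))
  n <- length(seq$directions)
  if (segment_index < 1L || segment_index > n)
    stop_input("segment_index out of range")
  d <- seq$directions
  d[segment_index] <- wrap360(d[segment_index] + 180)
  flip <- if (identical(seq$flipped_segment, as.integer(segment_index))) NULL
          else as.integer(segment_index)
  new_motion_sequence(d, seq$params, flipped_segment = flip)
}

#' Build a block-randomized session schedule
#'
#' Each session opens with two Congruent trials (the warm-up positions
#' are never deviant), followed by ten blocks of three trials holding a
#' fixed 2:1 Congruent:Flip ratio with order randomized within block, so
#' Flip trials are spread evenly through the session.  With the default
#' four sessions this yields 128 trials: 88 Congruent and 40 Flip
#' (about 31%).  Every trial gets a unique sequence id.
#'
#' @param rng_seed integer seed; the schedule is deterministic under it.
#' @param n_sessions number of sessions (default 4).
#' @return a data frame of class `trial_schedule` with columns `trial`
#'   (1..32 within session), `session`, `condition` ("Congruent" or
#'   "Flip"), and `sequence_id`.
#' @export
build_schedule <- function(rng_seed, n_sessions = 4L) {
  if (n_sessions < 1L) stop_input("n_sessions must be >= 1")
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    set.seed(derive_seed(rng_seed, s))
    conds <- c("Congruent", "Congruent",
               unlist(lapply(seq_len(10L), function(b)
                 sample(c("Congruent", "Congruent", "Flip")))))
    out[[s]] <- data.frame(trial = seq_along(conds), session = s,
                           condition = conds, stringsAsFactors = FALSE)
  }
  sched <- do.call(rbind, out)
  sched$sequence_id <- sprintf("seq-%03d", seq_len(nrow(sched)))
  rownames(sched) <- NULL
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Serialize a motion sequence to JSON
#'
#' The JSON carries `params`, `directions`, `vertices` (list of [x, y]
#' pairs) and `flipped_segment` (null for intact stimuli).  Output is
#' byte-identical for identical sequences.
#'
#' @param seq a `motion_sequence`.
#' @param path optional file to write; when NULL the JSON string is
#'   returned.
#' @return the JSON string (invisibly, when `path` is given).
#' @export
sequence_to_json <- function(seq, path = NULL) {
  obj <- list(
    params = unclass(seq$params),
    directions = seq$directions,
    vertices = unname(apply(seq$vertices, 1L, function(r) r, simplify = FALSE)),
    flipped_segment = seq$flipped_segment
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 12, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a motion sequence from JSON
#' @param path file written by [sequence_to_json()], or a JSON string.
#' @return a `motion_sequence`.
#' @export
sequence_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  p <- do.call(sequence_params, obj$params)
  flip <- if (is.null(obj$flipped_segment)) NULL else as.integer(obj$flipped_segment)
  new_motion_sequence(obj$directions, p, flipped_segment = flip)
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat(sprintf("motion_sequence: %d segments of %.2f cm%s\n",
              length(x$directions), x$params$segment_length,
              if (!is.null(x$flipped_segment))
                sprintf(" (segment %d flipped)", x$flipped_segment) else ""))
  cat("directions (deg):", paste(sprintf("%.1f", x$directions), collapse = ", "),
      "\n")
  invisible(x)
}
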