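# Planar segment geometry used by the stimulus generator and validator.
# Segments are closed: endpoints count as part of the segment.

# Orientation of the triplet (p, q, r): +1 counter-clockwise, -1
# clockwise, 0 collinear (with a small tolerance for roundoff).
orientation <- function(p, q, r, tol = 1e-12) {
  v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  if (abs(v) <= tol) 0 else sign(v)
}

on_segment <- function(p, q, r) {
  # collinear r within the bounding box of pq
  r[1] <= max(p[1], q[1]) + 1e-12 && r[1] >= min(p[1], q[1]) - 1e-12 &&
    r[2] <= max(p[2], q[2]) + 1e-12 && r[2] >= min(p[2], q[2]) - 1e-12
}

#' Do two closed segments intersect?
#' @param p1,p2 endpoints of the first segment (length-2 numerics).
#' @param q1,q2 endpoints of the second segment.
#' @return logical.
#' @keywords internal
segments_intersect <- function(p1, p2, q1, q2) {
  o1 <- orientation(p1, p2, q1)
  o2 <- orientation(p1, p2, q2)
  o3 <- orientation(q1, q2, p1)
  o4 <- orientation(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_segment(p1, p2, q1)) ||
    (o2 == 0 && on_segment(p1, p2, q2)) ||
    (o3 == 0 && on_segment(q1, q2, p1)) ||
    (o4 == 0 && on_segment(q1, q2, p2))
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - (a + t * ab))^2))
}

#' Minimum distance between two closed segments
#'
#' Zero when the segments intersect; otherwise the smallest of the four
#' endpoint-to-segment distances.
#' @param p1,p2,q1,q2 segment endpoints (length-2 numerics).
#' @return distance in the coordinate units.
#' @keywords internal
segment_distance <- function(p1, p2, q1, q2) {
  if (segments_intersect(p1, p2, q1, q2)) return(0)
  min(point_segment_distance(q1, p1, p2),
      point_segment_distance(q2, p1, p2),
      point_segment_distance(p1, q1, q2),
      point_segment_distance(p2, q1, q2))
}
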