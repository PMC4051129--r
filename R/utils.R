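`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped to [0, 360).
#' @keywords internal
wrap360 <- function(deg) ((deg %% 360) + 360) %% 360

#' Unsigned angular difference
#'
#' Absolute angular difference between two directions, wrapped to
#' [0, 180] degrees.  This is the directional-error metric used to score
#' reproductions: the smaller of the two arcs between the directions.
#'
#' @param a,b directions in degrees (any real values; vectors recycle).
#' @return unsigned difference in degrees, in [0, 180].
#' @examples
#' angular_error(350, 10)   # 20
#' angular_error(0, 180)    # 180
#' @export
angular_error <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Derive a 32-bit sub-seed from a master seed and an index.  Keeps all
# seeds below 2^31 so they are valid R integers.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 69069 + as.double(index) * 30269) %% 2147483587)
}

stop_input <- function(...) stop(..., call. = FALSE)
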