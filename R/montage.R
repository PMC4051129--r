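#' Electrode montage
#'
#' Channel identities with 3-D positions (arbitrary but consistent
#' units) and an optional alias table mapping conventional 10-20 names
#' (Fz, Cz, Pz, ...) to channels of a high-density cap.
#'
#' @param channels character vector of unique channel ids.
#' @param positions numeric matrix, channels x 3.
#' @param aliases named character vector, e.g. `c(Cz = "E065")`.
#' @return an object of class `montage`.
#' @export
montage <- function(channels, positions, aliases = NULL) {
  positions <- as.matrix(positions)
  if (length(channels) < 2L) stop_input("a montage needs >= 2 channels")
  if (anyDuplicated(channels)) stop_input("channel ids must be unique")
  if (nrow(positions) != length(channels) || ncol(positions) != 3L)
    stop_input("positions must be channels x 3")
  if (!all(is.finite(positions))) stop_input("positions must be finite")
  rownames(positions) <- channels
  colnames(positions) <- c("x", "y", "z")
  structure(list(channels = channels, positions = positions,
                 aliases = aliases),
            class = "montage")
}

#' Resolve channel ids or aliases against a montage
#' @param mont a [montage()].
#' @param ids channel ids or alias names.
#' @return channel ids.
#' @export
resolve_channels <- function(mont, ids) {
  out <- ids
  hit <- ids %in% names(mont$aliases)
  out[hit] <- mont$aliases[ids[hit]]
  bad <- !(out %in% mont$channels)
  if (any(bad)) stop_input("unknown channel(s): ",
                           paste(ids[bad], collapse = ", "))
  out
}

#' Read / write a montage in .sfp-style whitespace text
#'
#' Each line: `id x y z`, whitespace-delimited.
#' @param path file path.
#' @param mont a `montage` (for writing).
#' @return `read_sfp` returns a `montage`.
#' @export
read_sfp <- function(path) {
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("id", "x", "y", "z"),
                         stringsAsFactors = FALSE)
  montage(d$id, as.matrix(d[, c("x", "y", "z")]))
}

#' @rdname read_sfp
#' @export
write_sfp <- function(mont, path) {
  lines <- sprintf("%s\t%.6f\t%.6f\t%.6f", mont$channels,
                   mont$positions[, 1], mont$positions[, 2],
                   mont$positions[, 3])
  writeLines(lines, path)
  invisible(path)
}

#' Packaged montage fixtures
#'
#' `"hd129"` is a synthetic 129-channel high-density cap: 128 sensors
#' laid out deterministically (Fibonacci lattice) on a spherical cap
#' extending somewhat below the equator, plus a vertex sensor `Cz`.
#' Aliases Fz, Cz, Pz, Oz map to the channels nearest the conventional
#' midline positions.  It is a geometric stand-in with plausible scalp
#' coverage, not a vendor coordinate file.  `"grid9"` is a 3 x 3 planar
#' grid with unit spacing, for small exact tests.
#'
#' @param kind "hd129" or "grid9".
#' @return a [montage()].
#' @export
default_montage <- function(kind = c("hd129", "grid9")) {
  kind <- match.arg(kind)
  if (kind == "grid9") {
    g <- expand.grid(x = 0:2, y = 0:2)
    return(montage(paste0("G", seq_len(9L)),
                   cbind(g$x, g$y, 0),
                   aliases = c(Cz = "G5")))
  }
  # 128 Fibonacci-lattice points on a spherical cap (z >= -0.35, unit
  # radius, y toward the nasion), plus the vertex.
  n <- 128L
  zmin <- -0.35
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - zmin) * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(r * cos(phi), r * sin(phi), z)
  ids <- sprintf("E%03d", seq_len(n))
  pos <- rbind(pos, c(0, 0, 1))
  ids <- c(ids, "Cz")
  nearest <- function(target) {
    d2 <- rowSums(sweep(pos, 2L, target)^2)
    ids[which.min(d2)]
  }
  # conventional midline targets on the unit sphere (y = anterior)
  aliases <- c(Fz = nearest(c(0, sin(50 * pi / 180), cos(50 * pi / 180))),
               Cz = "Cz",
               Pz = nearest(c(0, -sin(50 * pi / 180), cos(50 * pi / 180))),
               Oz = nearest(c(0, -sin(90 * pi / 180), cos(90 * pi / 180))))
  montage(ids, pos, aliases = aliases)
}
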