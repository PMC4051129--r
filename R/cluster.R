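#' Two-tailed critical t-value
#'
#' The threshold t such that `P(|T_df| > t) = alpha` for a Student-t
#' variable with `df` degrees of freedom; used to form supra-threshold
#' (channel, time) cells before clustering.
#'
#' @param alpha two-sided significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return the critical value.
#' @examples
#' critical_t(0.01, 11)  # 3.106
#' @export
critical_t <- function(alpha, df) {
  if (!(alpha > 0 && alpha < 1)) stop_input("alpha must be in (0, 1)")
  if (df < 1) stop_input("df must be >= 1")
  stats::qt(1 - alpha / 2, df)
}

#' Configuration for the cluster-based permutation test
#'
#' @param alpha significance level from which `t_crit` is derived when
#'   not supplied directly.
#' @param t_crit cluster-forming threshold on |t|; when NULL it is
#'   computed as [critical_t()] at `alpha` with the design's df.
#' @param n_perm number of random sign-flip permutations (default 1000).
#' @param seed RNG seed for the permutation draw.
#' @param adjacency_radius spatial neighbor radius in montage units;
#'   NULL uses 1.3 x the median nearest-neighbor distance.
#' @param exhaustive if TRUE enumerate all `2^n_subjects` sign flips
#'   instead of sampling (exact test; feasible for small n).
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(alpha = 0.05, t_crit = NULL, n_perm = 1000L,
                           seed = 1L, adjacency_radius = NULL,
                           exhaustive = FALSE) {
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  if (!is.null(t_crit) && t_crit <= 0) stop_input("t_crit must be > 0")
  structure(list(alpha = alpha, t_crit = t_crit, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), adjacency_radius = adjacency_radius,
                 tail = "two-sided", exhaustive = isTRUE(exhaustive)),
            class = "cluster_config")
}

#' Paired t-map over channels and time
#'
#' Computes, at every (channel, sample) cell, the paired Student t of
#' the condition difference across subjects.  Cells with zero variance
#' across subjects are undefined and returned as NA; they are treated as
#' sub-threshold by the clustering step.
#'
#' @param cond_a,cond_b numeric arrays, subjects x channels x samples,
#'   with matched subject order.
#' @return list of class `t_map`: `values` (channels x samples matrix,
#'   NA where undefined) and `df` (= n_subjects - 1).
#' @export
paired_tmap <- function(cond_a, cond_b) {
  if (!identical(dim(cond_a), dim(cond_b)))
    stop_input("condition arrays must have identical dimensions")
  n <- dim(cond_a)[1L]
  if (n < 2L) stop_input("need >= 2 subjects")
  d <- cond_a - cond_b
  X <- matrix(d, nrow = n)                 # subjects x (channels*samples)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- ifelse(v > 0, m / sqrt(v / n), NA_real_)
  structure(list(values = matrix(t, dim(cond_a)[2L], dim(cond_a)[3L]),
                 df = n - 1L),
            class = "t_map")
}

#' Spatial adjacency from a montage
#'
#' Channels are neighbors when their Euclidean distance is positive and
#' at most `radius`.  The default radius, 1.3 times the median
#' nearest-neighbor distance, connects each sensor to its immediate ring
#' on a regular high-density layout.
#'
#' @param montage a [montage()] object.
#' @param radius neighbor distance threshold; NULL for the default.
#' @return symmetric logical channels x channels matrix (irreflexive),
#'   with the radius in attribute `radius`.  Warns (does not fail) when
#'   the graph has no edges.
#' @export
build_adjacency <- function(montage, radius = NULL) {
  stopifnot(inherits(montage, "montage"))
  dmat <- as.matrix(stats::dist(montage$positions))
  if (is.null(radius)) {
    nn <- apply(dmat + diag(Inf, nrow(dmat)), 1L, min)
    radius <- 1.3 * stats::median(nn)
  }
  if (radius <= 0) stop_input("radius must be > 0")
  adj <- dmat > 0 & dmat <= radius
  diag(adj) <- FALSE
  if (!any(adj)) warning("adjacency graph has no edges at radius ", radius)
  dimnames(adj) <- list(montage$channels, montage$channels)
  attr(adj, "radius") <- radius
  adj
}

# Precompute the spatial neighbor pairs (i < j) of an adjacency matrix.
adjacency_pairs <- function(adjacency) {
  idx <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L])
}

# Connected components of the supra-threshold cells of one sign.
# M: logical channels x samples matrix.  Returns a list of integer
# vectors of cell ids (column-major indices into the t-map matrix).
components_one_sign <- function(M, pairs) {
  ids <- which(M)
  if (length(ids) == 0L) return(list())
  C <- nrow(M); Tn <- ncol(M)
  # temporal edges: same channel, consecutive samples
  tmp <- which(M[, -Tn, drop = FALSE] & M[, -1L, drop = FALSE])
  te_a <- tmp                # column-major id in C x (T-1) equals id in C x T
  te_b <- tmp + C
  # spatial edges: adjacent channels, same sample
  if (length(pairs$i) > 0L) {
    Mi <- M[pairs$i, , drop = FALSE]
    Mj <- M[pairs$j, , drop = FALSE]
    hit <- which(Mi & Mj)
    np <- length(pairs$i)
    prow <- (hit - 1L) %% np + 1L
    pcol <- (hit - 1L) %/% np + 1L
    se_a <- pairs$i[prow] + (pcol - 1L) * C
    se_b <- pairs$j[prow] + (pcol - 1L) * C
  } else {
    se_a <- se_b <- integer(0)
  }
  ea <- c(te_a, se_a); eb <- c(te_b, se_b)
  k <- length(ids)
  if (length(ea) == 0L) return(lapply(ids, identity))
  va <- match(ea, ids); vb <- match(eb, ids)
  g <- igraph::make_graph(rbind(va, vb), n = k, directed = FALSE)
  memb <- igraph::components(g)$membership
  split(ids, memb)
}

#' Find spatiotemporal clusters in a t-map
#'
#' Partitions the supra-threshold cells (|t| > `t_crit`) into maximal
#' connected components.  Two cells are connected when they share a
#' channel and sit at consecutive samples, or share a sample and sit at
#' spatially adjacent channels.  Positive and negative cells never join
#' the same cluster.  Each cluster's mass is the sum of its member
#' t-scores.
#'
#' @param tmap a `t_map` from [paired_tmap()] (or a bare matrix).
#' @param t_crit cluster-forming threshold (> 0).
#' @param adjacency logical adjacency matrix from [build_adjacency()].
#' @return list of clusters, each a list with `members` (two-column
#'   matrix: channel, sample), `mass`, `sign`; ordered by decreasing
#'   |mass|.
#' @export
find_clusters <- function(tmap, t_crit, adjacency) {
  vals <- if (inherits(tmap, "t_map")) tmap$values else tmap
  if (t_crit <= 0) stop_input("t_crit must be > 0")
  pairs <- adjacency_pairs(adjacency)
  v <- vals
  v[is.na(v)] <- 0
  out <- list()
  for (sgn in c(1, -1)) {
    M <- if (sgn > 0) v > t_crit else v < -t_crit
    comps <- components_one_sign(M, pairs)
    for (cc in comps) {
      C <- nrow(v)
      members <- cbind(channel = (cc - 1L) %% C + 1L,
                       sample = (cc - 1L) %/% C + 1L)
      out[[length(out) + 1L]] <- list(members = members,
                                      mass = sum(v[cc]),
                                      sign = if (sgn > 0) "positive" else "negative")
    }
  }
  out[order(-vapply(out, function(cl) abs(cl$mass), numeric(1)))]
}

# Max |mass| over all clusters of a t-vector (internal, permutation loop).
max_cluster_mass <- function(tvec, C, Tn, t_crit, pairs) {
  tvec[is.na(tvec)] <- 0
  best <- 0
  for (sgn in c(1, -1)) {
    M <- matrix(if (sgn > 0) tvec > t_crit else tvec < -t_crit, C, Tn)
    comps <- components_one_sign(M, pairs)
    for (cc in comps) best <- max(best, abs(sum(tvec[cc])))
  }
  best
}

#' Spatiotemporal cluster-based permutation test (paired design)
#'
#' The full max-statistic procedure: a paired t-map over (channel, time)
#' cells, adjacency-constrained clusters at `|t| > t_crit`, summed-t
#' cluster mass, and a family-wise null built by randomly exchanging the
#' two condition labels within subjects (equivalently, sign-flipping
#' each subject's difference) and recording the largest cluster |mass|
#' of each permutation (0 when a permutation has no supra-threshold
#' cells).  The null pools both signs, so family-wise error is
#' controlled across positive and negative clusters jointly.  Cluster
#' p-values use the add-one convention
#' `p = (1 + #\{null >= |mass|\}) / (n_perm + 1)`, with ties counted as
#' exceedances; the smallest attainable p is `1 / (n_perm + 1)`.  In
#' exhaustive mode all `2^n` sign assignments (including the identity)
#' are enumerated and `p = #\{null >= |mass|\} / 2^n`.
#'
#' @param cond_a,cond_b subjects x channels x samples arrays of
#'   per-subject condition means (matched subjects).
#' @param montage a [montage()] (used to build spatial adjacency), or a
#'   prebuilt adjacency matrix via the `adjacency` argument.
#' @param config a [cluster_config()].
#' @param adjacency optional adjacency matrix overriding `montage`.
#' @return object of class `permutation_result`: list with `clusters`
#'   (each with members, mass, sign, p_value), `null_distribution`,
#'   `t_map`, `t_crit`, and the config.
#' @export
cluster_permutation_test <- function(cond_a, cond_b, montage = NULL,
                                     config = cluster_config(),
                                     adjacency = NULL) {
  if (!identical(dim(cond_a), dim(cond_b)))
    stop_input("condition arrays must have identical dimensions")
  n <- dim(cond_a)[1L]; C <- dim(cond_a)[2L]; Tn <- dim(cond_a)[3L]
  if (n < 2L) stop_input("need >= 2 subjects")
  if (is.null(adjacency)) {
    if (is.null(montage)) stop_input("supply a montage or an adjacency matrix")
    adjacency <- build_adjacency(montage, config$adjacency_radius)
  }
  pairs <- adjacency_pairs(adjacency)
  t_crit <- config$t_crit %||% critical_t(config$alpha, n - 1L)

  D <- matrix(cond_a - cond_b, nrow = n)   # subjects x (C*Tn)
  ss <- colSums(D^2)                        # invariant under sign flips
  t_from_signs <- function(sg) {
    m <- drop(sg %*% D) / n
    v <- (ss - n * m^2) / (n - 1)
    v[v < 1e-24] <- NA_real_
    m / sqrt(v / n)
  }

  t_obs <- t_from_signs(rep(1, n))
  tmap <- structure(list(values = matrix(t_obs, C, Tn), df = n - 1L),
                    class = "t_map")
  clusters <- find_clusters(tmap, t_crit, adjacency)

  if (config$exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(signs)                   # includes the identity
  } else {
    set.seed(config$seed)
    n_perm <- config$n_perm
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  null_dist <- numeric(n_perm)
  for (p in seq_len(n_perm))
    null_dist[p] <- max_cluster_mass(t_from_signs(signs[p, ]), C, Tn,
                                     t_crit, pairs)

  for (k in seq_along(clusters)) {
    exceed <- sum(null_dist >= abs(clusters[[k]]$mass))
    clusters[[k]]$p_value <- if (config$exhaustive) exceed / n_perm
                             else (1 + exceed) / (n_perm + 1)
  }
  structure(list(clusters = clusters, null_distribution = null_dist,
                 t_map = tmap, t_crit = t_crit, config = config,
                 adjacency_radius = attr(adjacency, "radius")),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("cluster permutation test: %d cluster(s), t_crit = %.3f, %d permutations\n",
              length(x$clusters), x$t_crit, length(x$null_distribution)))
  for (cl in x$clusters)
    cat(sprintf("  %s cluster: mass = %.2f, %d cells, p = %.4f\n",
                cl$sign, cl$mass, nrow(cl$members), cl$p_value))
  invisible(x)
}

#' Serialize a permutation result to JSON
#'
#' Per cluster: sign, mass, p, member channels, time window (ms), and
#' member count.  The null distribution can be written alongside as CSV.
#'
#' @param result a `permutation_result`.
#' @param time_ms sample-time axis used to report cluster windows.
#' @param channels channel ids.
#' @param path optional JSON file to write.
#' @param null_csv optional CSV path for the null distribution.
#' @return the JSON string, invisibly when written to file.
#' @export
clusters_to_json <- function(result, time_ms, channels, path = NULL,
                             null_csv = NULL) {
  items <- lapply(result$clusters, function(cl) {
    list(sign = cl$sign, mass = cl$mass, p = cl$p_value,
         channels = sort(unique(channels[cl$members[, "channel"]])),
         time_window_ms = range(time_ms[cl$members[, "sample"]]),
         n_members = nrow(cl$members))
  })
  js <- jsonlite::toJSON(list(t_crit = result$t_crit,
                              n_perm = length(result$null_distribution),
                              clusters = items),
                         auto_unbox = TRUE, digits = 10)
  if (!is.null(null_csv))
    utils::write.csv(data.frame(max_cluster_mass = result$null_distribution),
                     null_csv, row.names = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
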