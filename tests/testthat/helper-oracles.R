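# Independent brute-force oracles.  These deliberately avoid the
# package's own code paths: distances by dense sampling, clusters by
# flood fill, permutation p by full enumeration, ANOVA by the textbook
# sum-of-squares and Box-epsilon formulas.

# Minimum distance between two closed segments by dense sampling.
oracle_segment_distance <- function(p1, p2, q1, q2, n = 400) {
  t <- seq(0, 1, length.out = n)
  A <- cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]))
  B <- cbind(q1[1] + t * (q2[1] - q1[1]), q1[2] + t * (q2[2] - q1[2]))
  d2 <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
  sqrt(min(d2))
}

# Orientation-based segment intersection (textbook CCW test).
oracle_segments_intersect <- function(p1, p2, q1, q2) {
  ccw <- function(a, b, c)
    (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  ccw(p1, q1, q2) != ccw(p2, q1, q2) && ccw(p1, p2, q1) != ccw(p1, p2, q2)
}

# Exhaustive validity check of a motion sequence using the oracles.
oracle_validate <- function(seq) {
  v <- seq$vertices; p <- seq$params
  n <- length(seq$directions)
  turns <- abs(((diff(seq$directions) + 180) %% 360) - 180)
  ok_turn <- all(turns >= p$corner_min - 1e-9 & turns <= p$corner_max + 1e-9)
  ok_geom <- TRUE
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 2):n) {
      d <- oracle_segment_distance(v[i, ], v[i + 1, ], v[j, ], v[j + 1, ])
      if (d < p$margin_fraction * p$segment_length - 2e-3) ok_geom <- FALSE
      if (oracle_segments_intersect(v[i, ], v[i + 1, ], v[j, ], v[j + 1, ]))
        ok_geom <- FALSE
    }
  }
  ok_box <- all(abs(v[, 1]) <= p$display_halfwidth + 1e-9 &
                abs(v[, 2]) <= p$display_halfheight + 1e-9)
  ok_turn && ok_geom && ok_box
}

# Flood-fill clustering of a t-map (stack-based, one cell at a time).
oracle_find_clusters <- function(tmat, t_crit, adjacency) {
  C <- nrow(tmat); Tn <- ncol(tmat)
  tmat[is.na(tmat)] <- 0
  lab <- matrix(0L, C, Tn)
  nxt <- 0L
  out <- list()
  for (c0 in seq_len(C)) for (s0 in seq_len(Tn)) {
    if (lab[c0, s0] != 0L || abs(tmat[c0, s0]) <= t_crit) next
    nxt <- nxt + 1L
    sgn <- sign(tmat[c0, s0])
    stack <- list(c(c0, s0))
    members <- NULL
    lab[c0, s0] <- nxt
    while (length(stack) > 0) {
      cell <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      members <- rbind(members, cell)
      ch <- cell[1]; sa <- cell[2]
      nbrs <- list()
      if (sa > 1) nbrs <- c(nbrs, list(c(ch, sa - 1)))
      if (sa < Tn) nbrs <- c(nbrs, list(c(ch, sa + 1)))
      for (ch2 in which(adjacency[ch, ])) nbrs <- c(nbrs, list(c(ch2, sa)))
      for (nb in nbrs) {
        if (lab[nb[1], nb[2]] == 0L &&
            abs(tmat[nb[1], nb[2]]) > t_crit &&
            sign(tmat[nb[1], nb[2]]) == sgn) {
          lab[nb[1], nb[2]] <- nxt
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
    mass <- sum(tmat[members[, 1] + (members[, 2] - 1) * C])
    out[[nxt]] <- list(members = members, mass = mass)
  }
  out
}

# Exact sign-flip permutation p-values by enumeration over all 2^n
# assignments; returns p for each observed cluster mass.
oracle_exhaustive_p <- function(diffs, t_crit, adjacency) {
  n <- dim(diffs)[1]
  C <- dim(diffs)[2]; Tn <- dim(diffs)[3]
  tstat <- function(d) {
    m <- apply(d, c(2, 3), mean)
    s <- apply(d, c(2, 3), stats::sd)
    t <- m / (s / sqrt(n))
    t[s == 0] <- 0
    t
  }
  obs <- oracle_find_clusters(tstat(diffs), t_crit, adjacency)
  null <- numeric(2^n)
  for (k in 0:(2^n - 1)) {
    sg <- ifelse(bitwAnd(k, 2^(0:(n - 1))) > 0, -1, 1)
    d2 <- diffs * array(rep(sg, C * Tn), dim(diffs))
    cl <- oracle_find_clusters(tstat(d2), t_crit, adjacency)
    null[k + 1] <- if (length(cl)) max(abs(vapply(cl, `[[`, numeric(1), "mass")))
                   else 0
  }
  vapply(obs, function(cl) mean(null >= abs(cl$mass)), numeric(1))
}

# Textbook two-way within-subject ANOVA oracle: raw sum-of-squares
# loops and the Box epsilon computed from covariance-matrix entries
# (double-sum form), not the trace form the package uses.
oracle_rm_anova <- function(y) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  gm <- mean(y)
  ssa <- 0
  for (i in 1:a) ssa <- ssa + n * b * (mean(y[, i, ]) - gm)^2
  ssb <- 0
  for (j in 1:b) ssb <- ssb + n * a * (mean(y[, , j]) - gm)^2
  ssab <- 0
  for (i in 1:a) for (j in 1:b)
    ssab <- ssab + n * (mean(y[, i, j]) - mean(y[, i, ]) - mean(y[, , j]) + gm)^2
  ssas <- 0
  for (s in 1:n) for (i in 1:a)
    ssas <- ssas + b * (mean(y[s, i, ]) - mean(y[s, , ]) - mean(y[, i, ]) + gm)^2
  ssbs <- 0
  for (s in 1:n) for (j in 1:b)
    ssbs <- ssbs + a * (mean(y[s, , j]) - mean(y[s, , ]) - mean(y[, , j]) + gm)^2
  ssabs <- 0
  for (s in 1:n) for (i in 1:a) for (j in 1:b)
    ssabs <- ssabs + (y[s, i, j] - mean(y[s, i, ]) - mean(y[s, , j]) -
                        mean(y[, i, j]) + mean(y[s, , ]) + mean(y[, i, ]) +
                        mean(y[, , j]) - gm)^2
  box_eps <- function(S, k1) {
    # Box epsilon in the element-wise form on the contrast covariance
    tr <- sum(diag(S))
    tr^2 / (k1 * sum(S * S))
  }
  helmert_on <- function(k) {
    C <- stats::contr.helmert(k)
    qr.Q(qr(C))
  }
  Ca <- t(helmert_on(a)); Cb <- t(helmert_on(b))
  Ya <- apply(y, c(1, 2), mean)
  Yb <- apply(y, c(1, 3), mean)
  cells <- matrix(NA_real_, n, a * b)
  col <- 0
  for (i in 1:a) for (j in 1:b) { col <- col + 1; cells[, col] <- y[, i, j] }
  eps <- c(A = box_eps(Ca %*% stats::cov(Ya) %*% t(Ca), a - 1),
           B = box_eps(Cb %*% stats::cov(Yb) %*% t(Cb), b - 1),
           AB = box_eps(kronecker(Ca, Cb) %*% stats::cov(cells) %*%
                          t(kronecker(Ca, Cb)), (a - 1) * (b - 1)))
  Fa <- (ssa / (a - 1)) / (ssas / ((a - 1) * (n - 1)))
  Fb <- (ssb / (b - 1)) / (ssbs / ((b - 1) * (n - 1)))
  Fab <- (ssab / ((a - 1) * (b - 1))) / (ssabs / ((a - 1) * (b - 1) * (n - 1)))
  list(F = c(A = Fa, B = Fb, AB = Fab),
       epsilon = pmin(1, eps),
       pes = c(A = ssa / (ssa + ssas), B = ssb / (ssb + ssbs),
               AB = ssab / (ssab + ssabs)))
}

# Spectral amplitude of a single-frequency tone in a vector.
oracle_fft_amplitude <- function(x, freq, fs) {
  n <- length(x)
  k <- round(freq * n / fs) + 1
  2 * abs(stats::fft(x))[k] / n
}

toy_adjacency_chain <- function(k) {
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  adj
}
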