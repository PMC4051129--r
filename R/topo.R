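#' RMS-normalize a topography
#'
#' Corrects for overall amplitude differences between conditions before
#' comparing response topographies: each electrode's value is divided by
#' the root-mean-square voltage across electrodes within that condition,
#' so the normalized topography has RMS exactly 1 and is invariant to
#' any positive rescaling of the input.
#'
#' @param topography numeric vector (one value per channel) or matrix
#'   (channels x samples); must not be all zero.
#' @return same shape, divided by its RMS; class `normalized_topography`
#'   for vectors.
#' @export
rms_normalize <- function(topography) {
  x <- topography
  r <- sqrt(mean(x^2))
  if (!is.finite(r) || r == 0)
    stop_input("cannot normalize an all-zero topography")
  out <- x / r
  if (is.null(dim(out))) class(out) <- "normalized_topography"
  out
}

#' Windowed per-electrode mean amplitude
#'
#' Mean voltage over the samples whose timestamps fall in the half-open
#' window `[start, end)` ms, at the requested electrodes (montage
#' aliases such as Fz/Cz/Pz are resolved when a montage is given).
#'
#' @param erp an `erp` object (see [condition_average()]).
#' @param window `c(start, end)` in ms.
#' @param electrodes channel ids (or aliases); NULL for all channels.
#' @param montage optional [montage()] used to resolve aliases.
#' @return named numeric vector of per-electrode means, microvolts.
#' @export
window_mean <- function(erp, window, electrodes = NULL, montage = NULL) {
  stopifnot(inherits(erp, "erp"))
  sel <- erp$time_ms >= window[1] & erp$time_ms < window[2]
  if (!any(sel)) stop_input("no samples inside window [",
                            window[1], ", ", window[2], ") ms")
  chans <- erp$channels
  rows <- seq_along(chans)
  if (!is.null(electrodes)) {
    ids <- if (!is.null(montage)) resolve_channels(montage, electrodes)
           else electrodes
    rows <- match(ids, chans)
    if (anyNA(rows))
      stop_input("unknown electrode(s): ",
                 paste(electrodes[is.na(rows)], collapse = ", "))
  }
  out <- rowMeans(erp$data[rows, sel, drop = FALSE])
  names(out) <- if (!is.null(electrodes)) electrodes else chans
  out
}

# Orthonormal contrast matrix ((k-1) x k) for a k-level within factor.
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)              # k x (k-1)
  C <- qr.Q(qr(C))                          # orthonormal columns
  t(C)
}

# Greenhouse-Geisser epsilon from the covariance of the subject-level
# scores projected onto the effect's orthonormal contrasts.
gg_epsilon <- function(scores, contrasts) {
  M <- contrasts %*% stats::cov(scores) %*% t(contrasts)
  k1 <- nrow(M)
  eps <- sum(diag(M))^2 / (k1 * sum(M^2))
  min(1, max(1 / k1, eps))
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate within-subject ANOVA on a complete subjects x A x B table
#' of cell means (one observation per subject and cell).  Each effect is
#' tested against its own subject-by-effect interaction error term;
#' sphericity is corrected per effect with the Greenhouse-Geisser
#' epsilon computed from the covariance of the effect's orthonormal
#' contrast scores (for a 2-level factor epsilon is exactly 1).  Effect
#' size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table numeric 3-d array, subjects x levels(A) x levels(B),
#'   complete (no NA).  Dimension names, when present, name the factors
#'   and levels in the output.
#' @param factor_names length-2 character, names for the two factors.
#' @return data frame of class `anova_result` with one row per effect
#'   (A, B, A:B): `df_num`, `df_den`, `F`, `epsilon`, `p_uncorrected`,
#'   `p_gg`, `partial_eta_sq`.
#' @export
rm_anova <- function(table, factor_names = c("A", "B")) {
  y <- as.array(table)
  if (length(dim(y)) != 3L) stop_input("table must be subjects x A x B")
  if (any(is.na(y))) stop_input("table has missing cells")
  n <- dim(y)[1L]; a <- dim(y)[2L]; b <- dim(y)[3L]
  if (n < 2L) stop_input("need >= 2 subjects")
  gm <- mean(y)
  m_s  <- apply(y, 1L, mean)
  m_a  <- apply(y, 2L, mean)
  m_b  <- apply(y, 3L, mean)
  m_sa <- apply(y, c(1L, 2L), mean)
  m_sb <- apply(y, c(1L, 3L), mean)
  m_ab <- apply(y, c(2L, 3L), mean)

  ss_a  <- n * b * sum((m_a - gm)^2)
  ss_b  <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1L, m_a), 2L, m_b) + gm)^2)
  ss_as <- b * sum((m_sa - outer(m_s, m_a, `+`) + gm)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, m_b, `+`) + gm)^2)
  resid <- y
  for (s in seq_len(n)) for (i in seq_len(a)) for (j in seq_len(b))
    resid[s, i, j] <- y[s, i, j] - m_sa[s, i] - m_sb[s, j] - m_ab[i, j] +
      m_s[s] + m_a[i] + m_b[j] - gm
  ss_abs <- sum(resid^2)

  eff <- function(name, ss_eff, ss_err, df1, df2, eps) {
    Fv <- (ss_eff / df1) / (ss_err / df2)
    data.frame(effect = name, df_num = df1, df_den = df2, F = Fv,
               epsilon = eps,
               p_uncorrected = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               p_gg = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
               partial_eta_sq = ss_eff / (ss_eff + ss_err),
               stringsAsFactors = FALSE)
  }
  Ca <- orthonormal_contrasts(a)
  Cb <- orthonormal_contrasts(b)
  scores_a <- apply(y, c(1L, 2L), mean)     # collapse over B
  scores_b <- apply(y, c(1L, 3L), mean)
  # cell score columns ordered A slow, B fast, to match kronecker(Ca, Cb)
  cells <- matrix(NA_real_, n, a * b)
  col <- 0L
  for (i in seq_len(a)) for (j in seq_len(b)) {
    col <- col + 1L
    cells[, col] <- y[, i, j]
  }
  eps_a  <- gg_epsilon(scores_a, Ca)
  eps_b  <- gg_epsilon(scores_b, Cb)
  eps_ab <- gg_epsilon(cells, kronecker(Ca, Cb))

  out <- rbind(
    eff(factor_names[1], ss_a, ss_as, a - 1, (a - 1) * (n - 1), eps_a),
    eff(factor_names[2], ss_b, ss_bs, b - 1, (b - 1) * (n - 1), eps_b),
    eff(paste(factor_names, collapse = ":"), ss_ab, ss_abs,
        (a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1), eps_ab))
  attr(out, "ss") <- c(A = ss_a, B = ss_b, AB = ss_ab,
                       AS = ss_as, BS = ss_bs, ABS = ss_abs,
                       subjects = a * b * sum((m_s - gm)^2),
                       total = sum((y - gm)^2))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Paired post-hoc t-test
#'
#' Standard two-tailed paired Student t.  When the two vectors are
#' identical (all differences zero) the test degenerates to t = 0,
#' p = 1; any other zero-variance difference is an error.
#'
#' @param a,b paired numeric vectors (same subjects, length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
posthoc_paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop_input("need paired vectors of equal length >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1))
    stop_input("zero-variance non-zero differences: t undefined")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
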