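#' Behavioral generative model for synthetic reproductions
#'
#' The study's behavior is emulated minimally: each reproduced segment's
#' direction is the stimulus direction plus zero-mean Gaussian angular
#' noise whose SD shrinks over the four presentations (encoding
#' learning: most of the improvement happens after the first
#' presentation), strokes are drawn at a jittered constant speed, and
#' the stylus rests at each corner for a jittered pause.
#'
#' @param angular_noise_sd_by_presentation degrees, presentations 1-4;
#'   must be non-increasing from first to last presentation.
#' @param pause_jitter_sd s.
#' @param speed_jitter_fraction multiplicative speed jitter SD.
#' @param tablet_sample_rate Hz.
#' @return object of class `behavior_model`.
#' @export
behavior_model <- function(angular_noise_sd_by_presentation = c(25, 15, 13, 12),
                           pause_jitter_sd = 0.03,
                           speed_jitter_fraction = 0.10,
                           tablet_sample_rate = 100) {
  sds <- angular_noise_sd_by_presentation
  if (any(sds < 0)) stop_input("angular noise SDs must be >= 0")
  if (sds[1] < sds[length(sds)])
    stop_input("presentation-1 SD must be >= final-presentation SD")
  structure(list(angular_noise_sd_by_presentation = sds,
                 pause_jitter_sd = pause_jitter_sd,
                 speed_jitter_fraction = speed_jitter_fraction,
                 tablet_sample_rate = tablet_sample_rate),
            class = "behavior_model")
}

#' Simulate a stylus reproduction of a motion sequence
#'
#' Produces a trace of straight strokes, one per stimulus segment, each
#' rotated by Gaussian angular noise for the given presentation, drawn
#' at jittered speed and separated by stationary pauses.  With all noise
#' parameters zero the trace replays the stimulus exactly and scores
#' zero directional error.
#'
#' @param seq a `motion_sequence`.
#' @param model a [behavior_model()].
#' @param presentation presentation number, 1..4 (indexes the noise SD).
#' @param rng_seed integer seed.
#' @return a [stylus_trace()].
#' @export
simulate_reproduction <- function(seq, model = behavior_model(),
                                  presentation = 1L, rng_seed = 1L) {
  stopifnot(inherits(seq, "motion_sequence"))
  sds <- model$angular_noise_sd_by_presentation
  if (presentation < 1L || presentation > length(sds))
    stop_input("presentation must be in 1..", length(sds))
  set.seed(as.integer(rng_seed))
  p <- seq$params
  fs <- model$tablet_sample_rate
  dt <- 1 / fs
  t_cur <- 0
  pos <- c(0, 0)
  t_all <- 0; x_all <- pos[1]; y_all <- pos[2]
  n_seg <- length(seq$directions)
  for (i in seq_len(n_seg)) {
    dir <- seq$directions[i] +
      if (sds[presentation] > 0) stats::rnorm(1, 0, sds[presentation]) else 0
    spd <- p$speed * max(0.2, 1 + if (model$speed_jitter_fraction > 0)
      stats::rnorm(1, 0, model$speed_jitter_fraction) else 0)
    dur <- p$segment_length / spd
    nstep <- max(2L, round(dur * fs))
    step_t <- dur / nstep
    rad <- dir * pi / 180
    for (k in seq_len(nstep)) {
      t_cur <- t_cur + step_t
      pos <- pos + (p$segment_length / nstep) * c(cos(rad), sin(rad))
      t_all <- c(t_all, t_cur); x_all <- c(x_all, pos[1]); y_all <- c(y_all, pos[2])
    }
    if (i < n_seg) {
      pdur <- max(0.2, p$pause + if (model$pause_jitter_sd > 0)
        stats::rnorm(1, 0, model$pause_jitter_sd) else 0)
      npau <- max(1L, round(pdur * fs))
      for (k in seq_len(npau)) {
        t_cur <- t_cur + dt
        t_all <- c(t_all, t_cur); x_all <- c(x_all, pos[1]); y_all <- c(y_all, pos[2])
      }
    }
  }
  stylus_trace(t_all, x_all, y_all, sample_rate = fs)
}

#' ERP effect specification for the synthetic EEG generator
#'
#' Each component is a separable spatiotemporal template: a spatial
#' weight per channel (unitless topography), a Gaussian temporal profile
#' `exp(-(t - latency)^2 / (2 width^2))`, and a per-condition peak
#' amplitude in microvolts.  Epoch noise is spatially correlated
#' Gaussian noise with a squared-exponential covariance over sensor
#' distance.
#'
#' @param components list of components, each a list with `name`,
#'   `weights` (numeric per channel), `latency_ms`, `width_ms` (Gaussian
#'   SD), `amplitude` (named vector, one entry per condition).
#' @param noise list with `sd` (microvolts, per sample and channel) and
#'   `corr_length` (spatial correlation length, montage units).
#' @param subject_sd SD of the per-subject multiplicative component gain
#'   (gain ~ N(1, subject_sd), shared across conditions).
#' @return object of class `erp_effect_spec`.
#' @export
erp_effect_spec <- function(components, noise = list(sd = 10, corr_length = 0.3),
                            subject_sd = 0.2) {
  for (cmp in components) {
    if (cmp$width_ms <= 0) stop_input("component width must be > 0")
    if (!all(is.finite(cmp$amplitude))) stop_input("amplitudes must be finite")
  }
  structure(list(components = components, noise = noise,
                 subject_sd = subject_sd),
            class = "erp_effect_spec")
}

# Gaussian spatial weight profile centered on a scalp target.
topography_weights <- function(mont, center, spread = 0.45) {
  d2 <- rowSums(sweep(mont$positions, 2L, center)^2)
  exp(-d2 / (2 * spread^2))
}

#' Default effect specification for a montage
#'
#' Two late positivities, emulating the structure the analysis targets:
#' a broad centro-parietal component ("P3b-like", latency 420 ms, width
#' 40 ms) whose amplitude is graded deviant > new > familiar, and a
#' sharper fronto-central component ("P3a-like", latency 422 ms, width
#' 25 ms) strongly enhanced for deviants only.  On the hd129 cap the
#' topographies are Gaussian profiles centered just anterior (P3a) and
#' posterior (P3b) of the vertex.
#'
#' @param mont a [montage()].
#' @return an [erp_effect_spec()].
#' @export
default_effect_spec <- function(mont = default_montage("hd129")) {
  planar <- all(mont$positions[, 3] == 0)
  fc <- if (planar) c(1, 2, 0)
        else c(0, sin(35 * pi / 180), cos(35 * pi / 180))
  cp <- if (planar) c(1, 0, 0)
        else c(0, -sin(45 * pi / 180), cos(45 * pi / 180))
  erp_effect_spec(components = list(
    list(name = "P3b-like",
         weights = topography_weights(mont, cp),
         latency_ms = 420, width_ms = 40, window_ms = c(396, 448),
         amplitude = c(familiar = 2.0, new = 2.6, deviant = 3.0)),
    list(name = "P3a-like",
         weights = topography_weights(mont, fc),
         latency_ms = 422, width_ms = 39, window_ms = c(376, 468),
         amplitude = c(familiar = 0.3, new = 0.3, deviant = 5.8))))
}

#' Simulate epoched EEG for a cohort
#'
#' Every epoch is the sum of the specified components (per-condition
#' amplitude x spatial weight x Gaussian temporal profile, scaled by a
#' per-subject gain) plus spatially correlated Gaussian noise.  Epochs
#' run -200..600 ms (half-open) at the given rate.
#'
#' @param mont a [montage()].
#' @param spec an [erp_effect_spec()]; conditions are the union of the
#'   components' amplitude names.
#' @param subjects number of subjects (default 12).
#' @param epochs_per_condition epochs per subject and condition
#'   (default 32).
#' @param rng_seed integer master seed; per-subject sub-seeds derive
#'   from it.
#' @param sample_rate Hz (default 250).
#' @param window_ms half-open epoch window, ms.
#' @param conditions optional subset of condition names to simulate.
#' @return named list, one [epoch_set()] per subject, each with labels
#'   (subject, condition).
#' @export
simulate_epochs <- function(mont, spec = default_effect_spec(mont),
                            subjects = 12L, epochs_per_condition = 32L,
                            rng_seed = 1L, sample_rate = 250,
                            window_ms = c(-200, 600), conditions = NULL) {
  stopifnot(inherits(mont, "montage"), inherits(spec, "erp_effect_spec"))
  nC <- length(mont$channels)
  for (cmp in spec$components)
    if (length(cmp$weights) != nC)
      stop_input("component '", cmp$name, "' weights do not match montage")
  conds <- conditions %||%
    unique(unlist(lapply(spec$components, function(c) names(c$amplitude))))
  nT <- round((window_ms[2] - window_ms[1]) / 1000 * sample_rate)
  time_ms <- window_ms[1] + (seq_len(nT) - 1L) / sample_rate * 1000

  # spatial noise covariance factor (shared across subjects)
  dmat <- as.matrix(stats::dist(mont$positions))
  K <- exp(-dmat^2 / (2 * spec$noise$corr_length^2))
  cf <- chol(K + diag(1e-8, nC))

  profiles <- lapply(spec$components, function(cmp)
    exp(-(time_ms - cmp$latency_ms)^2 / (2 * cmp$width_ms^2)))

  out <- vector("list", subjects)
  for (s in seq_len(subjects)) {
    set.seed(derive_seed(rng_seed, s))
    gains <- 1 + stats::rnorm(length(spec$components), 0, spec$subject_sd)
    nE <- epochs_per_condition * length(conds)
    arr <- array(0, c(nC, nT, nE))
    labels <- data.frame(subject = rep(s, nE),
                         condition = rep(conds, each = epochs_per_condition))
    signal <- lapply(conds, function(cond) {
      sig <- matrix(0, nC, nT)
      for (k in seq_along(spec$components)) {
        cmp <- spec$components[[k]]
        amp <- if (cond %in% names(cmp$amplitude)) cmp$amplitude[[cond]] else 0
        sig <- sig + gains[k] * amp * outer(cmp$weights, profiles[[k]])
      }
      sig
    })
    names(signal) <- conds
    for (e in seq_len(nE)) {
      noise <- t(cf) %*% matrix(stats::rnorm(nC * nT, 0, spec$noise$sd), nC, nT)
      arr[, , e] <- signal[[labels$condition[e]]] + noise
    }
    out[[s]] <- epoch_set(arr, time_ms, sample_rate, labels = labels,
                          channels = mont$channels)
  }
  names(out) <- paste0("subj", seq_len(subjects))
  out
}

#' Per-subject condition means as a subjects x channels x samples array
#'
#' Averages each subject's epochs within the given condition; the
#' resulting array is the input format of [cluster_permutation_test()].
#'
#' @param epoch_sets list of `epoch_set`, one per subject.
#' @param condition condition label to average.
#' @return subjects x channels x samples numeric array.
#' @export
subject_condition_means <- function(epoch_sets, condition) {
  mats <- lapply(epoch_sets, function(es)
    condition_average(es, condition = condition)$data)
  arr <- array(NA_real_, c(length(mats), dim(mats[[1]])))
  for (s in seq_along(mats)) arr[s, , ] <- mats[[s]]
  arr
}

#' Spatiotemporal support of an injected component
#'
#' The ground-truth cells of an injected effect, as channels x window:
#' channels whose spatial weight is at least half the component's peak
#' weight, crossed with the samples inside the component's stated
#' window (`window_ms`; the temporal full width at half maximum when a
#' component carries no window).  Used as ground truth in
#' effect-recovery tests.
#'
#' @param spec an [erp_effect_spec()].
#' @param component component name.
#' @param time_ms epoch time axis, ms.
#' @return two-column matrix (channel, sample) of support cells.
#' @export
component_support <- function(spec, component, time_ms) {
  k <- which(vapply(spec$components, `[[`, character(1), "name") == component)
  if (length(k) != 1L) stop_input("unknown component '", component, "'")
  cmp <- spec$components[[k]]
  chans <- which(cmp$weights >= 0.5 * max(cmp$weights))
  if (!is.null(cmp$window_ms)) {
    samps <- which(time_ms >= cmp$window_ms[1] & time_ms < cmp$window_ms[2])
  } else {
    prof <- exp(-(time_ms - cmp$latency_ms)^2 / (2 * cmp$width_ms^2))
    samps <- which(prof >= 0.5)
  }
  as.matrix(expand.grid(channel = chans, sample = samps))
}

#' Jaccard overlap between a cluster and a cell set
#'
#' @param members two-column (channel, sample) matrix, e.g. a cluster's
#'   member set.
#' @param support two-column matrix of ground-truth cells.
#' @param n_channels number of channels (to key cells uniquely).
#' @return Jaccard index in [0, 1].
#' @export
jaccard_overlap <- function(members, support, n_channels) {
  key <- function(m) (m[, 2] - 1) * n_channels + m[, 1]
  a <- key(members); b <- key(support)
  length(intersect(a, b)) / length(union(a, b))
}
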