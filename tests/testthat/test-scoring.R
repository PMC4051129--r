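# Build a trace of straight strokes with stationary pauses at known
# boundaries (100 Hz), for segmentation fixtures.
make_stroke_trace <- function(dirs, lengths = rep(1, length(dirs)),
                              speed = 2, pause = 0.4, fs = 100) {
  t <- 0; x <- 0; y <- 0
  tt <- t; xx <- x; yy <- y
  for (i in seq_along(dirs)) {
    dur <- lengths[i] / speed
    nst <- round(dur * fs)
    rad <- dirs[i] * pi / 180
    for (k in seq_len(nst)) {
      t <- t + 1 / fs
      x <- x + lengths[i] / nst * cos(rad)
      y <- y + lengths[i] / nst * sin(rad)
      tt <- c(tt, t); xx <- c(xx, x); yy <- c(yy, y)
    }
    if (i < length(dirs)) {
      for (k in seq_len(round(pause * fs))) {
        t <- t + 1 / fs
        tt <- c(tt, t); xx <- c(xx, x); yy <- c(yy, y)
      }
    }
  }
  stylus_trace(tt, xx, yy, sample_rate = fs)
}

test_that("angular_error wraps correctly and is symmetric and periodic", {
  expect_equal(angular_error(10, 10), 0)
  expect_equal(angular_error(0, 180), 180)
  expect_equal(angular_error(350, 10), 20)
  set.seed(42)
  a <- runif(200, -720, 720); b <- runif(200, -720, 720)
  expect_equal(angular_error(a, b), angular_error(b, a))
  expect_equal(angular_error(a + 360 * sample(-3:3, 200, TRUE), b),
               angular_error(a, b))
  expect_true(all(angular_error(a, b) >= 0 & angular_error(a, b) <= 180))
})

test_that("fit_segment_direction respects travel order and matches the endpoint oracle", {
  pts <- cbind(seq(0, 2, 0.1), seq(0, 2, 0.1))   # on the 45-degree ray
  expect_equal(fit_segment_direction(pts), 45)
  expect_equal(fit_segment_direction(pts[nrow(pts):1, ]), 225)
  # noisy stroke near 10 degrees: endpoint fit equals direct computation
  set.seed(1)
  t <- seq(0, 1, 0.02)
  pts2 <- cbind(4 * t * cos(10 * pi / 180) + c(0, rnorm(length(t) - 2, 0, 0.02), 0),
                4 * t * sin(10 * pi / 180) + c(0, rnorm(length(t) - 2, 0, 0.02), 0))
  d <- pts2[nrow(pts2), ] - pts2[1, ]
  oracle <- (atan2(d[2], d[1]) * 180 / pi) %% 360
  expect_equal(fit_segment_direction(pts2), oracle, tolerance = 1e-9)
  expect_lt(angular_error(fit_segment_direction(pts2, method = "tls"), 10), 2)
  expect_error(fit_segment_direction(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("segment_trace recovers constructed stroke boundaries", {
  dirs <- c(0, 60, 150, 250, 340)
  tr <- make_stroke_trace(dirs)
  seg <- segment_trace(tr, expected_segments = 5)
  expect_equal(nrow(seg$segments), 5)
  expect_true(seg$valid)
  expect_equal(angular_error(seg$segments$fitted_direction, dirs),
               rep(0, 5), tolerance = 1e-6)
  # single straight stroke
  one <- segment_trace(make_stroke_trace(45))
  expect_equal(nrow(one$segments), 1)
  # smooth circle, no pauses: heading-change cuts give != 5 segments
  th <- seq(0, 2 * pi, length.out = 400)
  circ <- stylus_trace(seq_along(th) / 100, cos(th), sin(th))
  seg_c <- segment_trace(circ, expected_segments = 5)
  expect_false(seg_c$valid)
  expect_gt(nrow(seg_c$segments), 5)
})

test_that("turn detection splits pause-free corners", {
  # two strokes joined without any pause; 90-degree corner
  tr <- make_stroke_trace(c(0, 90), pause = 0)
  seg <- segment_trace(tr)
  expect_equal(nrow(seg$segments), 2)
  expect_equal(angular_error(seg$segments$fitted_direction, c(0, 90)),
               rep(0, 2), tolerance = 1)
})

test_that("score_reproduction scores positionally and flags count mismatches", {
  s <- generate_sequence(17)
  tr <- make_stroke_trace(s$directions)
  seg <- segment_trace(tr, expected_segments = 5)
  sc <- score_reproduction(seg, s)
  expect_true(sc$valid)
  expect_equal(sc$errors, rep(0, 5), tolerance = 1e-6)
  # globally rotated replay: constant error
  rot <- make_stroke_trace(s$directions + 30)
  sc_rot <- score_reproduction(segment_trace(rot), s)
  expect_equal(sc_rot$errors, rep(30, 5), tolerance = 1e-6)
  # 4-segment reproduction vs 5-segment stimulus is invalid
  four <- make_stroke_trace(s$directions[1:4])
  sc4 <- score_reproduction(segment_trace(four), s)
  expect_false(sc4$valid)
  expect_null(sc4$errors)
})

test_that("morey_within_subject_se removes between-subject offsets", {
  base <- matrix(c(1, 2, 3, 2, 3, 4), 2, 3, byrow = TRUE)
  # pure subject offsets: identical profiles -> all SEs zero
  offs <- base + c(0, 10)
  expect_equal(unname(morey_within_subject_se(offs)), rep(0, 3))
  # 2x2 toy table against the hand formula
  tab <- matrix(c(1, 3, 2, 8), 2, 2, byrow = TRUE)  # subjects x conditions
  centered <- tab - rowMeans(tab) + mean(tab)
  hand <- apply(centered, 2, sd) / sqrt(2) * sqrt(2 / 1)
  expect_equal(unname(morey_within_subject_se(tab)), unname(hand))
  expect_error(morey_within_subject_se(tab[, 1, drop = FALSE]), ">= 2")
  tab[1, 1] <- NA
  expect_error(morey_within_subject_se(tab), "missing")
})

test_that("trace CSV round-trips", {
  tr <- make_stroke_trace(c(10, 120))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  tr2 <- read_trace_csv(path)
  expect_equal(tr2$x, tr$x)
  expect_equal(tr2$t, tr$t)
})

test_that("stylus_trace validates its invariants", {
  expect_error(stylus_trace(c(0, 0.1, 0.1), 1:3, 1:3), "increasing")
  expect_error(stylus_trace(0, 1, 1), ">= 2")
})
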