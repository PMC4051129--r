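test_that("rms_normalize yields unit RMS and is scale invariant", {
  v <- c(3, 4)
  out <- rms_normalize(v)
  expect_equal(sqrt(mean(unclass(out)^2)), 1, tolerance = 1e-12)
  expect_equal(unclass(out), v / sqrt(mean(v^2)))        # = v / 3.5355...
  expect_equal(unclass(rms_normalize(10 * v)), unclass(out))
  u <- rms_normalize(rnorm(20))
  expect_equal(unclass(rms_normalize(unclass(u))), unclass(u))  # unit-RMS unchanged
  expect_error(rms_normalize(rep(0, 5)), "all-zero")
})

test_that("window_mean averages the half-open window and resolves aliases", {
  time_ms <- seq(-200, 596, by = 4)
  mk_erp <- function(data) structure(list(data = data, time_ms = time_ms,
                                          sample_rate = 250, n_epochs = 1,
                                          cell = list(),
                                          channels = rownames(data)),
                                     class = "erp")
  const <- matrix(2.5, 2, length(time_ms), dimnames = list(c("A", "B"), NULL))
  expect_equal(unname(window_mean(mk_erp(const), c(396, 448))), c(2.5, 2.5))
  # linear ramp over a window symmetric in sample positions -> midpoint
  ramp <- matrix(time_ms, 1, length(time_ms), byrow = TRUE,
                 dimnames = list("A", NULL))
  sel <- time_ms >= 300 & time_ms < 400
  expect_equal(unname(window_mean(mk_erp(ramp), c(300, 400))),
               mean(time_ms[sel]))
  # Gaussian peak: equals direct summation to machine precision
  g <- matrix(exp(-(time_ms - 420)^2 / 800), 1, length(time_ms),
              dimnames = list("A", NULL))
  sel2 <- time_ms >= 396 & time_ms < 448
  expect_equal(unname(window_mean(mk_erp(g), c(396, 448))),
               sum(g[1, sel2]) / sum(sel2), tolerance = 1e-12)
  # alias resolution through a montage
  hm <- default_montage("hd129")
  erp <- mk_erp(matrix(seq_len(129), 129, length(time_ms),
                       dimnames = list(hm$channels, NULL)))
  wm <- window_mean(erp, c(0, 100), electrodes = c("Fz", "Cz", "Pz"),
                    montage = hm)
  expect_equal(names(wm), c("Fz", "Cz", "Pz"))
  expect_equal(unname(wm["Cz"]), which(hm$channels == "Cz"))
  expect_error(window_mean(erp, c(0, 100), electrodes = "XX", montage = hm),
               "unknown")
  expect_error(window_mean(erp, c(700, 800)), "window")
})

test_that("rm_anova matches the textbook sum-of-squares and Box-epsilon oracle", {
  set.seed(20)
  for (rep in 1:5) {
    y <- array(rnorm(4 * 2 * 3, sd = 2) +
                 rep(rnorm(4, sd = 1), 2 * 3), c(4, 2, 3))
    got <- rm_anova(y)
    want <- oracle_rm_anova(y)
    expect_equal(got$F, unname(want$F), tolerance = 1e-10)
    expect_equal(got$epsilon, unname(want$epsilon), tolerance = 1e-10)
    expect_equal(got$partial_eta_sq, unname(want$pes), tolerance = 1e-10)
    # epsilon bounds; the GG correction is conservative on the side of
    # the F distribution that matters (for small F, shrinking both dfs
    # can lower p, so the direction only holds away from the null bulk)
    expect_true(all(got$epsilon <= 1 + 1e-12))
    conservative <- got$p_uncorrected <= 0.25
    expect_true(all(got$p_gg[conservative] >=
                      got$p_uncorrected[conservative] - 1e-12))
    # 2-level factor: epsilon exactly 1
    expect_equal(got$epsilon[1], 1)
  }
})

test_that("rm_anova handles degenerate structure correctly", {
  set.seed(21)
  y <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  # zero condition effect: identical level means per subject
  y0 <- y
  y0[, 2, ] <- y0[, 1, ]
  got <- rm_anova(y0)
  expect_equal(got$F[1], 0)
  expect_error(rm_anova(array(NA, c(3, 2, 2))), "missing")
  expect_error(rm_anova(y[1, , , drop = FALSE]), ">= 2 subjects")
})

test_that("ANOVA sums of squares decompose the total on balanced tables", {
  set.seed(22)
  y <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  ss <- attr(rm_anova(y), "ss")
  expect_equal(ss[["total"]],
               sum(ss[c("A", "B", "AB", "AS", "BS", "ABS", "subjects")]),
               tolerance = 1e-10)
})

test_that("normalization removes a global gain from all topo statistics", {
  set.seed(23)
  n <- 8
  w1 <- matrix(rnorm(n * 3, mean = 2), n, 3)
  w2 <- matrix(rnorm(n * 3, mean = 1), n, 3)
  build <- function(x1, x2) {
    vals <- array(NA_real_, c(n, 2, 3))
    for (s in seq_len(n)) {
      vals[s, 1, ] <- unclass(rms_normalize(x1[s, ]))
      vals[s, 2, ] <- unclass(rms_normalize(x2[s, ]))
    }
    rm_anova(vals)
  }
  a1 <- build(w1, w2)
  a2 <- build(w1 * 7, w2)    # one condition rescaled by k > 0
  expect_equal(a1$F, a2$F, tolerance = 1e-9)
  expect_equal(a1$p_gg, a2$p_gg, tolerance = 1e-9)
})

test_that("posthoc_paired_t matches the closed form and the t CDF", {
  base <- c(1, 5, 2)
  res <- posthoc_paired_t(base + c(1, 2, 3), base)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(2 * sqrt(3), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # a = b degenerates to t = 0, p = 1
  same <- posthoc_paired_t(base, base)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(posthoc_paired_t(base + 2, base), "zero-variance")
  # paired data scaled to t(11) = 3.700 exactly: p equals the CDF oracle
  set.seed(9)
  d0 <- rnorm(12)
  d <- d0 - mean(d0) + 3.700 * sd(d0) / sqrt(12)
  res12 <- posthoc_paired_t(d, rep(0, 12))
  expect_equal(res12$t, 3.700, tolerance = 1e-12)
  expect_equal(res12$p, 2 * pt(3.700, 11, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(res12$p - 0.003), 1e-3)
})
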