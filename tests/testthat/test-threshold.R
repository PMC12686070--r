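test_that("hinge fit recovers breakpoints and degrades gracefully", {
  t <- seq(0.5, 2, length.out = 40)
  y <- 1 + 2 * t - 2 * pmax(0, t - 1.2)  # slopes 2 then 0, knot 1.2
  h <- fit_hinge(t, y)
  expect_equal(h$psi, 1.2, tolerance = 1e-3)
  expect_equal(h$slope1, 2, tolerance = 1e-6)
  expect_equal(h$slope2, 0, tolerance = 1e-6)
  expect_false(h$degenerate)

  # collinear input: slope change ~0, RSS ~0, degenerate flag
  h2 <- fit_hinge(t, 3 + 0.5 * t)
  expect_true(h2$degenerate)
  expect_lt(h2$rss, 1e-18)
  expect_equal(h2$slope2 - h2$slope1, 0, tolerance = 1e-6)

  # nesting: hinge RSS never exceeds straight-line RSS
  set.seed(7)
  for (i in 1:10) {
    yy <- stats::rnorm(40)
    line_rss <- sum(stats::lm.fit(cbind(1, t), yy)$residuals^2)
    expect_lte(fit_hinge(t, yy)$rss, line_rss + 1e-10)
  }
  expect_error(fit_hinge(t[1:5], y[1:5]), "insufficient")
  expect_error(fit_hinge(rev(t), y), "increasing")
})

test_that("profiled hinge matches exhaustive breakpoint search", {
  set.seed(42)
  for (i in 1:20) {
    sp <- curve_spec("hinge", psi = stats::runif(1, log10(5), log10(60)),
                     b1 = stats::runif(1, 0.5, 3),
                     b2 = stats::runif(1, -0.5, 0.5),
                     noise_sigma = 0.05, seed = i, n_points = 50)
    g <- gen_curve(sp)
    t <- log10(g$curve$x)
    h <- fit_hinge(t, g$curve$y)
    ex <- oracle_hinge_exhaustive(t, g$curve$y, h$window)
    expect_lt(abs(h$psi - ex$psi), ex$step + 1e-12)
  }
})

test_that("classification: noiseless round trips and the margin rule", {
  for (sh in c("flat", "linear", "saturating", "logistic", "hinge")) {
    g <- gen_curve(curve_spec(sh, n_points = 40))
    cl <- classify_response(g$curve$x, g$curve$y)
    expect_identical(cl$shape, sh)
    if (sh %in% c("logistic", "hinge")) {
      expect_equal(cl$x_ter, 16, tolerance = 1e-3)
      expect_gt(cl$delta_best, 2)
    } else {
      expect_true(is.na(cl$x_ter))
    }
    expect_gte(cl$delta_best, 0)
  }
  expect_error(classify_response(1:5, 1:5), "insufficient")
  expect_error(classify_response(c(-1, 2:20), stats::rnorm(20)), "positive")
})

test_that("classification is invariant under ratio inversion (N:P vs P:N)", {
  for (sh in c("hinge", "logistic", "saturating")) {
    g <- gen_curve(curve_spec(sh, noise_sigma = 0.03, seed = 11,
                              n_points = 50))
    cl <- classify_response(g$curve$x, g$curve$y)
    cl_inv <- classify_response(1 / g$curve$x, g$curve$y)
    expect_identical(cl_inv$shape, cl$shape)
    if (is.finite(cl$x_ter))
      expect_equal(cl_inv$x_ter, 1 / cl$x_ter, tolerance = 1e-4)
  }
})

test_that("detect_ter localizes the model TER and flags its absence", {
  est <- exp1_estimates()
  # the two low scenarios carry a nonlinear response with a threshold
  for (nm in c("low_N", "low_P")) {
    expect_true(est[[nm]]$shape %in% c("logistic", "hinge"))
    expect_true(is.finite(est[[nm]]$x_ter))
  }
  # the two high scenarios do not
  for (nm in c("high_N", "high_P")) {
    expect_true(est[[nm]]$shape %in% c("flat", "linear", "saturating"))
    expect_true(is.na(est[[nm]]$x_ter))
    expect_true(is.na(est[[nm]]$y_ter))
  }
  # low-N threshold sits at the Redfield-proportioned consumption ratio
  expect_equal(est$low_N$x_ter, 16, tolerance = 0.125)
  expect_error(detect_ter(data.frame(x = 1:5, y = 1:5)), "insufficient")
  expect_error(detect_ter(data.frame(a = 1:20, b = 1:20)), "missing column")
})

test_that("hinge recovery from noisy data: median error < 5% (sigma 0.01)", {
  errs <- vapply(1:50, function(i) {
    g <- gen_curve(curve_spec("hinge", psi = 1.2, b1 = 2, b2 = 0,
                              noise_sigma = 0.01, seed = 1000 + i,
                              n_points = 40))
    est <- detect_ter(g$curve, attach_switch = FALSE)
    if (!is.finite(est$x_ter)) return(NA_real_)
    abs(est$x_ter - 10^1.2) / 10^1.2
  }, numeric(1))
  expect_lt(stats::median(errs, na.rm = TRUE), 0.05)
})

test_that("mechanistic switch: crossing at the consumption ratio", {
  e1 <- build_experiment1()
  p <- model_params()
  ms_lp <- mechanistic_switch(e1$low_P)
  expect_equal(ms_lp, consumption_np(p), tolerance = 0.15)
  # high-P: the N-to-P switch exists even though GPP shows no threshold
  ms_hp <- mechanistic_switch(e1$high_P)
  expect_true(is.finite(ms_hp))
  expect_equal(ms_hp, consumption_np(p), tolerance = 0.15)
  # symmetric construction m_N/m_P = c_N/c_P: crossing exactly at the
  # consumption ratio (residual nutrients cancel)
  psym <- model_params(m_N = 1.5 * (0.1084 / 0.015), m_P = 1.5)
  ssym <- scenario("sym", psym, "P_in", 15, 200, 700)
  expect_equal(mechanistic_switch(ssym), consumption_np(psym),
               tolerance = 1e-4)
  # no crossing: P so scarce it always limits
  snone <- scenario("none", p, "P_in", 0.5, 2, 700)
  expect_true(is.na(mechanistic_switch(snone)))
})

test_that("sensitivity slopes: round trip, symmetry, scenario contrast", {
  # noiseless hinge with slopes (2, 0)
  g <- gen_curve(curve_spec("hinge", b1 = 2, b2 = 0, n_points = 40))
  est <- detect_ter(g$curve, attach_switch = FALSE)
  expect_equal(est$slope_below, 2, tolerance = 0.01)
  expect_equal(est$slope_above, 0, tolerance = 0.01)
  sl <- sensitivity_slopes(est, g$curve)
  expect_equal(unname(sl), c(est$slope_below, est$slope_above))

  # symmetric tent: slope_below = -slope_above
  x <- 10^seq(0.5, 2.1, length.out = 41)
  t <- log10(x)
  tent <- data.frame(x = x, y = 3 - abs(t - 1.3))
  est_t <- detect_ter(tent, attach_switch = FALSE)
  expect_equal(est_t$slope_below, -est_t$slope_above, tolerance = 1e-6)

  # nutrient-limited limb steeper than the plateau limb
  est1 <- exp1_estimates()
  expect_gt(abs(est1$low_N$slope_below), abs(est1$low_N$slope_above))
  expect_gt(abs(est1$low_P$slope_above), abs(est1$low_P$slope_below))
  expect_error(sensitivity_slopes(est1$high_P, exp1_curves()$high_P),
               "absent")
})
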