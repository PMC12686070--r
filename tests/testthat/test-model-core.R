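test_that("monod term: half-saturation, zero, limits, errors", {
  expect_equal(monod(1.5, 1.5), 0.5)
  expect_equal(monod(0, 3), 0)
  expect_equal(monod(0.7, 0.7), 0.5)
  expect_error(monod(1, 0), "halfsat")
  expect_error(monod(-1, 1), "non-negative")
  # strictly increasing, saturating to 1
  cc <- seq(0, 1e6, length.out = 50)
  expect_true(all(diff(monod(cc, 2)) > 0))
  expect_equal(monod(1e9, 2), 1, tolerance = 1e-8)
})

test_that("light limitation: limit identities and quadrature oracle", {
  # h_I -> 0: the log ratio equals k*z exactly, so f_I -> 1
  p <- model_params(h_I = 1e-12)
  expect_equal(light_limitation(500, p), 1, tolerance = 1e-9)
  # A = 0, k_bg -> 0: no attenuation, surface Monod I/(h_I + I)
  p2 <- model_params(k_bg = 1e-9)
  expect_equal(light_limitation(0, p2), p2$I_in / (p2$h_I + p2$I_in),
               tolerance = 1e-6)
  # closed form agrees with brute-force depth averaging to 4 decimals
  p3 <- model_params(k_bg = 0.2, k_A = 0.0008, z_max = 2.5, I_in = 300,
                     h_I = 120)
  expect_equal(light_limitation(2000, p3),
               oracle_light(2000, 300, 120, 0.2, 0.0008, 2.5),
               tolerance = 5e-5)
  # strictly decreasing in biomass
  A <- seq(0, 2e4, length.out = 60)
  expect_true(all(diff(light_limitation(A, model_params())) < 0))
  expect_true(all(light_limitation(A, model_params()) > 0))
})

test_that("growth factors: Liebig argmin with fixed tie order N < P < light", {
  p <- model_params()
  # exact N/P tie at half saturation (light not binding): N wins the label
  gf <- growth_factors(list(A = 1e-6, N = p$m_N, P = p$m_P), p)
  expect_equal(gf$f_N, 0.5)
  expect_equal(gf$f_P, 0.5)
  expect_gt(gf$f_I, 0.5)
  expect_identical(gf$limiter, "N")
  # approximate three-way tie: growth rate is tie-break independent
  A_half <- stats::uniroot(function(A) light_limitation(A, p) - 0.5,
                           c(1, 1e5))$root
  gf3 <- growth_factors(list(A = A_half, N = p$m_N, P = p$m_P), p)
  expect_equal(gf3$f_I, 0.5, tolerance = 1e-6)
  expect_equal(min(gf3$f_N, gf3$f_P, gf3$f_I), 0.5, tolerance = 1e-6)
  # P exhausted, light off
  p_dark_off <- model_params(h_I = 1e-12)
  gf2 <- growth_factors(list(A = 10, N = 1e9, P = 0), p_dark_off)
  expect_identical(gf2$limiter, "P")
  expect_equal(gf2$f_P, 0)
})

test_that("rhs: no-biomass dilution, mass balance terms, error on NaN", {
  p <- model_params()
  sup <- supply(700, 30)
  d <- lake_rhs(list(A = 0, N = 100, P = 10), p, sup)
  expect_equal(unname(d["dA"]), 0)
  expect_equal(unname(d["dN"]), p$a * (700 - 100))
  expect_equal(unname(d["dP"]), p$a * (30 - 10))
  # direct substitution at N = N_in, P = P_in, A = 1
  gf <- growth_factors(list(A = 1, N = 700, P = 30), p)
  mu <- p$mu_max * min(gf$f_N, gf$f_P, gf$f_I)
  d2 <- lake_rhs(list(A = 1, N = 700, P = 30), p, sup)
  expect_equal(unname(d2["dN"]), -p$c_N * mu)
  expect_equal(unname(d2["dP"]), -p$c_P * mu)
})

test_that("solve_steady_state: washout, closed-form chemostat, mu = a", {
  # dilution exceeding max growth washes out and leaves pure dilution
  p_wo <- suppressWarnings(model_params(a = 1.2))
  ss <- solve_steady_state(p_wo, supply(700, 30))
  expect_true(ss$washout)
  expect_equal(ss$gpp, 0)
  expect_equal(ss$state[["N"]], 700, tolerance = 1e-4)
  expect_equal(ss$state[["P"]], 30, tolerance = 1e-4)

  # forced f_I = 1, P limiting: R* rule + mass balance
  p <- model_params(h_I = 1e-12, mu_max = 1.0, a = 0.1, m_P = 1.5,
                    c_P = 0.015)
  ss2 <- solve_steady_state(p, supply(1e9, 100), tol = 1e-8)
  P_star <- 1.5 * 0.1 / (1.0 - 0.1)
  A_star <- (100 - P_star) / 0.015
  expect_equal(ss2$state[["P"]], P_star, tolerance = 1e-3)
  expect_equal(ss2$state[["A"]], A_star, tolerance = 1e-3)
  expect_equal(ss2$limiter, "P")

  # growth balances dilution at any converged non-washout state
  tol <- 1e-6
  for (sup in list(supply(700, 30), supply(100, 80), supply(5000, 300))) {
    s <- solve_steady_state(model_params(), sup, tol = tol)
    expect_true(s$converged)
    expect_false(s$washout)
    expect_lt(abs(s$mu - 0.1), 10 * tol)
    # rhs ~ 0 at the stored steady state (R-side rhs, C++-side integration)
    d <- lake_rhs(as.list(s$state), model_params(), sup)
    expect_lt(max(abs(d) / (abs(s$state) + 1e-6)), 2 * tol)
  }
  # precondition checks
  expect_error(solve_steady_state(model_params(), supply(1, 1), t_max = 100),
               "t_max")
  expect_error(solve_steady_state(model_params(), supply(1, 1), tol = 0.1),
               "tol")
})

test_that("gpp conversion: washout zero, arithmetic, linearity in o2_per_c", {
  p <- model_params()
  ss <- list(mu = 0.1, state = c(A = 6655.556), washout = FALSE)
  expect_equal(gpp_from_state(ss, p), 0.1 * 6655.556 * (32 / 12) / 1000,
               tolerance = 1e-12)
  expect_equal(gpp_from_state(ss, p), 1.775, tolerance = 1e-3)
  p2 <- model_params(o2_per_c = 2 * 32 / 12)
  expect_equal(gpp_from_state(ss, p2), 2 * gpp_from_state(ss, p))
  ss_wo <- list(mu = 0.1, state = c(A = 0), washout = TRUE)
  expect_equal(gpp_from_state(ss_wo, p), 0)
})

test_that("mass balance holds at converged steady states (rel 1e-4)", {
  p <- model_params()
  for (sup in list(supply(700, 30), supply(700, 96), supply(7000, 500))) {
    ss <- solve_steady_state(p, sup, tol = 1e-7)
    A <- ss$state[["A"]]
    lhs_N <- p$a * (sup$N_in - ss$state[["N"]])
    lhs_P <- p$a * (sup$P_in - ss$state[["P"]])
    expect_equal(lhs_N, p$c_N * ss$mu * A, tolerance = 1e-4)
    expect_equal(lhs_P, p$c_P * ss$mu * A, tolerance = 1e-4)
    # gpp = 0 iff washout
    expect_true(xor(ss$gpp > 0, ss$washout))
  }
})

test_that("integrator agrees with root-finding oracle on random draws", {
  set.seed(101)
  dflt <- model_params()
  tune <- c("mu_max", "a", "z_max", "m_N", "m_P", "c_N", "c_P", "I_in",
            "h_I", "k_bg", "k_A")
  n_checked <- 0
  for (i in 1:20) {
    ov <- lapply(dflt[tune], function(v) v * stats::runif(1, 0.5, 1.5))
    p <- suppressWarnings(do.call(model_params, ov))
    sup <- supply(stats::runif(1, 100, 2000), stats::runif(1, 20, 300))
    ss <- suppressWarnings(solve_steady_state(p, sup, tol = 1e-8))
    or <- oracle_steady(p, sup$N_in, sup$P_in)
    expect_identical(ss$washout, or$washout)
    if (!or$washout) {
      expect_equal(ss$state[["A"]], or$A, tolerance = 1e-3)
      expect_equal(ss$state[["N"]], or$N, tolerance = 1e-3)
      expect_equal(ss$state[["P"]], or$P, tolerance = 1e-3)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 10)  # the draw box should mostly avoid washout
})

test_that("droop variant: subsistence quota, quota equilibrium, rigid limit", {
  dp <- droop_params()
  sup <- supply(700, 30)
  # at subsistence quota growth stops regardless of light
  d <- suppressWarnings(
    droop_rhs(list(A = 10, N = 700, P = 30, Q_N = dp$Qmin_N,
                   Q_P = dp$Qmin_P), dp, sup))
  expect_equal(unname(d["dA"]), -dp$a * 10)
  expect_warning(
    droop_rhs(list(A = 10, N = 700, P = 30, Q_N = dp$Qmin_N / 2,
                   Q_P = 2 * dp$Qmin_P), dp, sup),
    "subsistence")
  # constant-environment equilibrium: v_X = mu * Q_X
  ss <- solve_steady_state(dp, sup, variant = "droop", tol = 1e-8)
  v_N <- dp$vmax_N * monod(ss$state[["N"]], dp$m_N)
  v_P <- dp$vmax_P * monod(ss$state[["P"]], dp$m_P)
  expect_equal(v_N, ss$mu * ss$state[["Q_N"]], tolerance = 1e-4)
  expect_equal(v_P, ss$mu * ss$state[["Q_P"]], tolerance = 1e-4)
  expect_error(droop_rhs(list(A = 1, N = 1, P = 1), model_params(), sup),
               "droop_params")

  # rigid-quota limit reproduces the fixed-quota curve within 5%
  p <- model_params()
  rig <- droop_params(p, mu_inf = 40, Qmin_N = p$c_N, Qmin_P = p$c_P,
                      vmax_N = 50 * p$c_N, vmax_P = 50 * p$c_P)
  s_fix <- scenario("lowP", p, "P_in", 15, 200, 700, n_points = 25)
  s_dro <- scenario("lowP_d", rig, "P_in", 15, 200, 700, n_points = 25)
  gf <- run_gradient(s_fix)
  gd <- run_gradient(s_dro, variant = "droop")
  expect_lt(max(abs(gd$gpp - gf$gpp) / gf$gpp), 0.05)
})
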