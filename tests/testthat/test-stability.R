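# steady states reused across the stability tests
cfg1 <- scenario_preset("case_5_1")
cfg2 <- scenario_preset("case_5_2")
cfg3 <- scenario_preset("case_5_3")
ss1 <- solve_steady_state(cfg1$grid, cfg1$macro, cfg1$cycle)
ss2 <- solve_steady_state(cfg2$grid, cfg2$macro, cfg2$cycle)   # trivial
ss3 <- solve_steady_state(cfg3$grid, cfg3$macro, cfg3$cycle)   # trivial

test_that("the renewal kernel is nonnegative and vanishes without division", {
  g <- age_grid(50, 0.5)
  mp0 <- macro_transport_only(mu_p = 0.001, mu_q = 0.001)
  ss0 <- solve_steady_state(g, mp0, cycle_params())
  zet <- seq(0, 50, by = 5)
  expect_equal(max(abs(kernel_G(0, zet, zet, ss0, mp0))), 0,
               tolerance = 1e-100)
  for (lam in c(-0.01, 0, 0.5, 5))
    expect_true(all(kernel_G(lam, zet, rev(zet), ss2, cfg2$macro) >= 0))
})

test_that("the rank-one structure gives the spectral radius as the kernel trace", {
  g <- ss2$grid
  tr <- sum(g$weights * kernel_G(0, g$nodes, g$nodes, ss2, cfg2$macro))
  expect_equal(spectral_radius_U(0, ss2, cfg2$macro, "continuous"), tr,
               tolerance = 1e-10)
  # and at lambda = 0 it is the reproduction number
  expect_equal(spectral_radius_U(0, ss2, cfg2$macro, "upwind"),
               reproduction_number(0, g, cfg2$macro, cfg2$cycle, "upwind"),
               tolerance = 1e-12)
})

test_that("r(U_lambda) is strictly decreasing and decays to zero", {
  lams <- c(-0.02, 0, 0.05, 0.2, 1, 10, 100)
  rs <- vapply(lams, spectral_radius_U, numeric(1),
               steady = ss2, mp = cfg2$macro)
  expect_true(all(diff(rs) < 0))
  expect_lt(rs[lams == 10], rs[lams == 0])
  expect_lt(rs[lams == 100], 1e-3 * rs[lams == 0])
})

test_that("lambda0 obeys the sign rule and solves r = 1 tightly", {
  for (x in list(list(ss = ss1, mp = cfg1$macro),
                 list(ss = ss2, mp = cfg2$macro),
                 list(ss = ss3, mp = cfg3$macro))) {
    r0 <- spectral_radius_U(0, x$ss, x$mp)
    gb <- growth_bound_lambda0(x$ss, x$mp)
    expect_lt(abs(gb$r_at_root - 1), 1e-8)
    if (abs(r0 - 1) > 1e-6)
      expect_identical(sign(gb$lambda0), sign(r0 - 1))
    else
      expect_lt(abs(gb$lambda0), 1e-8)
  }
})

test_that("lambda0 is an eigenvalue of the discretized generator", {
  for (x in list(list(ss = ss1, mp = cfg1$macro, cp = cfg1$cycle),
                 list(ss = ss2, mp = cfg2$macro, cp = cfg2$cycle))) {
    rep <- classify_stability(x$ss, x$mp, x$cp)
    expect_lt(rep$agreement, 1e-8)
    # the dominant eigenvalue is real
    expect_lt(abs(rep$dominant_imag), 1e-6 * max(1, abs(rep$sC_estimate)))
  }
})

test_that("the generator cross-check tightens under grid refinement", {
  agree_at <- function(da) {
    g <- age_grid(50, da)
    ss <- solve_steady_state(g, cfg2$macro, cfg2$cycle)
    gb <- growth_bound_lambda0(ss, cfg2$macro)
    C <- linearized_generator(ss, cfg2$macro)
    sC <- max(Re(eigen(C, only.values = TRUE)$values))
    abs(gb$lambda0 - sC)
  }
  a1 <- agree_at(1.0)
  a2 <- agree_at(0.5)
  expect_lte(a2, a1 + 1e-10)
  expect_lt(a2, 1e-8)
})

test_that("verdicts match the case-study phenomenology", {
  rep2 <- classify_stability(ss2, cfg2$macro, cfg2$cycle)
  expect_identical(rep2$verdict, "stable")
  rep3 <- classify_stability(ss3, cfg3$macro, cfg3$cycle)
  expect_identical(rep3$verdict, "unstable")
  # the solved nontrivial state sits exactly on r(U_0) = 1
  rep1 <- classify_stability(ss1, cfg1$macro, cfg1$cycle)
  expect_identical(rep1$verdict, "marginal")
})

test_that("lambda0 predicts the early exponential growth of a sparse population", {
  # seed the unstable scenario far below the half-saturation population so
  # the trivial-state linearization applies, and compare growth rates
  cfg <- scenario_preset("case_5_3", t_end = 250)
  cfg$initial$k0 <- 100
  res <- run_simulation(cfg)
  sel <- res$times >= 100                 # past the initial transient
  slope <- coef(lm(log(res$N[sel]) ~ res$times[sel]))[2]
  lam0 <- growth_bound_lambda0(ss3, cfg3$macro)$lambda0
  expect_gt(lam0, 0)
  expect_gt(slope, lam0 / 2)
  expect_lt(slope, lam0 * 2)
})

test_that("inadmissible spectral parameters are rejected", {
  edge <- -(ss2$gamma_bar + 0.020)
  expect_error(spectral_radius_U(edge - 0.01, ss2, cfg2$macro),
               "admissible")
})
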