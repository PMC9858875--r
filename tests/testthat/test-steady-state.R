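test_that("survival profile starts at 1 and is flat without losses", {
  g <- age_grid(50, 0.5)
  mp <- macro_transport_only()          # tau, chi, mu all ~ 0
  Pi <- survival_profile(1e6, g, mp, cycle_params())
  expect_identical(Pi[1], 1)
  expect_equal(Pi, rep(1, 101), tolerance = 1e-12)
})

test_that("survival profile matches a refined quadrature oracle", {
  # on a grid fine enough to resolve the chi switching window, the
  # cumulative-trapezoid profile must agree with an oracle built on an
  # 8-fold finer quadrature of the same integrand
  mp <- macro_params(mu_p = 0.0014, mu_q = 0.0014, rho1 = 1.0)
  cp <- cycle_params()
  N_bar <- 1e8
  g <- age_grid(50, 0.01)
  Pi <- survival_profile(N_bar, g, mp, cp)
  expect_true(all(diff(Pi) <= 0))

  afine <- seq(0, 50, by = 0.01 / 8)
  gam <- gamma_of_N(N_bar, mp)
  x1f <- integrate_cycle(growth_factor(N_bar, mp), cp, afine)$states[, "x1"]
  Lf <- chi_of_age_cyclin(afine, x1f, mp) * mp$mu_q(afine) /
    (gam + mp$mu_q(afine)) + tau_of_age(afine, mp) + mp$mu_p(afine)
  Ef <- c(0, cumsum(diff(afine) * (head(Lf, -1) + tail(Lf, -1)) / 2))
  Pi_ref <- exp(-Ef[match(round(g$nodes, 10), round(afine, 10))])
  expect_lt(max(abs(Pi - Pi_ref) / Pi_ref), 1e-4)
})

test_that("reproduction number behaves as a renewal count", {
  g <- age_grid(50, 0.5)
  cp <- cycle_params()
  mp0 <- macro_transport_only()         # tau ~ 0 -> R ~ 0
  expect_lt(reproduction_number(1e6, g, mp0, cp), 1e-12)

  # decaying scenario: the trivial state does not reproduce itself
  c2 <- scenario_preset("case_5_2")
  expect_lt(reproduction_number(0, c2$grid, c2$macro, c2$cycle), 1)

  # upwind and continuous rules agree on a fine grid
  mp <- macro_params(rho1 = 1.0)
  gf <- age_grid(50, 0.002)
  expect_equal(reproduction_number(1e8, gf, mp, cp, "upwind"),
               reproduction_number(1e8, gf, mp, cp, "continuous"),
               tolerance = 1e-3)
})

test_that("a division-free model only has the trivial steady state", {
  g <- age_grid(50, 0.5)
  ss <- solve_steady_state(g, macro_transport_only(mu_p = 0.001,
                                                   mu_q = 0.001),
                           cycle_params())
  expect_true(ss$trivial)
  expect_identical(ss$N_bar, 0)
})

test_that("the solved steady state satisfies its defining identities", {
  cfg <- scenario_preset("case_5_1")
  ss <- solve_steady_state(cfg$grid, cfg$macro, cfg$cycle)
  expect_false(ss$trivial)
  expect_lt(abs(ss$residuals$R_minus_1), 1e-8)
  expect_lt(ss$residuals$mass, 1e-6)
  expect_lt(ss$residuals$ode_sup, cfg$grid$da)

  # the algebraic quiescent balance holds exactly at every node
  a <- cfg$grid$nodes
  chiv <- chi_of_age_cyclin(a, ss$x_bar$states[, "x1"], cfg$macro)
  lhs <- chiv * ss$p_bar - (ss$gamma_bar + cfg$macro$mu_q(a)) * ss$q_bar
  expect_equal(lhs, numeric(101), tolerance = 1e-12 * max(ss$p_bar))

  expect_true(all(ss$p_bar >= 0) && all(ss$q_bar >= 0))
  expect_equal(ss$p_bar[1], ss$p0_bar)
})

test_that("the steady state is an equilibrium of the simulated dynamics", {
  cfg <- scenario_preset("case_5_1", t_end = 500)
  ss <- solve_steady_state(cfg$grid, cfg$macro, cfg$cycle)
  cfg$initial <- list(type = "profile", q = ss$q_bar, p = ss$p_bar)
  res <- run_simulation(cfg)
  expect_lt(max(abs(res$N - ss$N_bar)) / ss$N_bar, 0.05)
})
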