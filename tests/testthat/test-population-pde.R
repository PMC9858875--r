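test_that("age grid and quadrature weights are well formed", {
  g <- age_grid(50, 0.5)
  expect_length(g$nodes, 101)
  expect_identical(g$nodes[1], 0)
  expect_identical(g$nodes[101], 50)
  expect_equal(sum(g$weights), 50)
  expect_error(age_grid(50, 0.7), "divide")
})

test_that("total population integrates q + p exactly for constants", {
  g <- age_grid(50, 0.5)
  st0 <- population_state(0, numeric(101), numeric(101), g)
  expect_identical(total_population(st0), 0)
  st <- population_state(0, rep(2, 101), rep(3, 101), g)
  expect_equal(total_population(st), 5 * 50)
})

test_that("total population of the Gaussian fixture matches fine quadrature", {
  g <- age_grid(50, 0.5)
  prof <- make_gaussian_profile(gaussian_profile_spec(1e6, 2, 200), g)
  st <- population_state(0, prof, prof, g)
  afine <- seq(0, 50, by = 0.5 / 64)
  ref <- 2 * trapz_ref(afine, gaussian_density(afine))
  expect_equal(total_population(st), ref, tolerance = 1e-3)
  # and the analytic normal mass inside [0, 50]
  mass <- 1e6 * (pnorm(50, 2, sqrt(200)) - pnorm(0, 2, sqrt(200)))
  expect_equal(total_population(st), 2 * mass, tolerance = 1e-3)
})

test_that("renewal boundary value reproduces the division integral", {
  g <- age_grid(50, 0.5)
  mp <- macro_params()
  expect_identical(renewal_boundary(numeric(101), g, mp), 0)
  # Gaussian profile against a Richardson-refined quadrature oracle
  p <- gaussian_density(g$nodes)
  afine <- seq(0, 50, by = 0.5 / 64)
  ref <- 2 * trapz_ref(afine, tau_of_age(afine, mp) * gaussian_density(afine))
  expect_equal(renewal_boundary(p, g, mp), ref, tolerance = 1e-3)
})

test_that("upwind transport at unit Courant number is exact advection", {
  g <- age_grid(50, 0.5)
  mp <- macro_transport_only()
  p0 <- bump_profile(g)
  st <- population_state(0, bump_profile(g, 30), p0, g)
  nstep <- 20L
  for (k in seq_len(nstep))
    st <- advance_step(st, g$da, numeric(101), 0, mp)  # dt = da, g = 1
  shifted <- c(numeric(nstep), p0[1:(101 - nstep)])
  expect_equal(st$p, shifted, tolerance = 1e-13)
  expect_equal(st$q, bump_profile(g, 30), tolerance = 1e-13)
})

test_that("decoupled decay multiplies the advected profile by (1 - mu dt)^k", {
  # on a locally constant profile the advected value equals the local one,
  # so the explicit step reduces to exact decay by (1 - mu dt) per step
  g <- age_grid(50, 0.5)
  mu <- 0.05
  mp <- macro_transport_only(mu_p = mu)
  st <- population_state(0, numeric(101), rep(1, 101), g)
  nstep <- 10L
  # the sharp empty-inflow front undershoots at unit Courant and is
  # clipped; nodes beyond the front are unaffected
  for (k in seq_len(nstep))
    suppressWarnings(st <- advance_step(st, g$da, numeric(101), 0, mp))
  idx <- (nstep + 2):101     # nodes not yet reached by the empty inflow
  expect_equal(st$p[idx], rep((1 - mu * g$da)^nstep, length(idx)),
               tolerance = 1e-12)
  # first-order consistency with the exponential decay factor
  expect_equal((1 - mu * g$da)^nstep, exp(-mu * nstep * g$da),
               tolerance = mu * g$da)
})

test_that("one upwind step agrees with the characteristics solution", {
  cfg <- scenario_preset("case_5_1")
  g <- cfg$grid
  mp <- cfg$macro
  q0 <- make_gaussian_profile(gaussian_profile_spec(1e6, 2, 200), g)
  st <- population_state(0, q0, q0, g)
  N <- total_population(st)
  x1 <- integrate_cycle(growth_factor(N, mp), cfg$cycle, g$nodes)$states[, "x1"]
  chiv <- chi_of_age_cyclin(g$nodes, x1, mp)
  gam <- gamma_of_N(N, mp)
  dt <- cfg$dt
  st1 <- advance_step(st, dt, chiv, gam, mp)

  # frozen-coefficient method of characteristics over one step (g == 1):
  # p(a, dt) = p0(a - dt) exp(-loss dt) + dt gamma q0(a) to leading order
  a <- g$nodes
  loss <- tau_of_age(a, mp) + chiv + mp$mu_p(a)
  p_moc <- gaussian_density(a - dt) * exp(-loss * dt) + dt * gam * q0
  idx <- 2:101
  expect_lt(max(abs(st1$p[idx] - p_moc[idx])) / max(p_moc), 1e-3)
})

test_that("a CFL-violating step is rejected before any computation", {
  g <- age_grid(50, 0.5)
  st <- population_state(0, numeric(101), numeric(101), g)
  expect_error(advance_step(st, 0.6, numeric(101), 0, macro_params()),
               "CFL")
  expect_error(simulation_config(dt = 0.6), "CFL")
})

test_that("mass is conserved when division, death and outflow are absent", {
  g <- age_grid(50, 0.5)
  mp <- macro_transport_only()
  q <- bump_profile(g, 22, 2)
  p <- bump_profile(g, 20, 2)
  st <- population_state(0, q, p, g)
  m0 <- total_population(st)
  chiv <- rep(0.3, 101)
  for (k in seq_len(20))                  # 10 h; bump tails stay inside
    st <- advance_step(st, g$da, chiv, 0.2, mp)
  expect_equal(total_population(st), m0, tolerance = 1e-12)
})

test_that("positivity is preserved from nonnegative data under case-study rates", {
  cfg <- scenario_preset("case_5_1", t_end = 40)   # 2000 explicit steps
  res <- run_simulation(cfg)
  expect_true(all(res$N >= 0))
  expect_true(all(res$final_state$q >= 0))
  expect_true(all(res$final_state$p >= 0))
})

test_that("refining the grid shows first-order convergence of N(t)", {
  Nat <- function(da, dt) {
    cfg <- simulation_config(
      macro = macro_params(mu_p = 0.0014, mu_q = 0.0014, rho1 = 1.0),
      grid = age_grid(50, da), dt = dt, t_end = 20,
      refresh = list(policy = "on_gf_change", tol = 1e-6))
    res <- run_simulation(cfg)
    res$N[length(res$N)]
  }
  n1 <- Nat(0.5, 0.02)
  n2 <- Nat(0.25, 0.01)
  n3 <- Nat(0.125, 0.005)
  ratio <- abs(n1 - n2) / abs(n2 - n3)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 3)
})
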