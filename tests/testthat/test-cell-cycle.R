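cp_tab <- cycle_params()

test_that("cycle right-hand side matches the written equations", {
  # empty cell, no growth factor: only the basal synthesis terms remain
  expect_equal(cycle_rhs(c(0, 0, 0, 0), 0, cp_tab),
               c(0, 0, cp_tab$k3s, cp_tab$k4s))
  # Cyclin synthesis term at gf = 1
  expect_equal(cycle_rhs(c(0, 0, 0, 0), 1, cp_tab)[1], 0.155 * 1 / 1.1)
  # E2F activation carries a factor x1
  s <- c(0, 0.4, 1.1, 0.2)
  expect_equal(cycle_rhs(s, 0.5, cp_tab)[2],
               -cp_tab$k32 * s[2] * s[3] - cp_tab$k2d * s[2])
  expect_error(cycle_rhs(c(0, 3, 0, 0), 1, cp_tab), "x2t")
  expect_error(cycle_rhs(c(-1, 0, 0, 0), 1, cp_tab), "nonnegative")
})

test_that("without growth factor Cyclin D-CDK4/6 never appears", {
  tr <- integrate_cycle(0, cp_tab, seq(0, 50, by = 0.5))
  expect_true(all(tr$states[, "x1"] == 0))
})

test_that("with negligible Rb coupling x3 follows its linear closed form", {
  cp <- cycle_params(k32 = 1e-12, k31 = 1e-12)
  ages <- seq(0, 50, by = 0.5)
  tr <- integrate_cycle(1, cp, ages)
  x3_exact <- cp$k3s / cp$k3d * (1 - exp(-cp$k3d * ages))
  expect_equal(tr$states[, "x3"], x3_exact, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("trajectory matches an independent adaptive integrator", {
  ages <- seq(0, 50, by = 0.5)
  tr <- integrate_cycle(1, cp_tab, ages)
  kv <- unlist(unclass(cp_tab))
  rhs <- function(t, x, parms) {
    list(c(kv[1] * 1 / (kv[2] + 1) - kv[3] * x[4] * x[1] -
             kv[4] * x[1] / (kv[5] + x[1]),
           kv[6] * x[1] * (kv[8] - x[2]) / (kv[7] + (kv[8] - x[2])) -
             kv[9] * x[2] * x[3] - kv[10] * x[2],
           kv[11] - kv[9] * x[2] * x[3] -
             kv[12] * x[1] * x[3] / (kv[13] + x[3]) - kv[14] * x[3],
           kv[15] + kv[16] * x[2] * kv[17] / (kv[17] + x[3]) -
             kv[18] * x[1] * x[4] / (kv[19] + x[4]) - kv[20] * x[4]))
  }
  ref <- deSolve::ode(c(0, 0, 0, 0), ages, rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)[, 2:5]
  rel <- abs(tr$states - ref) / (abs(ref) + 1e-8)
  expect_lt(max(rel), 1e-6)
})

test_that("the solution is resolution-independent at the default substep", {
  ages <- seq(0, 50, by = 0.5)
  a1 <- integrate_cycle(0.7, cp_tab, ages, hmax = 0.025)$states
  a2 <- integrate_cycle(0.7, cp_tab, ages, hmax = 0.0125)$states
  expect_lt(max(abs(a1 - a2) / (abs(a2) + 1e-10)), 1e-6)
})

test_that("trajectories stay nonnegative for all growth-factor levels", {
  ages <- seq(0, 50, by = 0.5)
  for (gf in seq(0, 1, by = 0.1)) {
    expect_silent(tr <- integrate_cycle(gf, cp_tab, ages))
    expect_true(all(tr$states >= 0))
    expect_true(all(tr$states[, "x2"] <= cp_tab$x2t))
  }
})

test_that("Cyclin response separates growth-factor regimes at the restriction threshold", {
  mp <- macro_params()
  ages <- seq(0, 50, by = 0.5)
  peaks <- vapply(c(0.01, 0.1, 0.5, 1),
                  function(gf) max(integrate_cycle(gf, cp_tab, ages)$states[, "x1"]),
                  numeric(1))
  expect_true(all(diff(peaks) > 0))       # response increasing in gf
  expect_lt(peaks[1], mp$sigma2)          # starved cells stay below threshold
  expect_gt(peaks[4], mp$sigma2)          # gf-rich cells cross it
})

test_that("compiled and reference engines agree", {
  ages <- seq(0, 50, by = 0.5)
  a <- integrate_cycle(0.4, cp_tab, ages, engine = "compiled")$states
  b <- integrate_cycle(0.4, cp_tab, ages, engine = "r")$states
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("invalid trajectory requests are rejected", {
  expect_error(integrate_cycle(1.5, cp_tab, seq(0, 10, 0.5)), "\\[0, 1\\]")
  expect_error(integrate_cycle(0.5, cp_tab, c(1, 2)), "start at 0")
  expect_error(integrate_cycle(0.5, cp_tab, c(0, 0.5, 0.4)),
               "strictly increasing")
})
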