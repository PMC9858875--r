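# Steady states of the coupled system.
#
# At a steady state the quiescent balance is algebraic,
#   q(a) = chi(a, x1(a)) p(a) / (gamma(N) + mu_q(a)),
# and substituting it into the proliferating equation leaves a linear ODE in
# age for g(a) p(a) whose solution is p(0) times a survival profile Pi(a).
# Self-consistency of the division (renewal) boundary value then requires
# the reproduction number R(N) = (2/g(0)) int tau Pi da to equal 1, a scalar
# root-finding problem in the total population N.

# effective per-age loss rate of the proliferating cohort at steady state:
# division + proliferative death + switching that ends in quiescent death
# (a cell diverted by chi returns with probability gamma/(gamma+mu_q))
steady_loss_rate <- function(N_bar, grid, mp, cp, lambda = 0) {
  a <- grid$nodes
  gam <- gamma_of_N(N_bar, mp)
  gfb <- growth_factor(N_bar, mp)
  x1 <- integrate_cycle(gfb, cp, a)$states[, "x1"]
  chiv <- chi_of_age_cyclin(a, x1, mp)
  muq <- mp$mu_q(a)
  if (any(lambda + gam + muq <= 0))
    stop("singular denominator: lambda + gamma(N) + mu_q vanishes at age ",
         a[which(lambda + gam + muq <= 0)[1]])
  list(L = lambda + tau_of_age(a, mp) + chiv + mp$mu_p(a) -
         gam * chiv / (lambda + gam + muq),
       gam = gam, gf = gfb, x1 = x1, chi = chiv, muq = muq)
}

# survival factors on the grid under the two discretizations; both equal
# g(0) p(a) / (g(0) p(0)) * g(a)/g(0) ... i.e. p(a)/p(0)
survival_factors <- function(N_bar, grid, mp, cp, lambda = 0,
                             discretization = c("upwind", "continuous")) {
  discretization <- match.arg(discretization)
  a <- grid$nodes
  g <- mp$g(a)
  ls <- steady_loss_rate(N_bar, grid, mp, cp, lambda)
  if (discretization == "continuous") {
    E <- pracma::cumtrapz(a, ls$L / g)[, 1]
    S <- (g[1] / g) * exp(-E)
  } else {
    # exact per-cell survival of the first-order upwind scheme:
    # g_i p_i = g_{i-1} p_{i-1} / (1 + da * L_i / g_i)
    f <- 1 / (1 + grid$da * ls$L / g)
    S <- (g[1] / g) * cumprod(c(1, f[-1]))
  }
  c(ls, list(S = S))
}

#' Steady-state survival profile Pi(a)
#'
#' The normalized proliferating-cell age profile at a candidate steady
#' population `N_bar`:
#' \deqn{\Pi(a) = \exp\left(-\int_0^a \frac{1}{g(\xi)}\Big[g'(\xi) +
#'   \frac{\chi(\xi, x_1(\xi))\,\mu_q(\xi)}{\gamma(\bar N)+\mu_q(\xi)} +
#'   \tau(\xi) + \mu_p(\xi)\Big] d\xi\right)}
#' with the Cyclin profile `x1` obtained from [integrate_cycle()] at
#' `growth_factor(N_bar)`. `Pi(0) = 1`; `Pi` is nonincreasing when
#' `g' >= 0`. Integrals are cumulative trapezoids on the grid; `g'` is
#' obtained analytically for constant `g` (zero) and by central differences
#' otherwise.
#'
#' @param N_bar candidate steady total population (cells), `>= 0`.
#' @param grid an [age_grid()].
#' @param mp a [macro_params()] object.
#' @param cp a [cycle_params()] object.
#' @return numeric vector `Pi(a)` on the grid nodes.
#' @export
survival_profile <- function(N_bar, grid, mp, cp) {
  stopifnot(N_bar >= 0)
  survival_factors(N_bar, grid, mp, cp, 0, "continuous")$S
}

#' Reproduction number R(N)
#'
#' Expected number of newborn proliferating cells produced per newborn cell
#' over its life, at the frozen population size `N_bar`:
#' `R = (2/g(0)) * int tau(a) Pi(a) da`. A nontrivial steady state requires
#' `R(N_bar) = 1`.
#'
#' @inheritParams survival_profile
#' @param discretization `"upwind"` (default) evaluates the survival
#'   profile by the product rule of the first-order upwind scheme, so that
#'   the root of `R - 1` is an exact fixed point of the simulator's
#'   discretization; `"continuous"` uses the exponential-integral formula.
#' @return scalar reproduction number.
#' @export
reproduction_number <- function(N_bar, grid, mp, cp,
                                discretization = c("upwind", "continuous")) {
  discretization <- match.arg(discretization)
  stopifnot(N_bar >= 0)
  sf <- survival_factors(N_bar, grid, mp, cp, 0, discretization)
  tau <- tau_of_age(grid$nodes, mp)
  2 / mp$g(0) * sum(grid$weights * tau * sf$S)
}

#' Solve for steady states
#'
#' Scans `R(N) - 1` over a bracket (64 log-spaced points), runs a bracketed
#' root solve on every sign change, and assembles the steady state at the
#' largest root: `p(a) = p(0) Pi(a)`,
#' `q(a) = chi(a, x1(a)) p(a) / (gamma(N) + mu_q(a))`, with `p(0)` fixed so
#' that the total-population integral reproduces `N`. If no sign change
#' exists in the bracket the trivial state (`N = 0`) is returned with
#' `trivial = TRUE` (not an error).
#'
#' @inheritParams reproduction_number
#' @param bracket numeric length-2, the search interval for `N_bar`
#'   (cells); both endpoints `> 0`.
#' @return A `steady_state`: `N_bar`, `p0_bar`, `p_bar`, `q_bar`,
#'   `gamma_bar`, `gf_bar`, `x_bar` (cycle trajectory at `gf_bar`),
#'   `all_roots`, `trivial`, `residuals` (list: `R_minus_1`, absolute
#'   `ode_sup` of the discrete steady ODE, relative `mass`), plus the
#'   `grid` and `discretization` used.
#' @examples
#' \donttest{
#' cfg <- scenario_preset("case_5_1")
#' ss <- solve_steady_state(cfg$grid, cfg$macro, cfg$cycle)
#' ss$N_bar
#' }
#' @export
solve_steady_state <- function(grid, mp, cp, bracket = c(1, 1e10),
                               discretization = c("upwind", "continuous")) {
  discretization <- match.arg(discretization)
  stopifnot(length(bracket) == 2L, bracket[1] > 0, bracket[1] < bracket[2])
  f <- function(u) reproduction_number(exp(u), grid, mp, cp,
                                       discretization) - 1
  us <- seq(log(bracket[1]), log(bracket[2]), length.out = 64)
  fs <- vapply(us, f, numeric(1))
  sgn <- sign(fs)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    r <- uniroot(f, c(us[i], us[i + 1]), tol = 1e-13)
    exp(r$root)
  }, numeric(1))
  roots <- c(roots, exp(us[fs == 0]))

  if (length(roots) == 0L)
    return(trivial_steady_state(grid, mp, cp, discretization,
                                R_in_bracket = fs + 1))

  N_bar <- max(roots)
  sf <- survival_factors(N_bar, grid, mp, cp, 0, discretization)
  a <- grid$nodes
  denom <- sum(grid$weights * sf$S * (1 + sf$chi / (sf$gam + sf$muq)))
  p0 <- N_bar / denom
  p_bar <- p0 * sf$S
  q_bar <- sf$chi * p_bar / (sf$gam + sf$muq)

  # residual of the steady proliferating ODE, evaluated with the same
  # discrete derivative the scheme uses
  g <- mp$g(a)
  L0 <- sf$L
  gp <- g * p_bar
  ode_res <- (gp[-1] - gp[-length(gp)]) / grid$da + (L0 * p_bar)[-1]
  res <- list(
    R_minus_1 = reproduction_number(N_bar, grid, mp, cp, discretization) - 1,
    ode_sup = max(abs(ode_res)) / max(p_bar),
    mass = abs(sum(grid$weights * (p_bar + q_bar)) - N_bar) / N_bar)

  structure(list(N_bar = N_bar, p0_bar = p0, p_bar = p_bar, q_bar = q_bar,
                 gamma_bar = sf$gam, gf_bar = sf$gf,
                 x_bar = integrate_cycle(sf$gf, cp, a),
                 all_roots = sort(roots), trivial = FALSE,
                 residuals = res, grid = grid,
                 discretization = discretization),
            class = "steady_state")
}

trivial_steady_state <- function(grid, mp, cp,
                                 discretization = "upwind",
                                 R_in_bracket = NULL) {
  a <- grid$nodes
  structure(list(N_bar = 0, p0_bar = 0,
                 p_bar = numeric(length(a)), q_bar = numeric(length(a)),
                 gamma_bar = gamma_of_N(0, mp),
                 gf_bar = growth_factor(0, mp),
                 x_bar = integrate_cycle(growth_factor(0, mp), cp, a),
                 all_roots = numeric(0), trivial = TRUE,
                 residuals = list(
                   R_minus_1 = reproduction_number(0, grid, mp, cp,
                                                   discretization) - 1,
                   ode_sup = 0, mass = 0),
                 R_in_bracket = R_in_bracket,
                 grid = grid, discretization = discretization),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  if (x$trivial) {
    cat("Trivial steady state (no reproduction-number root in bracket)\n")
    cat(sprintf("  R(0) = %.4f, gamma(0) = %.4g, g_f(0) = %g\n",
                x$residuals$R_minus_1 + 1, x$gamma_bar, x$gf_bar))
  } else {
    cat(sprintf("Nontrivial steady state: N = %.6g cells (p(0) = %.4g)\n",
                x$N_bar, x$p0_bar))
    cat(sprintf("  gamma(N) = %.4g /day, g_f(N) = %.4g\n",
                x$gamma_bar, x$gf_bar))
    cat(sprintf("  residuals: |R-1| = %.2g, steady-ODE sup = %.2g, mass = %.2g\n",
                abs(x$residuals$R_minus_1), x$residuals$ode_sup,
                x$residuals$mass))
    if (length(x$all_roots) > 1L)
      cat("  all roots:", paste(signif(x$all_roots, 6), collapse = ", "),
          "\n")
  }
  invisible(x)
}
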