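#' Uniform age grid
#'
#' @param a_star maximal age (h).
#' @param da grid spacing (h); must divide `a_star` to within rounding.
#' @return An `age_grid`: list with `a_star`, `da`, `nodes` (from 0 to
#'   `a_star` inclusive) and `weights` (composite-trapezoid quadrature
#'   weights).
#' @export
age_grid <- function(a_star = 50, da = 0.5) {
  stopifnot(a_star > 0, da > 0)
  n <- round(a_star / da)
  if (abs(n * da - a_star) > 1e-9 * a_star)
    stop("da must divide a_star")
  nodes <- seq(0, by = da, length.out = n + 1L)
  nodes[n + 1L] <- a_star
  w <- rep(da, n + 1L)
  w[c(1L, n + 1L)] <- da / 2
  structure(list(a_star = a_star, da = da, nodes = nodes, weights = w),
            class = "age_grid")
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf("Age grid: [0, %g] h, da = %g (%d nodes)\n",
              x$a_star, x$da, length(x$nodes)))
  invisible(x)
}

#' Population state on an age grid
#'
#' @param t time (h).
#' @param q,p nonnegative density vectors (cells/age) on the nodes of
#'   `grid` for the quiescent and proliferating compartments.
#' @param grid an [age_grid()].
#' @return A `population_state`.
#' @export
population_state <- function(t, q, p, grid) {
  stopifnot(inherits(grid, "age_grid"))
  n <- length(grid$nodes)
  if (length(q) != n || length(p) != n)
    stop("q and p must have one value per grid node")
  if (any(q < 0) || any(p < 0)) stop("densities must be nonnegative")
  structure(list(t = t, q = as.numeric(q), p = as.numeric(p), grid = grid),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state at t = %g h: N = %.6g cells (q: %.3g, p: %.3g)\n",
              x$t, total_population(x),
              sum(x$grid$weights * x$q), sum(x$grid$weights * x$p)))
  invisible(x)
}

#' Total population N(t)
#'
#' Composite-trapezoid integral of `q + p` over `[0, a_star]`.
#'
#' @param state a [population_state()].
#' @param grid optional [age_grid()]; defaults to the state's own grid.
#' @return total cell count (cells).
#' @export
total_population <- function(state, grid = state$grid) {
  stopifnot(inherits(state, "population_state"), inherits(grid, "age_grid"))
  sum(grid$weights * (state$q + state$p))
}

#' Renewal (division) boundary value
#'
#' Newborn proliferating-cell density fed into age 0 by cell division:
#' `p(0) = (2 / g(0)) * integral tau(a) p(a) da`, the factor 2 accounting
#' for the two daughter cells. The integral is a composite trapezoid on the
#' grid.
#'
#' @param p nonnegative density vector on the grid nodes.
#' @param grid an [age_grid()].
#' @param mp a [macro_params()] object.
#' @return scalar newborn density (cells/age).
#' @export
renewal_boundary <- function(p, grid, mp) {
  stopifnot(inherits(grid, "age_grid"), inherits(mp, "macro_params"))
  if (length(p) != length(grid$nodes)) stop("p must match the grid")
  tau <- tau_of_age(grid$nodes, mp)
  2 / mp$g(0) * sum(grid$weights * tau * p)
}

#' One explicit time step of the macroscale system
#'
#' Advances the pair `(q, p)` by one explicit Euler step of length `dt`:
#' the quiescent balance is a node-local ODE (quiescent cells do not age),
#' the proliferating equation is first-order upwind transport of `g(a) p`
#' plus its local reaction terms, and the new boundary value `p(0)` is the
#' renewal integral of the pre-step `p` (Dirichlet-like inflow). Outputs are
#' clipped at zero, with a warning for undershoots below `-1e-9`.
#'
#' The step requires the CFL condition `dt * max(g) / da <= 1`.
#'
#' @param state a [population_state()].
#' @param dt time step (h).
#' @param chi_vec switching rate `chi(a, x1(a))` evaluated on the grid
#'   nodes (1/h).
#' @param gamma_N scalar quiescent-exit rate `gamma(N)` for the current
#'   total population.
#' @param mp a [macro_params()] object.
#' @return the advanced [population_state()] at `t + dt`.
#' @export
advance_step <- function(state, dt, chi_vec, gamma_N, mp) {
  stopifnot(inherits(state, "population_state"),
            inherits(mp, "macro_params"))
  grid <- state$grid
  a <- grid$nodes
  n <- length(a)
  if (length(chi_vec) != n) stop("chi_vec must match the grid")
  g <- mp$g(a)
  if (dt * max(g) / grid$da > 1 + 1e-12)
    stop("CFL condition violated: dt * max(g) / da must be <= 1")

  q <- state$q
  p <- state$p
  tau <- tau_of_age(a, mp)
  mup <- mp$mu_p(a)
  muq <- mp$mu_q(a)

  p0_new <- renewal_boundary(p, grid, mp)
  q_new <- q + dt * (chi_vec * p - (gamma_N + muq) * q)
  flux <- g * p
  p_new <- p
  i <- 2:n
  p_new[i] <- p[i] + dt * (-(flux[i] - flux[i - 1L]) / grid$da +
                             gamma_N * q[i] -
                             (tau[i] + chi_vec[i] + mup[i]) * p[i])
  p_new[1L] <- p0_new

  low <- min(q_new, p_new)
  if (low < -1e-9)
    warning(sprintf("densities clipped at 0 (min %.3g)", low))
  population_state(state$t + dt, pmax(q_new, 0), pmax(p_new, 0), grid)
}
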