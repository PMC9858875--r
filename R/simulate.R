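#' Simulation configuration
#'
#' Bundles everything one coupled run needs: macro- and microscale
#' parameters, the age grid, the time step and horizon, the initial age
#' profile and the output/refresh policies.
#'
#' @param macro a [macro_params()] object.
#' @param cycle a [cycle_params()] object.
#' @param grid an [age_grid()].
#' @param dt time step (h); must satisfy the CFL condition
#'   `dt * max(g) / da <= 1`.
#' @param t_end simulation horizon (h).
#' @param initial initial age profile: either
#'   `list(type = "gaussian", k0 =, mu =, sigma2 =)` (applied to both `q`
#'   and `p`, see [make_gaussian_profile()]) or
#'   `list(type = "profile", q =, p =)` with explicit node vectors.
#' @param record_every thinning of the scalar time series, in steps.
#' @param snapshot_every spacing of stored `(q, p)` age snapshots, in hours
#'   (0 disables snapshots).
#' @param refresh microscale refresh policy: `"every_step"` (recompute the
#'   cell-cycle trajectory at every time step; the faithful default) or
#'   `list(policy = "on_gf_change", tol = 1e-4)` (skip the recompute while
#'   `g_f` has moved less than `tol`).
#' @param seed reserved; the model is deterministic and no randomness is
#'   used.
#' @param preset optional name recorded when built by [scenario_preset()].
#' @return A `simulation_config`.
#' @export
simulation_config <- function(macro = macro_params(), cycle = cycle_params(),
                              grid = age_grid(), dt = 0.02, t_end = 5000,
                              initial = list(type = "gaussian", k0 = 1e6,
                                             mu = 2, sigma2 = 200),
                              record_every = 1L, snapshot_every = 0,
                              refresh = "every_step", seed = NULL,
                              preset = NULL) {
  stopifnot(inherits(macro, "macro_params"), inherits(cycle, "cycle_params"),
            inherits(grid, "age_grid"), dt > 0, t_end > 0,
            record_every >= 1)
  if (dt * max(macro$g(grid$nodes)) / grid$da > 1 + 1e-12)
    stop("CFL condition violated: dt * max(g) / da must be <= 1")
  if (is.character(refresh)) refresh <- list(policy = refresh)
  if (!refresh$policy %in% c("every_step", "on_gf_change"))
    stop("unknown refresh policy '", refresh$policy, "'")
  if (refresh$policy == "on_gf_change" && is.null(refresh$tol))
    refresh$tol <- 1e-4
  if (!is.list(initial) || is.null(initial$type))
    stop("initial must be a list with a 'type' field")
  if (!initial$type %in% c("gaussian", "profile"))
    stop("unknown initial profile type '", initial$type, "'")
  structure(list(macro = macro, cycle = cycle, grid = grid, dt = dt,
                 t_end = t_end, initial = initial,
                 record_every = as.integer(record_every),
                 snapshot_every = snapshot_every, refresh = refresh,
                 seed = seed, preset = preset),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration",
      if (!is.null(x$preset)) sprintf("(preset %s)", x$preset), "\n")
  cat(sprintf("  grid: [0, %g] h, da = %g; dt = %g h, horizon %g h\n",
              x$grid$a_star, x$grid$da, x$dt, x$t_end))
  cat(sprintf("  initial: %s; microscale refresh: %s\n",
              x$initial$type, x$refresh$policy))
  invisible(x)
}

#' Case-study presets
#'
#' Ready-made configurations for the three published case studies, all on
#' the grid `da = 0.5` h, `dt = 0.02` h, `a* = 50` h with unit cycle speed
#' and the Gaussian initial profile (`k0 = 1e6`, `mu = 2`, `sigma2 = 200`)
#' applied to both compartments:
#'
#' * `"case_5_1"` - nontrivial steady state: `mu_p = mu_q = 0.0014`,
#'   `rho1 = 1.0`; the population grows and then plateaus.
#' * `"case_5_2"` - decay to the trivial state: `mu_p = mu_q = 0.020`,
#'   `rho1 = 0.20`, `nu = 0.1`; the population dies out within 2500 h.
#' * `"case_5_3"` - instability: as `"case_5_1"` but `k_gf = 1e-4`, which
#'   unhooks Cyclin D-CDK4/6 synthesis from the growth-factor signal and
#'   produces exponential growth. Its default horizon is 600 h, covering
#'   the exponential regime (beyond roughly 1500 h the growth saturates
#'   once `g_f` falls to the `k_gf` scale).
#'
#' @param name one of `"case_5_1"`, `"case_5_2"`, `"case_5_3"`.
#' @param t_end optional horizon override (h).
#' @return A [simulation_config()].
#' @examples
#' cfg <- scenario_preset("case_5_2")
#' cfg$macro$mu_p(0)   # 0.020
#' @export
scenario_preset <- function(name, t_end = NULL) {
  grid <- age_grid(a_star = 50, da = 0.5)
  base_init <- list(type = "gaussian", k0 = 1e6, mu = 2, sigma2 = 200)
  cfg <- switch(name,
    case_5_1 = simulation_config(
      macro = macro_params(mu_p = 0.0014, mu_q = 0.0014, rho1 = 1.0),
      cycle = cycle_params(), grid = grid, dt = 0.02,
      t_end = if (is.null(t_end)) 5000 else t_end,
      initial = base_init, preset = "case_5_1"),
    case_5_2 = simulation_config(
      macro = macro_params(mu_p = 0.020, mu_q = 0.020, rho1 = 0.20,
                           nu = 0.1),
      cycle = cycle_params(), grid = grid, dt = 0.02,
      t_end = if (is.null(t_end)) 5000 else t_end,
      initial = base_init, preset = "case_5_2"),
    case_5_3 = simulation_config(
      macro = macro_params(mu_p = 0.0014, mu_q = 0.0014, rho1 = 1.0),
      cycle = cycle_params(k_gf = 1e-4), grid = grid, dt = 0.02,
      t_end = if (is.null(t_end)) 600 else t_end,
      initial = base_init, preset = "case_5_3"),
    stop("unknown preset '", name, "'")
  )
  cfg
}

initial_profiles <- function(cfg) {
  init <- cfg$initial
  if (init$type == "gaussian") {
    prof <- make_gaussian_profile(gaussian_profile_spec(init$k0, init$mu,
                                                        init$sigma2),
                                  cfg$grid)
    list(q = prof, p = prof)
  } else {
    n <- length(cfg$grid$nodes)
    if (length(init$q) != n || length(init$p) != n)
      stop("initial profile vectors must match the grid")
    list(q = as.numeric(init$q), p = as.numeric(init$p))
  }
}

#' Run the coupled multiscale simulation
#'
#' Advances the feedback loop: the total population `N(t)` sets the
#' growth-factor signal `g_f`, the cell-cycle trajectory at that `g_f`
#' yields the Cyclin profile `x1(a)` and hence the switching rate
#' `chi(a, x1(a))`, which enters the explicit upwind step of the
#' age-structured system; the step updates `N`. The model is deterministic:
#' identical configurations give identical results.
#'
#' If the population exceeds `1e300` (possible in the unstable scenario)
#' the run stops early and reports the blow-up time; this is growth, not an
#' error.
#'
#' @param cfg a [simulation_config()].
#' @param engine `"compiled"` (default) or `"r"` (pure-R reference loop
#'   built on [advance_step()]; identical scheme, used for validation).
#' @param verbose print a progress line every 1000 recorded steps.
#' @return A `simulation_result`: list with the recorded series `times`,
#'   `N`, `g_f`, `gamma_N`, `p_boundary`; `snapshots` (times plus `q`, `p`
#'   matrices, one column per snapshot); `final_state`
#'   ([population_state()]); `final_cycle` ([integrate_cycle()] trajectory
#'   in use at the end); `blowup_time` (`NA` unless the overflow guard
#'   fired) and the resolved `config`.
#' @export
run_simulation <- function(cfg, engine = c("compiled", "r"),
                           verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(cfg, "simulation_config"))
  grid <- cfg$grid
  a <- grid$nodes
  init <- initial_profiles(cfg)
  nsteps <- as.integer(round(cfg$t_end / cfg$dt))
  refresh_tol <- if (cfg$refresh$policy == "every_step") 0 else cfg$refresh$tol
  snap_steps <- if (cfg$snapshot_every > 0)
    max(1L, as.integer(round(cfg$snapshot_every / cfg$dt))) else 0L

  mp <- cfg$macro
  macro_vec <- c(mp$nu, mp$theta, mp$kappa, mp$k_t, mp$sigma1, mp$sigma2,
                 mp$sigma3, mp$gamma2, mp$gamma3)
  if (engine == "compiled") {
    out <- simulate_cpp(init$q, init$p, grid$da, cfg$dt, nsteps,
                        tau_of_age(a, mp), mp$mu_p(a), mp$mu_q(a), mp$g(a),
                        macro_vec, cycle_param_vector(cfg$cycle),
                        0.025, refresh_tol, cfg$record_every, snap_steps,
                        1e300, 1e-9)
    if (isTRUE(out$clip_warn))
      warning(sprintf("densities clipped at 0 (min %.3g)",
                      out$min_before_clip))
  } else {
    out <- simulate_r(cfg, init, nsteps, refresh_tol, snap_steps, verbose)
  }

  final_t <- out$t[length(out$t)]
  res <- structure(list(
    times = out$t, N = out$N, g_f = out$g_f, gamma_N = out$gamma_N,
    p_boundary = out$p_boundary,
    snapshots = list(t = out$snapshot_t, q = out$snapshot_q,
                     p = out$snapshot_p),
    final_state = population_state(final_t, out$q, out$p, grid),
    final_cycle = structure(list(ages = a,
                                 states = `colnames<-`(out$cycle_states,
                                                       c("x1", "x2", "x3", "x4")),
                                 gf_level = out$gf_used),
                            class = "cycle_trajectory"),
    blowup_time = out$blowup_time, config = cfg), class = "simulation_result")
  res
}

simulate_r <- function(cfg, init, nsteps, refresh_tol, snap_steps, verbose) {
  grid <- cfg$grid
  a <- grid$nodes
  mp <- cfg$macro
  state <- population_state(0, init$q, init$p, grid)
  tau <- tau_of_age(a, mp)
  nrec <- nsteps %/% cfg$record_every + 1L
  r_t <- r_N <- r_gf <- r_gam <- r_p0 <- numeric(nrec)
  snaps_t <- numeric(0); snaps_q <- snaps_p <- NULL
  if (snap_steps > 0) {
    nsnap <- nsteps %/% snap_steps + 1L
    snaps_q <- matrix(0, length(a), nsnap)
    snaps_p <- matrix(0, length(a), nsnap)
    snaps_t <- numeric(nsnap)
  }
  gf_used <- NA_real_
  traj <- NULL
  chiv <- NULL
  irec <- 0L; isnap <- 0L
  blowup <- NA_real_
  for (s in 0:nsteps) {
    N <- total_population(state)
    gf <- growth_factor(N, mp)
    gam <- gamma_of_N(N, mp)
    if (s %% cfg$record_every == 0L) {
      irec <- irec + 1L
      r_t[irec] <- s * cfg$dt; r_N[irec] <- N; r_gf[irec] <- gf
      r_gam[irec] <- gam; r_p0[irec] <- renewal_boundary(state$p, grid, mp)
      if (verbose && irec %% 1000L == 0L)
        message(sprintf("t = %.1f h, N = %.4g", s * cfg$dt, N))
    }
    if (snap_steps > 0 && s %% snap_steps == 0L) {
      isnap <- isnap + 1L
      snaps_q[, isnap] <- state$q; snaps_p[, isnap] <- state$p
      snaps_t[isnap] <- s * cfg$dt
    }
    if (!is.finite(N) || N > 1e300) { blowup <- s * cfg$dt; break }
    if (s == nsteps) break
    if (is.na(gf_used) || abs(gf - gf_used) > refresh_tol) {
      traj <- integrate_cycle(gf, cfg$cycle, a)
      chiv <- chi_of_age_cyclin(a, traj$states[, "x1"], mp)
      gf_used <- gf
    }
    state <- advance_step(state, cfg$dt, chiv, gam, mp)
  }
  list(t = r_t[seq_len(irec)], N = r_N[seq_len(irec)],
       g_f = r_gf[seq_len(irec)], gamma_N = r_gam[seq_len(irec)],
       p_boundary = r_p0[seq_len(irec)], q = state$q, p = state$p,
       snapshot_t = snaps_t[seq_len(isnap)],
       snapshot_q = if (isnap > 0) snaps_q[, seq_len(isnap), drop = FALSE]
                    else matrix(0, length(a), 0),
       snapshot_p = if (isnap > 0) snaps_p[, seq_len(isnap), drop = FALSE]
                    else matrix(0, length(a), 0),
       cycle_states = traj$states, gf_used = gf_used, blowup_time = blowup)
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Coupled simulation over %g h (%d recorded points)\n",
              x$times[n], n))
  cat(sprintf("  N: %.6g -> %.6g cells; g_f: %.4g -> %.4g; gamma(N): %.4g -> %.4g\n",
              x$N[1], x$N[n], x$g_f[1], x$g_f[n],
              x$gamma_N[1], x$gamma_N[n]))
  if (!is.na(x$blowup_time))
    cat(sprintf("  overflow guard reached at t = %g h (unbounded growth)\n",
                x$blowup_time))
  invisible(x)
}
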