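# Local stability of a steady state.
#
# Linearizing the coupled system about a steady state (with the microscale
# Cyclin profile frozen, since the linearization acts only on the
# population densities) gives a transport-reaction generator C with the
# renewal boundary condition. Its point spectrum is governed by a family of
# positive rank-one integral operators U_lambda: lambda is an eigenvalue of
# C's renewal branch exactly when the spectral radius r(U_lambda) equals 1.
# r is continuous and strictly decreasing in real lambda with r -> 0 as
# lambda -> +infinity, so there is a unique real root lambda0, and the
# steady state is locally asymptotically stable when r(U_0) < 1 (lambda0 <
# 0) and unstable when r(U_0) > 1. The Nystrom discretization uses the
# trapezoid weights of the shared age grid; by default the survival factor
# inside the kernel uses the upwind product rule, which makes lambda0 an
# exact eigenvalue of the discretized generator assembled by
# linearized_generator().

lambda_domain_edge <- function(steady, mp) {
  -(steady$gamma_bar + min(mp$mu_q(steady$grid$nodes)))
}

# survival-to-age factor of a perturbation cohort decaying at rate lambda
perturbation_survival <- function(lambda, steady, mp,
                                  discretization = c("upwind",
                                                     "continuous")) {
  discretization <- match.arg(discretization)
  grid <- steady$grid
  a <- grid$nodes
  g <- mp$g(a)
  gam <- steady$gamma_bar
  muq <- mp$mu_q(a)
  if (any(lambda + gam + muq <= 0))
    stop("lambda outside the admissible domain: lambda + gamma + mu_q ",
         "vanishes at age ", a[which(lambda + gam + muq <= 0)[1]])
  chiv <- chi_of_age_cyclin(a, steady$x_bar$states[, "x1"], mp)
  Psi <- (lambda + tau_of_age(a, mp) + chiv + mp$mu_p(a) -
            gam * chiv / (lambda + gam + muq)) / g
  if (discretization == "continuous") {
    E <- pracma::cumtrapz(a, Psi)[, 1]
    (g[1] / g) * exp(-E)
  } else {
    f <- 1 / (1 + grid$da * Psi)
    (g[1] / g) * cumprod(c(1, f[-1]))
  }
}

#' Renewal kernel G_lambda(zeta, a)
#'
#' Kernel of the rank-one renewal operator `U_lambda` acting on
#' proliferating-cell perturbations:
#' `G_lambda(zeta, a) = (2 / g(0)) * tau(zeta) * P_lambda(a)`, where
#' `P_lambda(a)` is the survival-to-age-`a` factor of a perturbation cohort
#' decaying at rate `lambda`,
#' \deqn{P_\lambda(a) = \frac{g(0)}{g(a)} \exp\left(-\int_0^a
#'   \Psi_\lambda(\xi)\, d\xi\right), \quad
#'   \Psi_\lambda = \frac{1}{g}\Big[\lambda + \tau + \chi + \mu_p -
#'   \frac{\bar\gamma\,\chi}{\lambda + \bar\gamma + \mu_q}\Big].}
#' The subtracted term is the return flow of perturbed cells that switch to
#' quiescence and come back. The kernel is entrywise nonnegative on the
#' admissible domain `lambda > -min(gamma + mu_q)` and vanishes
#' identically iff `tau == 0`. At `lambda = 0`, `P_0` is the steady-state
#' survival profile, so `r(U_0)` equals the reproduction number `R(N_bar)`.
#'
#' @param lambda real spectral parameter (1/h), with
#'   `lambda + gamma_bar + mu_q(a) > 0` for all grid ages.
#' @param zeta,a evaluation points in `[0, a_star]` (vectors are recycled
#'   to a common length).
#' @param steady a [solve_steady_state()] result (or trivial report).
#' @param mp the [macro_params()] the steady state was computed under.
#' @return kernel values, nonnegative.
#' @export
kernel_G <- function(lambda, zeta, a, steady, mp) {
  stopifnot(inherits(steady, "steady_state"), inherits(mp, "macro_params"))
  nodes <- steady$grid$nodes
  if (any(zeta < 0) || any(zeta > max(nodes)) ||
      any(a < 0) || any(a > max(nodes)))
    stop("zeta and a must lie in [0, a_star]")
  P <- perturbation_survival(lambda, steady, mp, "continuous")
  P_at <- approx(nodes, P, xout = a)$y
  2 / mp$g(0) * tau_of_age(zeta, mp) * P_at
}

# Nystrom matrix of U_lambda on the grid: M[i, j] = G(a_j, a_i) * w_j
nystrom_matrix <- function(lambda, steady, mp,
                           discretization = c("upwind", "continuous")) {
  discretization <- match.arg(discretization)
  grid <- steady$grid
  P <- perturbation_survival(lambda, steady, mp, discretization)
  tau <- tau_of_age(grid$nodes, mp)
  outer(2 / mp$g(0) * P, tau * grid$weights)
}

#' Spectral radius of the discretized renewal operator
#'
#' Power iteration on the nonnegative Nystrom matrix of `U_lambda`
#' (trapezoid weights on the steady state's grid), with a dense
#' eigendecomposition fallback if the iteration has not converged after 500
#' sweeps. `r` is strictly decreasing in `lambda` and tends to 0 as
#' `lambda -> +Inf`.
#'
#' @inheritParams kernel_G
#' @param discretization survival-factor rule inside the kernel; see
#'   [reproduction_number()].
#' @return scalar spectral radius.
#' @export
spectral_radius_U <- function(lambda, steady, mp,
                              discretization = c("upwind", "continuous")) {
  discretization <- match.arg(discretization)
  M <- nystrom_matrix(lambda, steady, mp, discretization)
  if (all(M == 0)) return(0)
  v <- rep(1, nrow(M))
  r <- 0
  for (it in seq_len(500L)) {
    w <- M %*% v
    r_new <- max(abs(w))
    if (r_new == 0) return(0)
    v <- as.numeric(w / r_new)
    if (abs(r_new - r) <= 1e-13 * max(1, r_new)) return(r_new)
    r <- r_new
  }
  max(abs(Re(eigen(M, only.values = TRUE)$values)))
}

#' Dominant singular point lambda0
#'
#' The unique real `lambda0` with `r(U_lambda0) = 1`, located by a scan for
#' a sign change of `r - 1` (using the monotonicity of `r`) followed by a
#' bracketed root solve polished to `|r(lambda0) - 1| <= 1e-8`.
#' `sign(lambda0) = sign(r(U_0) - 1)`. If `r < 1` everywhere down to the
#' admissible domain edge `-min(gamma_bar + mu_q)`, the edge value is
#' returned with `edge = TRUE` (the state is then stable but the root is
#' out of reach).
#'
#' @inheritParams spectral_radius_U
#' @return list with `lambda0`, `r_at_root` and `edge`.
#' @export
growth_bound_lambda0 <- function(steady, mp,
                                 discretization = c("upwind",
                                                    "continuous")) {
  discretization <- match.arg(discretization)
  r_of <- function(l) spectral_radius_U(l, steady, mp, discretization)
  edge <- lambda_domain_edge(steady, mp)
  r0 <- r_of(0)
  if (r0 >= 1) {
    lo <- 0
    hi <- max(0.01, -edge)
    while (r_of(hi) > 1) hi <- 2 * hi
  } else {
    hi <- 0
    # approach the domain edge geometrically from above
    gap <- -edge
    lo <- NA_real_
    for (frac in 2^-(1:40)) {
      cand <- edge + gap * frac
      if (r_of(cand) >= 1) { lo <- cand; break }
      hi <- cand
    }
    if (is.na(lo))
      return(list(lambda0 = edge + gap * 2^-40, r_at_root = r_of(hi),
                  edge = TRUE))
  }
  root <- uniroot(function(l) r_of(l) - 1, c(lo, hi), tol = 1e-14)$root
  # polish by bisection until the residual meets tolerance
  a_ <- lo; b_ <- hi
  l <- root
  for (it in seq_len(100L)) {
    res <- r_of(l) - 1
    if (abs(res) <= 1e-8) break
    if (res > 0) a_ <- l else b_ <- l
    l <- (a_ + b_) / 2
  }
  list(lambda0 = l, r_at_root = r_of(l), edge = FALSE)
}

#' Discretized linearized generator C
#'
#' Dense matrix of the linearization about a steady state on the shared
#' grid: node-local quiescent balance, first-order upwind transport of
#' `g p` with the reaction terms, and the renewal boundary row (the age-0
#' proliferating node is algebraically eliminated through the trapezoid
#' renewal integral, exactly as the simulator treats it). The state
#' ordering is `(q_1..q_n, p_2..p_n)`.
#'
#' @inheritParams kernel_G
#' @return a `(2n-1) x (2n-1)` matrix.
#' @export
linearized_generator <- function(steady, mp) {
  grid <- steady$grid
  a <- grid$nodes
  n <- length(a)
  g <- mp$g(a)
  da <- grid$da
  gam <- steady$gamma_bar
  muq <- mp$mu_q(a)
  mup <- mp$mu_p(a)
  tau <- tau_of_age(a, mp)
  chiv <- chi_of_age_cyclin(a, steady$x_bar$states[, "x1"], mp)
  w <- grid$weights

  # renewal elimination: p_1 = (2/g(0)) sum_j w_j tau_j p_j  (tau_1 = 0)
  b <- 2 / g[1] * (w * tau)[-1]

  m <- 2L * n - 1L
  C <- matrix(0, m, m)
  iq <- seq_len(n)
  ip <- n + seq_len(n - 1L)           # p at nodes 2..n

  # quiescent rows: dq_i = -(gam + muq_i) q_i + chi_i p_i
  C[cbind(iq, iq)] <- -(gam + muq)
  C[cbind(iq[-1], ip)] <- chiv[-1]
  C[1L, ip] <- chiv[1] * b            # q_1 couples to the eliminated p_1

  # proliferating rows i = 2..n:
  # dp_i = -(g_i p_i - g_{i-1} p_{i-1})/da + gam q_i - (tau+chi+mup)_i p_i
  for (k in seq_len(n - 1L)) {
    i <- k + 1L                        # grid node index
    row <- ip[k]
    C[row, ip[k]] <- C[row, ip[k]] - g[i] / da -
      (tau[i] + chiv[i] + mup[i])
    C[row, iq[i]] <- gam
    if (k == 1L) {
      C[row, ip] <- C[row, ip] + g[1] / da * b
    } else {
      C[row, ip[k - 1L]] <- C[row, ip[k - 1L]] + g[i - 1L] / da
    }
  }
  C
}

#' Classify the local stability of a steady state
#'
#' Computes `r(U_0)` and the dominant singular point `lambda0`, assembles
#' the discretized linearized generator and its eigenvalues, and returns
#' the verdict: stable if `r(U_0) < 1`, unstable if `r(U_0) > 1`, marginal
#' if `|r(U_0) - 1| <= 1e-6` (a solved nontrivial steady state is marginal
#' by construction under the frozen-population linearization, since
#' `r(U_0) = R(N_bar) = 1` there). A grid-refinement value of `r(U_0)` at
#' half the spacing is reported alongside.
#'
#' @inheritParams spectral_radius_U
#' @param cp the [cycle_params()] used for the steady state (needed to
#'   rebuild the Cyclin profile on the refined grid).
#' @return A `stability_report`: `r_U0`, `r_U0_refined`, `lambda0`,
#'   `verdict`, `sC_estimate` (largest real part of the generator's
#'   eigenvalues), `dominant_imag`, `agreement` (`|lambda0 -
#'   sC_estimate|`) and `edge`.
#' @export
classify_stability <- function(steady, mp, cp,
                               discretization = c("upwind", "continuous")) {
  discretization <- match.arg(discretization)
  r0 <- spectral_radius_U(0, steady, mp, discretization)
  gb <- growth_bound_lambda0(steady, mp, discretization)

  C <- linearized_generator(steady, mp)
  ev <- eigen(C, only.values = TRUE)$values
  sC <- max(Re(ev))
  dom <- ev[which.max(Re(ev))]

  grid2 <- age_grid(steady$grid$a_star, steady$grid$da / 2)
  steady2 <- regrid_steady(steady, grid2, mp, cp)
  r0_half <- spectral_radius_U(0, steady2, mp, discretization)

  verdict <- if (abs(r0 - 1) <= 1e-6) "marginal"
             else if (r0 < 1) "stable" else "unstable"
  structure(list(r_U0 = r0, r_U0_refined = r0_half,
                 lambda0 = gb$lambda0, edge = gb$edge,
                 sC_estimate = sC, dominant_imag = Im(dom),
                 agreement = abs(gb$lambda0 - sC),
                 verdict = verdict, N_bar = steady$N_bar,
                 discretization = discretization),
            class = "stability_report")
}

# rebuild the parts of a steady state that live on the grid (for the
# refinement study); N_bar and the scalar rates are unchanged
regrid_steady <- function(steady, grid, mp, cp) {
  s2 <- steady
  s2$grid <- grid
  s2$x_bar <- integrate_cycle(steady$gf_bar, cp, grid$nodes)
  s2
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report (N_bar = %.6g cells): %s\n",
              x$N_bar, toupper(x$verdict)))
  cat(sprintf("  r(U_0) = %.6g (da/2 refinement: %.6g)\n",
              x$r_U0, x$r_U0_refined))
  cat(sprintf("  lambda0 = %.6g /h%s; max Re eig(C) = %.6g /h (|Im| = %.2g)\n",
              x$lambda0, if (x$edge) " [domain edge]" else "",
              x$sC_estimate, abs(x$dominant_imag)))
  cat(sprintf("  |lambda0 - s(C)| = %.3g\n", x$agreement))
  invisible(x)
}
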