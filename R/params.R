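#' Macroscale model parameters
#'
#' Container for the rate-law constants and age-dependent coefficient
#' functions of the age-structured population model. The transition rates are
#' saturating (Hill-type) laws: `gamma_of_N()` (quiescent -> proliferating,
#' decreasing in total population `N`), `tau_of_age()` (division, increasing
#' in age), `chi_of_age_cyclin()` (proliferating -> quiescent, decreasing in
#' both age and Cyclin D-CDK4/6 level), and the growth-factor signal
#' `growth_factor()`.
#'
#' Death rates `mu_p`, `mu_q` and the cycle-progression speed `g` may be
#' given either as single nonnegative constants (the usual case; the case
#' studies use constant death rates and unit speed) or as vectorized
#' functions of age on `[0, a_star]`. `g` must be bounded away from zero.
#'
#' Default values: `theta`, `kappa`, `sigma3`, `k_t` as tabulated for stem
#' cell lines; `nu`, `rho1`, `sigma1` at the middle of their literature
#' ranges; Hill exponents `gamma1 = 10`, `gamma2 = gamma3 = 5`;
#' `rho2 = 35` h (division concentrated around the mammalian cell-cycle
#' length) and `sigma2 = 0.05` uM (restriction-point threshold placed inside
#' the attainable Cyclin D-CDK4/6 range, below its high-growth-factor
#' plateau of about 0.118 uM). See the methods vignette for the rationale
#' behind each choice.
#'
#' @param nu maximum quiescent -> proliferating transition rate (1/day).
#' @param theta total population at which that transition is at half maximum
#'   (cells).
#' @param kappa Hill exponent of the `gamma(N)` law (>= 1).
#' @param rho1 maximum division rate (1/day).
#' @param rho2 age of half-maximum division rate (h).
#' @param gamma1 Hill exponent of the division-rate law (>= 1).
#' @param sigma1 maximum proliferating -> quiescent switching rate (1/h).
#' @param sigma2 Cyclin D-CDK4/6 threshold of the restriction point (uM).
#' @param sigma3 age beyond which cells are committed to division (h).
#' @param gamma2,gamma3 Hill exponents of the switching law (>= 1).
#' @param k_t coupling constant from total population to growth factor
#'   (1/cells).
#' @param mu_p,mu_q death rates of the proliferating / quiescent
#'   compartments: a nonnegative constant or a vectorized function of age
#'   (1/h).
#' @param g cell-cycle evolution speed: a positive constant or a vectorized
#'   function of age, bounded away from zero (dimensionless age speed).
#' @param a_star maximal age (h).
#'
#' @return An object of class `macro_params`.
#' @examples
#' mp <- macro_params()
#' gamma_of_N(0, mp)            # = nu
#' tau_of_age(mp$rho2, mp)      # = rho1 / 2
#' @export
macro_params <- function(nu = 0.55, theta = 0.095e6, kappa = 1,
                         rho1 = 0.5, rho2 = 35, gamma1 = 10,
                         sigma1 = 0.9, sigma2 = 0.05, sigma3 = 16,
                         gamma2 = 5, gamma3 = 5,
                         k_t = 1.80e-9,
                         mu_p = 0.0014, mu_q = 0.0014,
                         g = 1, a_star = 50) {
  sc <- list(nu = nu, theta = theta, kappa = kappa, rho1 = rho1, rho2 = rho2,
             gamma1 = gamma1, sigma1 = sigma1, sigma2 = sigma2,
             sigma3 = sigma3, gamma2 = gamma2, gamma3 = gamma3,
             k_t = k_t, a_star = a_star)
  for (nm in names(sc)) {
    v <- sc[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("macro parameter '", nm, "' must be a finite numeric scalar")
  }
  if (any(unlist(sc[c("nu", "theta", "rho1", "rho2", "sigma1", "sigma2",
                      "sigma3", "k_t", "a_star")]) <= 0))
    stop("macro rate constants must be strictly positive")
  if (kappa < 1 || gamma1 < 1 || gamma2 < 1 || gamma3 < 1)
    stop("Hill exponents must be >= 1")

  mp <- c(sc, list(mu_p = as_age_fun(mu_p, "mu_p"),
                   mu_q = as_age_fun(mu_q, "mu_q"),
                   g    = as_age_fun(g, "g"),
                   # constants retained for serialization when supplied
                   mu_p_const = if (is.numeric(mu_p)) mu_p else NA_real_,
                   mu_q_const = if (is.numeric(mu_q)) mu_q else NA_real_,
                   g_const    = if (is.numeric(g)) g else NA_real_))
  class(mp) <- "macro_params"

  probe <- seq(0, a_star, length.out = 101)
  if (any(mp$mu_p(probe) < 0) || any(mp$mu_q(probe) < 0))
    stop("death rates must be nonnegative on [0, a_star]")
  if (any(mp$g(probe) <= 1e-12))
    stop("g must be bounded away from zero on [0, a_star]")
  mp
}

as_age_fun <- function(x, name) {
  if (is.function(x)) return(x)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a constant or a function of age")
  force(x)
  function(a) rep_len(x, length(a))
}

#' @export
print.macro_params <- function(x, ...) {
  cat("Macroscale parameters\n")
  cat(sprintf("  gamma(N): nu = %g /day, theta = %g cells, kappa = %g\n",
              x$nu, x$theta, x$kappa))
  cat(sprintf("  tau(a):   rho1 = %g /day, rho2 = %g h, gamma1 = %g\n",
              x$rho1, x$rho2, x$gamma1))
  cat(sprintf("  chi(a,x1): sigma1 = %g /h, sigma2 = %g uM, sigma3 = %g h, gamma2 = %g, gamma3 = %g\n",
              x$sigma1, x$sigma2, x$sigma3, x$gamma2, x$gamma3))
  cat(sprintf("  g_f(N):   k_t = %g /cells\n", x$k_t))
  cat(sprintf("  mu_p(0) = %g /h, mu_q(0) = %g /h, g(0) = %g, a* = %g h\n",
              x$mu_p(0), x$mu_q(0), x$g(0), x$a_star))
  invisible(x)
}

#' Cell-cycle (microscale) kinetic constants
#'
#' The twenty kinetic constants of the four-protein cell-cycle network:
#' x1 = Cyclin D-CDK4/6 complex, x2 = E2F, x3 = Rb, x4 = p21 (all uM, rates
#' per hour). Defaults are the tabulated literature values and should rarely
#' be changed, with the exception of `k_gf` (the Michaelis constant of
#' growth-factor-induced Cyclin synthesis), whose reduction decouples Cyclin
#' synthesis from the growth-factor signal and is the lever of the unstable
#' case study.
#'
#' @param k1s,k_gf,k14,k1d,k1 synthesis, growth-factor Michaelis constant,
#'   p21 binding, maximum degradation and degradation Michaelis constant of
#'   Cyclin D-CDK4/6.
#' @param k21,k2,x2t,k32,k2d E2F activation rate and Michaelis constant,
#'   total E2F pool, Rb binding, nonspecific degradation.
#' @param k3s,k31,k3,k3d Rb synthesis, phosphorylation rate and Michaelis
#'   constant, degradation.
#' @param k4s,k42,k34,k41,k4,k4d p21 basal and E2F-induced synthesis, Rb
#'   inhibition constant, phosphorylation rate and Michaelis constant,
#'   degradation.
#'
#' @return An object of class `cycle_params`.
#' @export
cycle_params <- function(k1s = 0.155, k_gf = 0.1, k14 = 0.15, k1d = 0.255,
                         k1 = 0.1, k21 = 0.805, k2 = 0.01, x2t = 2,
                         k32 = 0.01, k2d = 0.02, k3s = 0.8, k31 = 2.2,
                         k3 = 0.1, k3d = 0.01, k4s = 0.8, k42 = 0.1,
                         k34 = 0.1, k41 = 50, k4 = 0.5, k4d = 0.06) {
  cp <- list(k1s = k1s, k_gf = k_gf, k14 = k14, k1d = k1d, k1 = k1,
             k21 = k21, k2 = k2, x2t = x2t, k32 = k32, k2d = k2d,
             k3s = k3s, k31 = k31, k3 = k3, k3d = k3d,
             k4s = k4s, k42 = k42, k34 = k34, k41 = k41, k4 = k4, k4d = k4d)
  for (nm in names(cp)) {
    v <- cp[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("cycle parameter '", nm, "' must be a positive numeric scalar")
  }
  class(cp) <- "cycle_params"
  cp
}

#' @export
print.cycle_params <- function(x, ...) {
  cat("Cell-cycle kinetic constants (uM, /h)\n")
  v <- unlist(unclass(x))
  print(noquote(format(v, digits = 4)))
  invisible(x)
}

# internal: pack cycle params in the fixed order the C++ kernel expects
cycle_param_vector <- function(cp) {
  stopifnot(inherits(cp, "cycle_params"))
  unlist(unclass(cp))
}

#' Quiescent-to-proliferating transition rate gamma(N)
#'
#' Monotone decreasing Hill function of the total population:
#' `nu * theta^kappa / (theta^kappa + N^kappa)`. Its value at `N = 0` is the
#' maximal rate `nu`; at `N = theta` it is `nu / 2`.
#'
#' @param N total cell population (cells), scalar or vector, `>= 0`.
#' @param mp a [macro_params()] object.
#' @return rate (1/day), same length as `N`.
#' @export
gamma_of_N <- function(N, mp) {
  stopifnot(inherits(mp, "macro_params"))
  if (any(N < 0)) stop("N must be nonnegative")
  tk <- mp$theta^mp$kappa
  out <- mp$nu * tk / (tk + N^mp$kappa)
  out[is.infinite(N)] <- 0
  out
}

#' Age-dependent division rate tau(a)
#'
#' Increasing Hill function of age: `rho1 * a^gamma1 / (rho2^gamma1 +
#' a^gamma1)`; zero at age zero, half-maximal at `a = rho2`, saturating at
#' `rho1`.
#'
#' @param a age (h), scalar or vector, in `[0, a_star]`.
#' @param mp a [macro_params()] object.
#' @return rate (1/day), same length as `a`.
#' @export
tau_of_age <- function(a, mp) {
  stopifnot(inherits(mp, "macro_params"))
  if (any(a < 0) || any(a > mp$a_star))
    stop("age must lie in [0, a_star]")
  mp$rho1 * a^mp$gamma1 / (mp$rho2^mp$gamma1 + a^mp$gamma1)
}

#' Proliferating-to-quiescent switching rate chi(a, x1)
#'
#' Product of two decreasing Hill factors: cells can leave the proliferating
#' phase only while young (age below the commitment age `sigma3`) and while
#' their Cyclin D-CDK4/6 level `x1` is below the restriction-point threshold
#' `sigma2`:
#' `sigma1 * sigma2^gamma2/(sigma2^gamma2 + x1^gamma2) *
#'  sigma3^gamma3/(sigma3^gamma3 + a^gamma3)`.
#'
#' @param a age (h), `>= 0`; scalar or vector.
#' @param x1 Cyclin D-CDK4/6 concentration (uM), `>= 0`; recycled against
#'   `a`.
#' @param mp a [macro_params()] object.
#' @return rate (1/h).
#' @export
chi_of_age_cyclin <- function(a, x1, mp) {
  stopifnot(inherits(mp, "macro_params"))
  if (any(a < 0) || any(x1 < 0)) stop("age and x1 must be nonnegative")
  s2g <- mp$sigma2^mp$gamma2
  s3g <- mp$sigma3^mp$gamma3
  mp$sigma1 * (s2g / (s2g + x1^mp$gamma2)) * (s3g / (s3g + a^mp$gamma3))
}

#' Growth-factor signal g_f(N)
#'
#' Quasi-steady-state cytokine signal derived from the total population:
#' `1 / (1 + k_t * N)`, equal to 1 for an empty tissue and decaying to zero
#' for large populations.
#'
#' @param N total cell population (cells), `>= 0`; scalar or vector.
#' @param mp a [macro_params()] object.
#' @return dimensionless signal in `(0, 1]`.
#' @export
growth_factor <- function(N, mp) {
  stopifnot(inherits(mp, "macro_params"))
  if (any(N < 0)) stop("N must be nonnegative")
  1 / (1 + mp$k_t * N)
}
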