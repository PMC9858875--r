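# shared fixtures for the test suite (everything is built in code)

# a macro parameter set whose division and switching rates are numerically
# zero (rho2 enormous, sigma1 at the double-precision floor), used to test
# pure transport/decay behaviour of the scheme
macro_transport_only <- function(mu_p = 0, mu_q = 0) {
  macro_params(rho1 = 1, rho2 = 1e12, gamma1 = 10,
               sigma1 = 1e-300, mu_p = mu_p, mu_q = mu_q)
}

# compact bump well away from both age boundaries
bump_profile <- function(grid, center = 15, width = 3) {
  exp(-(grid$nodes - center)^2 / (2 * width^2))
}

gaussian_density <- function(a, k0 = 1e6, mu = 2, sigma2 = 200) {
  k0 / sqrt(2 * pi * sigma2) * exp(-(a - mu)^2 / (2 * sigma2))
}

# composite-trapezoid quadrature on an arbitrary fine grid (independent of
# the package's grid weights)
trapz_ref <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
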