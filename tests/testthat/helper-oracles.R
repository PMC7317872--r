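# Independent numeric oracles used across tests.

# Bell-Evans rupture CDF by numeric quadrature of the density (independent
# of the closed form used in the package).
quadrature_rupture_cdf <- function(F, tau0, x_beta, kBT, rate) {
  koff <- 1 / tau0
  dens <- function(f) {
    (koff / rate) * exp(f * x_beta / kBT) *
      exp(-(koff * kBT / (rate * x_beta)) * (exp(f * x_beta / kBT) - 1))
  }
  vapply(F, function(f) {
    if (f <= 0) return(0)
    stats::integrate(dens, 0, f, rel.tol = 1e-10)$value
  }, numeric(1))
}

# Analytic most probable rupture force.
analytic_mode <- function(tau0, x_beta, kBT, rate) {
  arg <- rate * x_beta * tau0 / kBT
  if (arg <= 1) 0 else (kBT / x_beta) * log(arg)
}

# Normalized pair-distance distribution of a solid sphere of diameter D.
sphere_pr <- function(r, D) {
  x <- r / D
  p <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
  p[x > 1] <- 0
  p
}

# Orientation-averaged form factor of a thin rod of length L.
rod_form_factor <- function(q, L) {
  Si <- vapply(q * L, function(u) {
    stats::integrate(function(t) sin(t) / t, 0, u, rel.tol = 1e-9)$value
  }, numeric(1))
  2 * Si / (q * L) - 4 * sin(q * L / 2)^2 / (q * L)^2
}

# Wald-Wolfowitz runs test z-statistic on the signs of a residual vector.
runs_test_z <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / (n1 + n2)
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  (runs - mu) / sqrt(v)
}
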