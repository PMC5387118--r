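# Shared fixtures and independent oracles.

default_cell <- cell_properties()
default_fluid <- fluid_properties()
hard_substrate <- substrate_properties(stiffness = 1)

# Independent surface-of-revolution quadrature for the oblate-spheroid area:
# parametrised by latitude to keep the integrand smooth at the poles.
oblate_area_quadrature <- function(D_eq, h) {
  a <- D_eq / 2
  c <- h / 2
  f <- function(th) 2 * pi * a * cos(th) * sqrt((a * sin(th))^2 + (c * cos(th))^2)
  stats::integrate(f, -pi / 2, pi / 2, rel.tol = 1e-13, abs.tol = 0)$value
}

# Survival probability for one droplet with selective overrides, warnings off.
eta_of <- function(D_0, V_0, cell = default_cell, fluid = default_fluid,
                   S = 1, ...) {
  suppressWarnings(predict_impact(
    D_0, V_0, cell = cell, fluid = fluid,
    substrate = substrate_properties(stiffness = S), ...))$eta
}
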