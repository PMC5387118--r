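test_that("Weber and Reynolds numbers evaluate and scale correctly", {
  expect_equal(weber_number(1015, 10, 15e-6, 0.072), 21.1458333333,
               tolerance = 1e-9)
  expect_equal(reynolds_number(1015, 10, 15e-6, 0.012), 12.6875,
               tolerance = 1e-12)
  expect_identical(weber_number(1015, 0, 15e-6, 0.072), 0)
  expect_identical(reynolds_number(1015, 0, 15e-6, 0.012), 0)
  # We quadratic in V, Re inversely proportional to mu
  expect_equal(weber_number(1015, 20, 15e-6, 0.072),
               4 * weber_number(1015, 10, 15e-6, 0.072))
  expect_equal(reynolds_number(1015, 10, 15e-6, 0.024),
               reynolds_number(1015, 10, 15e-6, 0.012) / 2)
  expect_error(weber_number(-1, 10, 15e-6, 0.072), "rho")
  expect_error(weber_number(1015, 10, 0, 0.072), "D")
  expect_error(reynolds_number(1015, 10, 15e-6, 0), "mu")
  expect_error(weber_number(1015, -1, 15e-6, 0.072), "V")
})

test_that("substrate stiffness follows the capped linear gelatin law", {
  expect_identical(substrate_stiffness(0), 0)
  expect_identical(substrate_stiffness(0.1), 0.5)
  expect_identical(substrate_stiffness(0.2), 1)
  expect_identical(substrate_stiffness(0.5), 1)  # saturated
  expect_error(substrate_stiffness(-0.01), "C_g")
  expect_error(substrate_stiffness(1.5), "C_g")
})

test_that("effective impact interpolates between hard-wall and liquid-pool limits", {
  hard <- effective_impact(40e-6, 10, S = 1)
  expect_identical(hard$D_eff, 40e-6)
  expect_identical(hard$V_eff, 10)
  pool <- effective_impact(40e-6, 10, S = 0)
  expect_identical(pool$D_eff, 80e-6)
  expect_identical(pool$V_eff, 5)
  mid <- effective_impact(40e-6, 10, S = 0.5)
  expect_gt(mid$D_eff, 40e-6); expect_lt(mid$D_eff, 80e-6)
  expect_gt(mid$V_eff, 5); expect_lt(mid$V_eff, 10)
  # D_eff non-increasing, V_eff non-decreasing in S
  S <- seq(0, 1, 0.1)
  eff <- effective_impact(40e-6, 10, S)
  expect_true(all(diff(eff$D_eff) <= 0))
  expect_true(all(diff(eff$V_eff) >= 0))
  expect_error(effective_impact(40e-6, 10, S = 1.2), "S")
  expect_error(effective_impact(40e-6, 10, S = -0.1), "S")
})

test_that("spreading ratio is constant below the low-We threshold, then increases", {
  cst <- model_constants()
  r0 <- spreading_ratio(0, Re = 1e4)
  expect_gte(r0, 1)
  # flat region (i): no velocity dependence below We_low
  expect_equal(spreading_ratio(c(0.5, 2, 4.999), Re = 1e4), rep(r0, 3))
  # continuous at the matching point, strictly increasing beyond it
  expect_equal(spreading_ratio(cst$We_low, Re = 1e4), r0)
  We <- seq(cst$We_low, 200, length.out = 50)
  ratios <- spreading_ratio(We, Re = 1e6)
  expect_true(all(diff(ratios) > 0))
  expect_gt(spreading_ratio(50, Re = 1e4), spreading_ratio(10, Re = 1e4))
  # out-of-validity inputs warn with a dedicated class, never fail
  expect_warning(spreading_ratio(100, Re = 10), class = "cellspray_validity")
  expect_silent(spreading_ratio(100, Re = 1e6))
  expect_silent(spreading_ratio(100, Re = 10, warn = FALSE))
})

test_that("spheroid height conserves volume", {
  expect_equal(spheroid_height(10e-6, 10e-6), 10e-6)
  expect_equal(spheroid_height(10e-6, 20e-6), 2.5e-6)
  set.seed(11)
  D <- runif(50, 5e-6, 50e-6)
  Dmax <- D * runif(50, 1, 5)
  h <- spheroid_height(D, Dmax)
  expect_equal(pi / 6 * Dmax^2 * h, pi / 6 * D^3, tolerance = 1e-14)
})

test_that("deformation parameter spans sphere to plane", {
  expect_identical(deformation_M0(13e-6, 13e-6), 0)
  expect_equal(deformation_M0(13e-6, 26e-6), 7 / 9)  # ratio 2: (8-1)/(8+1)
  expect_equal(deformation_M0(1e-6, 1e-6 * 1e6), 1, tolerance = 1e-4)
  # strict monotonicity in the spreading ratio
  m <- deformation_M0(10e-6, 10e-6 * c(1, 1.5, 2, 3, 10))
  expect_true(all(diff(m) > 0))
  expect_true(all(m >= 0 & m < 1))
  expect_error(deformation_M0(10e-6, 9e-6), "D_max")
})

test_that("cushioning reduces deformation, more for big droplets and low viscosity", {
  # bare-cell limit: no surrounding liquid to cushion
  expect_equal(cushioned_deformation(0.8, D_ratio = 1, mu_ratio = 1), 0.8)
  expect_equal(cushioned_deformation(0.5, D_ratio = 1, mu_ratio = 0.01), 0.5)
  expect_lt(cushioned_deformation(0.8, D_ratio = 3, mu_ratio = 0.1), 0.8)
  # stronger cushioning for larger droplets
  expect_lt(cushioned_deformation(0.8, 3, 0.1),
            cushioned_deformation(0.8, 1.5, 0.1))
  # raising droplet viscosity weakens cushioning (deformation increases)
  mu <- c(1 / 12, 1 / 6, 1 / 3, 2 / 3, 1)
  m <- cushioned_deformation(0.8, 3, mu)
  expect_true(all(diff(m) > 0))
  # endpoints preserved
  expect_identical(cushioned_deformation(0, 3, 0.1), 0)
  expect_identical(cushioned_deformation(1, 3, 0.1), 1)
  expect_error(cushioned_deformation(0.8, 0.9, 0.1), "D_ratio")
  expect_error(cushioned_deformation(1.2, 3, 0.1), "M0")
})

test_that("spreading <-> deformation is an exact round trip", {
  expect_equal(spreading_from_deformation(0, 13e-6), 13e-6)
  for (M in c(0.1, 0.5, 0.9)) {
    D_max <- spreading_from_deformation(M, 13e-6)
    expect_equal(deformation_M0(13e-6, D_max), M, tolerance = 1e-9)
  }
  set.seed(4)
  M <- runif(100, 0, 0.999)
  back <- deformation_M0(10e-6, spreading_from_deformation(M, 10e-6))
  expect_equal(back, M, tolerance = 1e-9)
  expect_true(all(diff(spreading_from_deformation(seq(0, 0.99, 0.01), 1e-5)) > 0))
  expect_error(spreading_from_deformation(1, 13e-6), "plane limit")
})

test_that("spreading clamp takes the physical minimum", {
  expect_equal(clamp_spreading(12e-6, 15e-6, 20e-6), 12e-6)
  expect_equal(clamp_spreading(25e-6, 15e-6, 20e-6), 15e-6)
  expect_equal(clamp_spreading(18e-6, 30e-6, 16e-6), 16e-6)
  # literal reading ignores the cushion-derived diameter
  expect_equal(clamp_spreading(12e-6, 15e-6, 20e-6, mode = "literal"), 15e-6)
})

test_that("oblate-spheroid area matches the quadrature oracle", {
  # sphere limit
  expect_equal(oblate_area(10e-6, 10e-6), pi * (10e-6)^2, tolerance = 1e-12)
  # frozen oracle value for the 20 x 2.5 um spheroid
  expect_equal(oblate_area(20e-6, 2.5e-6), 6.557146555368e-10,
               tolerance = 1e-9)
  # 100 random aspect ratios against the oracle, including near-sphere
  set.seed(21)
  D_eq <- runif(100, 5e-6, 80e-6)
  ar <- c(runif(90, 0.02, 1), runif(10, 0.999, 1))
  h <- D_eq * ar
  closed <- oblate_area(D_eq, h)
  oracle <- vapply(seq_along(h), function(i) oblate_area_quadrature(D_eq[i], h[i]),
                   numeric(1))
  expect_equal(closed, oracle, tolerance = 1e-9)
  # the sphere minimises area at fixed volume
  D <- 10e-6
  D_max <- 20e-6
  expect_gt(oblate_area(D_max, spheroid_height(D, D_max)), pi * D^2)
  expect_error(oblate_area(10e-6, 12e-6), "prolate")
})

test_that("survival law is a linear ramp through the critical expansion", {
  expect_equal(survival_probability(1.5), 0.5)
  expect_equal(survival_probability(1.0), 1)
  expect_equal(survival_probability(2.0), 0)
  expect_gt(survival_probability(1.2), survival_probability(1.8))
  g <- seq(0, 3, 0.05)
  eta <- survival_probability(g)
  expect_true(all(eta >= 0 & eta <= 1))
  expect_true(all(diff(eta) <= 0))
  # compression does no damage
  expect_equal(survival_probability(0.4), 1)
  expect_error(survival_probability(-0.1), "gamma")
  # custom parameters move the midpoint
  expect_equal(survival_probability(2, survival_parameters(2, 0.25)), 0.5)
})

test_that("predict_impact chains all intermediates consistently", {
  out <- suppressWarnings(
    predict_impact(39e-6, 10, fluid = fluid_properties(viscosity = 0.0012)))
  expect_s3_class(out, "impact_outcome")
  # stored intermediates are mutually consistent
  expect_equal(out$We_c, weber_number(1015, out$V_eff, 13e-6, 0.072))
  expect_equal(out$h_spheroid * out$D_c_max^2, (13e-6)^3, tolerance = 1e-14)
  expect_equal(out$gamma, out$A_max / (pi * (13e-6)^2))
  expect_equal(out$eta, survival_probability(out$gamma))
  expect_true(out$M <= out$M0)
  expect_true(out$eta >= 0 && out$eta <= 1)
  # no impact, no membrane stretch
  expect_gt(eta_of(39e-6, 0, fluid = fluid_properties(viscosity = 0.0012)),
            0.99)
  # droplet must be able to contain the cell
  expect_error(predict_impact(10e-6, 5), ">= cell diameter")
  expect_error(predict_impact(c(30e-6, 40e-6), 5), "single droplet")
  # validity warning propagates from the spreading law
  expect_warning(predict_impact(20e-6, 30), class = "cellspray_validity")
})

test_that("viability responds monotonically to the four control parameters", {
  # velocity sweep (regime ii): eta non-increasing, reference droplet
  V <- seq(0, 50, 1)
  eta_V <- vapply(V, function(v) eta_of(39e-6, v), numeric(1))
  expect_true(all(diff(eta_V) <= 1e-12))
  expect_gt(eta_V[1], 0.99)
  expect_lt(eta_V[length(eta_V)], 0.05)
  # droplet size: larger droplets cushion more
  eta_D <- vapply(c(13, 19.5, 26, 32.5, 39) * 1e-6,
                  function(d) eta_of(d, 12), numeric(1))
  expect_true(all(diff(eta_D) >= -1e-12))
  # droplet viscosity: more viscous droplets are more lethal
  eta_mu <- vapply(c(1, 2, 4, 8, 12) * 1e-3, function(mu)
    eta_of(39e-6, 25, fluid = fluid_properties(viscosity = mu)), numeric(1))
  expect_true(all(diff(eta_mu) <= 1e-12))
  # substrate softness cushions
  eta_S <- vapply(seq(0, 1, 0.25), function(s) eta_of(30e-6, 15, S = s),
                  numeric(1))
  expect_true(all(diff(eta_S) <= 1e-12))
})

test_that("below the low-We threshold viability is velocity independent", {
  cell <- default_cell
  V_low <- sqrt(model_constants()$We_low * cell$surface_tension /
                  (cell$density * cell$diameter)) # We_c = We_low
  V <- seq(0, V_low * 0.999, length.out = 20)
  eta <- vapply(V, function(v) eta_of(26e-6, v), numeric(1))
  expect_equal(eta, rep(eta[1], length(eta)))
})

test_that("survival probability stays in [0,1] under parameter fuzzing", {
  set.seed(101)
  n <- 1e4
  cellD <- runif(n, 5e-6, 50e-6)
  D0 <- cellD * runif(n, 1, 4)
  V0 <- runif(n, 0, 80)
  mu0 <- 10^runif(n, -3.3, -1)
  S <- runif(n)
  eta <- vapply(seq_len(n), function(i) {
    cell <- cell_properties(diameter = cellD[i])
    fl <- fluid_properties(viscosity = mu0[i])
    suppressWarnings(predict_impact(D0[i], V0[i], cell = cell, fluid = fl,
                                    substrate = substrate_properties(stiffness = S[i])))$eta
  }, numeric(1))
  expect_true(all(is.finite(eta)))
  expect_true(all(eta >= 0 & eta <= 1))
})

test_that("property constructors validate their inputs", {
  expect_error(cell_properties(diameter = 2e-4), "\\[1e-6, 1e-4\\]")
  expect_error(cell_properties(viscosity = -1), "positive")
  expect_error(fluid_properties(density = 0), "positive")
  expect_error(substrate_properties(stiffness = 2), "\\[0, 1\\]")
  expect_error(survival_parameters(gamma_cr = 0.9), "> 1")
  expect_error(model_constants(C0 = -5), "positive")
  s <- substrate_properties(gelatin_fraction = 0.05)
  expect_equal(s$stiffness, 0.25)
})
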