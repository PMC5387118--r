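test_that("spray_sample validates its observations", {
  s <- spray_sample(D_0 = 30e-6, V_0 = 10)
  expect_s3_class(s, "spray_sample")
  expect_equal(s$observations$weight, 1)
  expect_error(spray_sample(numeric(0), numeric(0)), "at least one")
  expect_error(spray_sample(c(1e-5, 2e-5), 1), "equal length")
  expect_error(spray_sample(30e-6, -1), "non-negative")
  expect_error(spray_sample(30e-6, 10, weight = -1), "non-negative")
})

test_that("ensemble mean is the weighted per-droplet average", {
  # one droplet: the mean is its own survival probability
  one <- spray_sample(39e-6, 10)
  d1 <- predict_ensemble(one, fluid = fluid_properties(viscosity = 0.0012),
                         warn = FALSE)
  expect_equal(d1$mean_eta, d1$per_droplet_eta[1])
  expect_equal(d1$mean_eta,
               eta_of(39e-6, 10, fluid = fluid_properties(viscosity = 0.0012)))

  # a certain survivor (slow, large: gamma ~ 1.001) and a certain fatality
  # (fast, bare-sized: gamma ~ 6); both sit on a saturation plateau of a
  # survival band placed well clear of them
  pars <- survival_parameters(gamma_cr = 2, delta_gamma = 0.9)
  two <- spray_sample(c(60e-6, 13.5e-6), c(0.5, 40))
  d2 <- predict_ensemble(two, params = pars, warn = FALSE)
  expect_equal(d2$per_droplet_eta, c(1, 0))
  expect_equal(d2$mean_eta, 0.5)
  # unequal weights shift the mean accordingly
  d2w <- predict_ensemble(spray_sample(c(60e-6, 13.5e-6), c(0.5, 40),
                                       weight = c(3, 1)),
                          params = pars, warn = FALSE)
  expect_equal(d2w$mean_eta, 0.75)
})

test_that("ensemble is invariant to duplication and permutation", {
  set.seed(8)
  D <- runif(40, 14e-6, 60e-6)
  V <- runif(40, 0, 30)
  base <- predict_ensemble(spray_sample(D, V), warn = FALSE)
  dup <- predict_ensemble(spray_sample(c(D, D), c(V, V)), warn = FALSE)
  expect_equal(dup$mean_eta, base$mean_eta)
  p <- sample(40)
  perm <- predict_ensemble(spray_sample(D[p], V[p]), warn = FALSE)
  expect_equal(perm$mean_eta, base$mean_eta)
  expect_equal(sort(perm$per_droplet_eta), sort(base$per_droplet_eta))
  expect_equal(perm$bin_frequencies, base$bin_frequencies)
})

test_that("the viability histogram is a proper relative-incidence distribution", {
  set.seed(9)
  s <- spray_sample(runif(200, 14e-6, 60e-6), runif(200, 0, 30))
  d <- predict_ensemble(s, warn = FALSE)
  expect_equal(sum(d$bin_frequencies), 1)
  expect_length(d$bin_frequencies, 20)
  expect_equal(length(d$bin_edges), 21)
  expect_gte(d$mean_eta, min(d$per_droplet_eta))
  expect_lte(d$mean_eta, max(d$per_droplet_eta))
  # identical droplets occupy a single bin
  mono <- predict_ensemble(spray_sample(rep(30e-6, 25), rep(12, 25)),
                           warn = FALSE)
  expect_equal(sum(mono$bin_frequencies > 0), 1)
  # configurable bin count
  d5 <- predict_ensemble(s, bins = 5, warn = FALSE)
  expect_length(d5$bin_frequencies, 5)
})

test_that("droplets smaller than the cell are excluded (or treated as bare cells)", {
  s <- spray_sample(c(5e-6, 8e-6, 30e-6, 40e-6), c(10, 10, 10, 10))
  d <- predict_ensemble(s, warn = FALSE)
  expect_equal(d$excluded_fraction, 0.5)
  expect_length(d$per_droplet_eta, 2)
  bare <- predict_ensemble(s, small_droplets = "bare_cell", warn = FALSE)
  expect_length(bare$per_droplet_eta, 4)
  expect_equal(bare$excluded_fraction, 0)
  # small droplets behave as bare-cell impacts: most lethal case
  expect_lte(bare$mean_eta, d$mean_eta)
  expect_error(predict_ensemble(spray_sample(5e-6, 10), warn = FALSE),
               "smaller than the cell")
  expect_error(predict_ensemble(list()), "spray_sample")
})

test_that("ensemble warns once when part of the spectrum is out of validity", {
  s <- spray_sample(c(14e-6, 15e-6), c(30, 35))
  expect_warning(predict_ensemble(s), class = "cellspray_validity")
})

test_that("droplet tables round-trip through CSV losslessly", {
  set.seed(10)
  s <- spray_sample(runif(100, 2e-6, 90e-6), runif(100, 0, 40),
                    weight = runif(100, 0.1, 2),
                    pressure = 0.4e5, distance = 0.03, viscosity = 1e-3,
                    label = "round trip")
  f <- tempfile(fileext = ".csv")
  write_droplet_table(s, f)
  r <- read_droplet_table(f)
  expect_equal(r$observations$D_0, s$observations$D_0, tolerance = 1e-12)
  expect_equal(r$observations$V_0, s$observations$V_0, tolerance = 1e-12)
  expect_equal(r$observations$weight, s$observations$weight, tolerance = 1e-12)
  expect_equal(r$metadata, s$metadata)
})

test_that("droplet table parsing reports malformed input precisely", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("diameter_um,velocity_m_s", "30,10"), f)
  s <- read_droplet_table(f)
  expect_equal(s$observations$D_0, 30e-6)
  expect_equal(s$observations$V_0, 10)

  writeLines(c("diameter_um,velocity_m_s", "30,10", "oops,5"), f)
  expect_error(read_droplet_table(f), "line 3.*non-numeric")
  writeLines(c("diameter_um,velocity_m_s", "30,10", "7"), f)
  expect_error(read_droplet_table(f), "line 3.*expected 2 fields")
  writeLines(c("size,speed", "30,10"), f)
  expect_error(read_droplet_table(f), "diameter_um")
  writeLines(character(0), f)
  expect_error(read_droplet_table(f), "empty")
  expect_error(read_droplet_table(tempfile()), "not found")
})

test_that("viability maps are monotone and yield a unique 50% contour", {
  m <- viability_map(seq(15e-6, 80e-6, length.out = 12), seq(0, 45, 1.5))
  expect_equal(dim(m$eta), c(12, 31))
  # no impact, (almost) no damage: small constant low-We deformation only
  expect_true(all(m$eta[, 1] > 0.8))
  # each row non-increasing along velocity
  expect_true(all(apply(m$eta, 1, function(r) all(diff(r) <= 1e-12))))
  # at fixed lethal velocity, bigger droplets survive better
  expect_true(all(apply(m$eta, 2, function(c) all(diff(c) >= -1e-12))))
  # the 50% contour crosses each crossing row exactly once
  ct <- viability_contour(m, 0.5)
  crossed <- !is.na(ct$V_0)
  expect_gt(sum(crossed), 0)
  for (i in which(crossed)) {
    eta_at <- approx(m$V_grid, m$eta[i, ], xout = ct$V_0[i])$y
    expect_equal(eta_at, 0.5, tolerance = 1e-6)
  }
  # droplets smaller than the cell have no prediction
  m2 <- viability_map(c(5e-6, 20e-6), c(0, 10))
  expect_true(all(is.na(m2$eta[1, ])))
  expect_error(viability_map(c(2e-5, 1e-5), c(0, 1)), "sorted")
})

test_that("parameter sweeps reproduce the measured spray trends", {
  set.seed(12)
  s <- generate_spray(spray_config(), n = 2000, seed = 5)
  sw_g <- parameter_sweep("gelatin", c(0, 0.02, 0.05, 0.10, 0.20),
                          samples = s, warn = FALSE)
  expect_equal(nrow(sw_g), 5)
  expect_true(all(diff(sw_g$mean_eta) <= 0))  # softer substrate survives better
  sw_mu <- parameter_sweep("viscosity", c(1, 2, 4, 8, 12) * 1e-3,
                           samples = s, warn = FALSE)
  expect_true(all(diff(sw_mu$mean_eta) <= 0)) # viscous bio-inks are lethal
  # degenerate one-point grid
  one <- parameter_sweep("viscosity", 1e-3, samples = s, warn = FALSE)
  expect_equal(nrow(one), 1)
  # per-point samples via a generator function
  sw_p <- parameter_sweep(
    "pressure", c(0.2e5, 1e5),
    generator = function(p) generate_spray(spray_config(pressure = p),
                                           n = 2000, seed = 5),
    warn = FALSE)
  expect_lt(sw_p$mean_eta[2], sw_p$mean_eta[1])
  expect_error(parameter_sweep("viscosity", 1e-3), "no spray sample")
})
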