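#' Weber number
#'
#' Ratio of kinetic (inertial) to surface energy of an impacting drop,
#' We = rho V^2 D / sigma.
#'
#' @param rho Density in kg/m^3 (> 0).
#' @param V Impact velocity in m/s (>= 0). Vectorised.
#' @param D Diameter in m (> 0).
#' @param sigma Surface tension in N/m (> 0).
#' @return Dimensionless Weber number, same length as `V`.
#' @examples
#' weber_number(1015, 10, 15e-6, 0.072)
#' @export
weber_number <- function(rho, V, D, sigma) {
  check_dimensionless_inputs(rho, V, D, other = sigma, other_name = "sigma")
  rho * V^2 * D / sigma
}

#' Reynolds number
#'
#' Ratio of inertial to viscous forces, Re = rho V D / mu.
#'
#' @param rho Density in kg/m^3 (> 0).
#' @param V Velocity in m/s (>= 0). Vectorised.
#' @param D Diameter in m (> 0).
#' @param mu Dynamic viscosity in Pa s (> 0).
#' @return Dimensionless Reynolds number, same length as `V`.
#' @examples
#' reynolds_number(1015, 10, 15e-6, 0.012)
#' @export
reynolds_number <- function(rho, V, D, mu) {
  check_dimensionless_inputs(rho, V, D, other = mu, other_name = "mu")
  rho * V * D / mu
}

check_dimensionless_inputs <- function(rho, V, D, other, other_name) {
  if (any(rho <= 0)) stop("rho must be positive", call. = FALSE)
  if (any(D <= 0)) stop("D must be positive", call. = FALSE)
  if (any(other <= 0)) stop(other_name, " must be positive", call. = FALSE)
  if (any(V < 0)) stop("V must be non-negative", call. = FALSE)
  invisible(NULL)
}

#' Substrate stiffness from gelatin mass fraction
#'
#' Maps the gelatin mass fraction of a gelatin-water substrate to the
#' dimensionless stiffness parameter, S = min(1, C1 * C_g). With the fitted
#' C1 = 5 any substrate with C_g > 0.2 behaves as effectively stiff (S = 1);
#' C_g = 0 is the liquid-pool limit (S = 0).
#'
#' @param C_g Gelatin mass fraction in [0, 1]. Vectorised.
#' @param constants A [model_constants()] object supplying C1.
#' @return Stiffness S in [0, 1].
#' @examples
#' substrate_stiffness(c(0, 0.05, 0.2, 0.5))
#' @export
substrate_stiffness <- function(C_g, constants = model_constants()) {
  if (any(is.na(C_g)) || any(C_g < 0) || any(C_g > 1)) {
    stop("gelatin mass fraction C_g must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, constants$C1 * C_g)
}

#' Effective impact parameters on a soft substrate
#'
#' Impact on a deformable substrate is mapped to an equivalent hard-substrate
#' impact. A droplet hitting a liquid pool (S = 0) behaves, to first
#' approximation, like a droplet of twice the diameter at half the velocity
#' hitting a hard wall; a hard substrate (S = 1) leaves the parameters
#' unchanged. In between the mapping interpolates linearly:
#' D_eff = (2 - S) D_0 and V_eff = (1 + S)/2 V_0.
#'
#' @param D_0 Droplet diameter in m (> 0). Vectorised.
#' @param V_0 Impact velocity in m/s (>= 0). Vectorised.
#' @param S Substrate stiffness in [0, 1].
#' @return A list with components `D_eff` (m) and `V_eff` (m/s).
#' @examples
#' effective_impact(40e-6, 10, S = 0)   # liquid pool: 80 um at 5 m/s
#' effective_impact(40e-6, 10, S = 1)   # glass: unchanged
#' @export
effective_impact <- function(D_0, V_0, S) {
  if (any(D_0 <= 0)) stop("D_0 must be positive", call. = FALSE)
  if (any(V_0 < 0)) stop("V_0 must be non-negative", call. = FALSE)
  if (any(is.na(S)) || any(S < 0) || any(S > 1)) {
    stop("stiffness S must lie in [0, 1]", call. = FALSE)
  }
  list(D_eff = (2 - S) * D_0, V_eff = (1 + S) / 2 * V_0)
}

#' Maximal spreading ratio of an impacting drop
#'
#' Capillary-regime spreading law for the maximal spreading diameter of a
#' Newtonian drop on a hard surface: D_max / D = 0.9 We^(1/4) for We >= 5.
#' Below We = 5 the kinetic energy is too small to drive spreading and a
#' small, constant deformation is assumed, equal to the We = 5 value
#' (0.9 * 5^(1/4) ~ 1.35), which makes the law continuous at the threshold.
#'
#' The law holds in the capillary regime We <= Re^(4/5); outside it a
#' warning of class `cellspray_validity` is emitted (never an error).
#'
#' @param We Weber number (>= 0). Vectorised.
#' @param Re Reynolds number (> 0). Vectorised.
#' @param constants A [model_constants()] object (uses `We_low`,
#'   `spread_coef`).
#' @param warn Emit the out-of-validity warning? Set `FALSE` when the caller
#'   aggregates validity flags itself.
#' @return Spreading ratio D_max / D (>= 1).
#' @examples
#' spreading_ratio(c(0, 5, 20, 100), Re = 1e4)
#' @export
spreading_ratio <- function(We, Re, constants = model_constants(),
                            warn = TRUE) {
  if (any(We < 0)) stop("We must be non-negative", call. = FALSE)
  if (any(Re <= 0)) stop("Re must be positive", call. = FALSE)
  bad <- We > Re^(4 / 5)
  if (warn && any(bad)) {
    warning(warningCondition(
      sprintf(paste0("spreading law evaluated outside its capillary-regime ",
                     "validity We <= Re^(4/5) for %d of %d input(s)"),
              sum(bad), length(bad)),
      class = c("cellspray_validity", "warning")
    ))
  }
  pmax(1, constants$spread_coef * pmax(We, constants$We_low)^(1 / 4))
}

#' Height of the maximally spread oblate spheroid
#'
#' At maximal extension the drop (or cell) is an oblate spheroid of equatorial
#' diameter `D_max`; volume conservation with the resting sphere of diameter
#' `D` forces its height to h = D^3 / D_max^2.
#'
#' @param D Resting diameter in m (> 0). Vectorised.
#' @param D_max Maximal spreading diameter in m (> 0). Vectorised.
#' @return Spheroid height h in m.
#' @examples
#' spheroid_height(10e-6, 20e-6)   # 2.5 um
#' @export
spheroid_height <- function(D, D_max) {
  if (any(D <= 0) || any(D_max <= 0)) {
    stop("D and D_max must be positive", call. = FALSE)
  }
  D^3 / D_max^2
}

#' Deformation parameter of a flattened cell
#'
#' Taylor-type deformation of an oblate spheroid relative to its resting
#' sphere, M0 = (D_max - h)/(D_max + h) with h the volume-conserving height.
#' Equivalently M0 = (r^3 - 1)/(r^3 + 1) in terms of the spreading ratio
#' r = D_max/D. M0 = 0 for an undeformed sphere and M0 -> 1 as the cell is
#' flattened towards a plane.
#'
#' @param D Resting diameter in m (> 0). Vectorised.
#' @param D_max Maximal spreading diameter in m (>= D).
#' @return Deformation M0 in [0, 1).
#' @examples
#' deformation_M0(13e-6, 13e-6)   # sphere: 0
#' deformation_M0(13e-6, 26e-6)
#' @export
deformation_M0 <- function(D, D_max) {
  if (any(D <= 0)) stop("D must be positive", call. = FALSE)
  if (any(D_max < D)) {
    stop("D_max must be >= D (oblate deformation only)", call. = FALSE)
  }
  r3 <- (D_max / D)^3
  (r3 - 1) / (r3 + 1)
}

#' Cushioned deformation of a cell inside a droplet
#'
#' The surrounding droplet absorbs part of the impact, reducing the cell
#' deformation from its bare-cell value M0 by attenuating the deformation
#' odds M/(1 - M):
#' M = M0 / (M0 + (1 - M0) K), with cushioning strength
#' K = 1 + C0 (D_0/D_c - 1) / (1 + mu_0/mu_c) and C0 = 5 a fitting constant.
#' Larger surrounding droplets cushion more strongly; raising the droplet
#' viscosity weakens the cushioning (the stiffened droplet transmits its
#' impact into the cell), so M increases with mu_0/mu_c. A bare cell
#' (D_0 = D_c, K = 1) is left uncushioned regardless of viscosity, and in
#' the plane limit M0 -> 1 no finite cushioning prevents flattening
#' (M -> 1).
#'
#' @param M0 Bare-cell deformation in [0, 1]. Vectorised.
#' @param D_ratio Droplet-to-cell diameter ratio D_0/D_c (>= 1).
#' @param mu_ratio Droplet-to-cell viscosity ratio mu_0/mu_c (> 0).
#' @param constants A [model_constants()] object supplying C0.
#' @return Cushioned deformation M in [0, M0].
#' @examples
#' cushioned_deformation(0.8, D_ratio = 3, mu_ratio = 0.1)
#' @export
cushioned_deformation <- function(M0, D_ratio, mu_ratio,
                                  constants = model_constants()) {
  if (any(M0 < 0) || any(M0 > 1)) stop("M0 must lie in [0, 1]", call. = FALSE)
  if (any(D_ratio < 1)) {
    stop("D_ratio must be >= 1: the cell cannot exceed its droplet",
         call. = FALSE)
  }
  if (any(mu_ratio <= 0)) stop("mu_ratio must be positive", call. = FALSE)
  K <- 1 + constants$C0 * (D_ratio - 1) / (1 + mu_ratio)
  M0 / (M0 + (1 - M0) * K)
}

#' Maximal spreading diameter from the deformation parameter
#'
#' Inverts the deformation definition under volume conservation:
#' D_c,max = D_c ((1 + M)/(1 - M))^(1/3). Exact inverse of
#' [deformation_M0()].
#'
#' @param M Deformation in [0, 1). Vectorised.
#' @param D_c Resting cell diameter in m (> 0).
#' @return Maximal spreading diameter in m.
#' @examples
#' spreading_from_deformation(0.5, 13e-6)
#' @export
spreading_from_deformation <- function(M, D_c) {
  if (any(M < 0) || any(M >= 1)) {
    stop("M must lie in [0, 1): M = 1 is the infinite-spreading plane limit",
         call. = FALSE)
  }
  if (any(D_c <= 0)) stop("D_c must be positive", call. = FALSE)
  D_c * ((1 + M) / (1 - M))^(1 / 3)
}

#' Clamp the cell spreading diameter
#'
#' The cushion-derived spreading diameter can occasionally exceed both the
#' bare-cell spreading and the droplet's own spreading diameter; neither is
#' physical. The default ("cushioned") reading takes
#' D_c,max = min(D_from_M, D_c,max,0, D_max): cushioning can only reduce
#' spreading and the cell never spreads beyond its droplet. The "literal"
#' reading, min(D_c,max,0, D_max), ignores the cushioning result in the clamp.
#'
#' @param D_from_M Cushion-derived cell spreading diameter in m. Vectorised.
#' @param D_c_max_0 Bare-cell maximal spreading diameter in m.
#' @param D_max Droplet maximal spreading diameter in m.
#' @param mode `"cushioned"` (default) or `"literal"`.
#' @return Final cell spreading diameter D_c,max in m.
#' @examples
#' clamp_spreading(25e-6, 15e-6, 20e-6)   # capped at 15 um
#' @export
clamp_spreading <- function(D_from_M, D_c_max_0, D_max,
                            mode = c("cushioned", "literal")) {
  mode <- match.arg(mode)
  if (any(D_from_M <= 0) || any(D_c_max_0 <= 0) || any(D_max <= 0)) {
    stop("all diameters must be positive", call. = FALSE)
  }
  if (mode == "cushioned") {
    pmin(D_from_M, D_c_max_0, D_max)
  } else {
    pmin(D_c_max_0, D_max)
  }
}

#' Surface area of an oblate spheroid
#'
#' Closed-form area of an oblate spheroid of equatorial diameter `D_eq` and
#' polar diameter (height) `h`:
#' A = 2 pi a^2 + 2 pi c^2 atanh(e)/e with a = D_eq/2, c = h/2 and
#' eccentricity e = sqrt(1 - c^2/a^2). Reduces to the sphere area pi D^2 for
#' h = D_eq; a series expansion is used near the sphere limit for numerical
#' stability.
#'
#' @param D_eq Equatorial diameter in m (>= h). Vectorised.
#' @param h Polar diameter in m (> 0).
#' @return Surface area in m^2.
#' @examples
#' oblate_area(10e-6, 10e-6)   # pi * (10 um)^2
#' oblate_area(20e-6, 2.5e-6)
#' @export
oblate_area <- function(D_eq, h) {
  if (any(h <= 0)) stop("h must be positive", call. = FALSE)
  if (any(h > D_eq * (1 + 1e-12))) {
    stop("h must not exceed D_eq (prolate spheroids are not modelled)",
         call. = FALSE)
  }
  a <- D_eq / 2
  c <- pmin(h, D_eq) / 2
  e2 <- pmax(0, 1 - (c / a)^2)
  e <- sqrt(e2)
  # atanh(e)/e: series for small e avoids 0/0 at the sphere limit
  f <- ifelse(e < 1e-4,
              1 + e2 / 3 + e2^2 / 5,
              atanh(e) / e)
  2 * pi * a^2 + 2 * pi * c^2 * f
}

#' Survival probability from relative membrane area
#'
#' Stretch-rupture survival law: the probability that a cell survives a
#' membrane-area expansion to `gamma` times its resting area is 1 below
#' gamma_cr - delta_gamma, 0 above gamma_cr + delta_gamma, and falls linearly
#' in between, so eta(gamma_cr) = 1/2 exactly. Values of gamma below 1
#' (compression) are floored at 1: the law models stretch-induced rupture
#' only.
#'
#' @param gamma Relative membrane area (>= 0). Vectorised.
#' @param params A [survival_parameters()] object.
#' @return Survival probability eta in [0, 1].
#' @examples
#' survival_probability(c(1, 1.25, 1.5, 1.75, 2))
#' @export
survival_probability <- function(gamma, params = survival_parameters()) {
  if (any(gamma < 0)) stop("gamma must be non-negative", call. = FALSE)
  g <- pmax(gamma, 1)
  eta <- (params$gamma_cr + params$delta_gamma - g) / (2 * params$delta_gamma)
  pmin(1, pmax(0, eta))
}

# Vectorised model chain: from (D_0, V_0) to survival probability, with all
# intermediates. Inputs in SI units; D_0 and V_0 may be vectors.
# Returns a data.frame, one row per droplet.
impact_chain <- function(D_0, V_0, cell, fluid, substrate,
                         params = survival_parameters(),
                         constants = model_constants(),
                         clamp = c("cushioned", "literal")) {
  clamp <- match.arg(clamp)
  n <- max(length(D_0), length(V_0))
  D_0 <- rep_len(D_0, n)
  V_0 <- rep_len(V_0, n)
  if (any(D_0 < cell$diameter)) {
    stop("droplet diameter D_0 must be >= cell diameter D_c", call. = FALSE)
  }

  eff <- effective_impact(D_0, V_0, substrate$stiffness)
  D_eff <- eff$D_eff
  V_eff <- eff$V_eff

  We_c <- weber_number(cell$density, V_eff, cell$diameter,
                       cell$surface_tension)
  Re_c <- reynolds_number(cell$density, V_eff, cell$diameter, cell$viscosity)
  We_0 <- weber_number(fluid$density, V_eff, D_eff, fluid$surface_tension)
  Re_0 <- reynolds_number(fluid$density, V_eff, D_eff, fluid$viscosity)

  # validity of the capillary spreading law, flagged not fatal
  valid_cell <- We_c <= pmax(Re_c, .Machine$double.xmin)^(4 / 5) | V_eff == 0
  valid_drop <- We_0 <= pmax(Re_0, .Machine$double.xmin)^(4 / 5) | V_eff == 0

  ratio_c <- spreading_ratio(We_c, pmax(Re_c, .Machine$double.xmin),
                             constants, warn = FALSE)
  ratio_0 <- spreading_ratio(We_0, pmax(Re_0, .Machine$double.xmin),
                             constants, warn = FALSE)
  D_c_max_0 <- ratio_c * cell$diameter
  D_max <- ratio_0 * D_eff

  M0 <- deformation_M0(cell$diameter, D_c_max_0)
  M <- cushioned_deformation(M0, D_eff / cell$diameter,
                             fluid$viscosity / cell$viscosity, constants)
  D_from_M <- spreading_from_deformation(M, cell$diameter)
  D_c_max <- clamp_spreading(D_from_M, D_c_max_0, D_max, mode = clamp)
  # the caps cannot push the cell below its resting diameter in practice,
  # but guard the degenerate case: an unclamped sphere stays a sphere
  D_c_max <- pmax(D_c_max, cell$diameter)

  h <- spheroid_height(cell$diameter, D_c_max)
  A_max <- oblate_area(D_c_max, h)
  A_sphere <- pi * cell$diameter^2
  gamma <- pmax(1, A_max / A_sphere)
  eta <- survival_probability(gamma, params)

  data.frame(
    D_0 = D_0, V_0 = V_0, D_eff = D_eff, V_eff = V_eff,
    We_c = We_c, Re_c = Re_c, We_0 = We_0, Re_0 = Re_0,
    D_c_max_0 = D_c_max_0, D_max = D_max,
    M0 = M0, M = M, D_c_max = D_c_max, h_spheroid = h,
    A_max = A_max, gamma = gamma, eta = eta,
    valid_cell = valid_cell, valid_drop = valid_drop
  )
}

#' Predict single-cell survival for one droplet impact
#'
#' Runs the full analytical chain for a single cell-containing droplet:
#' soft-substrate mapping to effective impact parameters, Weber/Reynolds
#' numbers for cell and droplet, maximal-spreading laws, bare-cell
#' deformation, compound-droplet cushioning, spreading clamp, oblate-spheroid
#' geometry, relative membrane area and finally the survival probability.
#'
#' @param D_0 Droplet diameter in m (must be >= the cell diameter).
#' @param V_0 Impact velocity in m/s (>= 0).
#' @param cell A [cell_properties()] object.
#' @param fluid A [fluid_properties()] object.
#' @param substrate A [substrate_properties()] object.
#' @param params A [survival_parameters()] object.
#' @param constants A [model_constants()] object.
#' @param clamp Spreading-clamp semantics, `"cushioned"` (default) or
#'   `"literal"`; see [clamp_spreading()].
#' @param warn Emit a `cellspray_validity` warning when the spreading law is
#'   evaluated outside its validity regime?
#' @return An object of class `impact_outcome`: a list with every
#'   intermediate of the chain (`We_c`, `Re_c`, `We_0`, `Re_0`, `D_eff`,
#'   `V_eff`, `D_c_max_0`, `D_max`, `M0`, `M`, `D_c_max`, `h_spheroid`,
#'   `A_max`, `gamma`) and the survival probability `eta`.
#' @examples
#' out <- predict_impact(D_0 = 39e-6, V_0 = 10)
#' out$eta
#' print(out)
#' @export
predict_impact <- function(D_0, V_0,
                           cell = cell_properties(),
                           fluid = fluid_properties(),
                           substrate = substrate_properties(),
                           params = survival_parameters(),
                           constants = model_constants(),
                           clamp = c("cushioned", "literal"),
                           warn = TRUE) {
  if (length(D_0) != 1 || length(V_0) != 1) {
    stop("predict_impact() handles a single droplet; ",
         "use predict_ensemble() for spectra", call. = FALSE)
  }
  row <- impact_chain(D_0, V_0, cell, fluid, substrate, params, constants,
                      clamp = match.arg(clamp))
  if (warn && (!row$valid_cell || !row$valid_drop)) {
    warning(warningCondition(
      "spreading law evaluated outside its capillary-regime validity",
      class = c("cellspray_validity", "warning")
    ))
  }
  out <- as.list(row)
  out$cell <- cell
  out$fluid <- fluid
  out$substrate <- substrate
  class(out) <- "impact_outcome"
  out
}

#' @export
print.impact_outcome <- function(x, ...) {
  cat("Droplet impact outcome\n")
  cat(sprintf("  droplet      D_0 = %8.3f um   V_0 = %7.3f m/s\n",
              x$D_0 * 1e6, x$V_0))
  cat(sprintf("  effective    D_eff = %6.3f um   V_eff = %5.3f m/s (S = %g)\n",
              x$D_eff * 1e6, x$V_eff, x$substrate$stiffness))
  cat(sprintf("  cell         We_c = %8.3f    Re_c = %8.3f\n", x$We_c, x$Re_c))
  cat(sprintf("  droplet      We_0 = %8.3f    Re_0 = %8.3f\n", x$We_0, x$Re_0))
  cat(sprintf("  spreading    D_c,max,0 = %7.3f um   D_max = %7.3f um\n",
              x$D_c_max_0 * 1e6, x$D_max * 1e6))
  cat(sprintf("  deformation  M0 = %6.4f   M = %6.4f (cushioned)\n",
              x$M0, x$M))
  cat(sprintf("  cell shape   D_c,max = %7.3f um   h = %6.3f um\n",
              x$D_c_max * 1e6, x$h_spheroid * 1e6))
  cat(sprintf("  membrane     A_max = %.4g m^2   gamma = %6.4f\n",
              x$A_max, x$gamma))
  cat(sprintf("  survival     eta = %6.4f\n", x$eta))
  if (!x$valid_cell || !x$valid_drop) {
    cat("  note: spreading law outside capillary-regime validity\n")
  }
  invisible(x)
}
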