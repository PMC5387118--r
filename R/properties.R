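#' Physical description of the impacting cell
#'
#' The cell is modelled as a spherical liquid droplet characterised by its
#' diameter, dynamic viscosity, mass density and surface tension. Defaults are
#' typical values for a trypsinized mammalian cell in suspension: a viscous
#' (12 mPa s) liquid sphere of 13 um, slightly denser than water, with an
#' effective surface tension equal to that of water.
#'
#' @param diameter Cell diameter D_c in m. Must lie in [1e-6, 1e-4] m.
#' @param viscosity Dynamic viscosity mu_c in Pa s.
#' @param density Mass density rho_c in kg/m^3.
#' @param surface_tension Effective surface tension sigma_c in N/m.
#' @return An object of class `cell_properties`.
#' @examples
#' cell_properties()
#' cell_properties(diameter = 15e-6)
#' @export
cell_properties <- function(diameter = 13e-6,
                            viscosity = 0.012,
                            density = 1015,
                            surface_tension = 0.072) {
  stop_if_not_positive(diameter, "diameter")
  stop_if_not_positive(viscosity, "viscosity")
  stop_if_not_positive(density, "density")
  stop_if_not_positive(surface_tension, "surface_tension")
  if (diameter < 1e-6 || diameter > 1e-4) {
    stop("cell diameter must lie in [1e-6, 1e-4] m (got ",
         format(diameter), " m)", call. = FALSE)
  }
  structure(
    list(diameter = diameter, viscosity = viscosity, density = density,
         surface_tension = surface_tension),
    class = "cell_properties"
  )
}

#' Physical properties of the carrier liquid (bio-ink)
#'
#' Describes the droplet liquid surrounding the cell. The default is a
#' water-like culture medium: the reference spray liquid has a viscosity of
#' 1 mPa s; density and surface tension default to those of water.
#'
#' @param viscosity Dynamic viscosity mu_0 in Pa s.
#' @param density Mass density rho_0 in kg/m^3.
#' @param surface_tension Surface tension sigma_0 in N/m.
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties()                    # water-like medium, 1 mPa s
#' fluid_properties(viscosity = 8e-3)    # dextran-thickened bio-ink
#' @export
fluid_properties <- function(viscosity = 0.001,
                             density = 1000,
                             surface_tension = 0.072) {
  stop_if_not_positive(viscosity, "viscosity")
  stop_if_not_positive(density, "density")
  stop_if_not_positive(surface_tension, "surface_tension")
  structure(
    list(viscosity = viscosity, density = density,
         surface_tension = surface_tension),
    class = "fluid_properties"
  )
}

#' Impact-substrate stiffness
#'
#' The substrate is summarised by a dimensionless stiffness parameter S,
#' ranging from S = 0 for a liquid pool to S = 1 for a hard (glass) surface.
#' For gelatin-coated substrates S is mapped linearly from the gelatin mass
#' fraction, S = min(1, C1 * C_g), so that substrates with C_g > 1/C1 behave
#' as effectively stiff.
#'
#' @param stiffness Dimensionless stiffness S in [0, 1]. Ignored when
#'   `gelatin_fraction` is supplied.
#' @param gelatin_fraction Optional gelatin mass fraction C_g in [0, 1].
#' @param constants A [model_constants()] object supplying C1.
#' @return An object of class `substrate_properties` with fields `stiffness`
#'   and (possibly `NA`) `gelatin_fraction`.
#' @examples
#' substrate_properties()                        # hard glass, S = 1
#' substrate_properties(gelatin_fraction = 0.05) # soft gelatin, S = 0.25
#' @export
substrate_properties <- function(stiffness = 1,
                                 gelatin_fraction = NULL,
                                 constants = model_constants()) {
  if (!is.null(gelatin_fraction)) {
    stiffness <- substrate_stiffness(gelatin_fraction, constants)
  } else {
    gelatin_fraction <- NA_real_
  }
  if (!is.numeric(stiffness) || length(stiffness) != 1 ||
      is.na(stiffness) || stiffness < 0 || stiffness > 1) {
    stop("substrate stiffness S must be a single value in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(stiffness = stiffness, gelatin_fraction = gelatin_fraction),
    class = "substrate_properties"
  )
}

#' Parameters of the membrane-stretch survival law
#'
#' Cell survival is governed by the relative membrane area gamma reached at
#' maximal deformation. Survival is certain below `gamma_cr - delta_gamma`,
#' impossible above `gamma_cr + delta_gamma`, and falls linearly in between;
#' the defaults place the 50% point at the critical membrane expansion
#' gamma_cr = 1.5 with a partial-survival band of total width 2*delta_gamma = 1.
#'
#' @param gamma_cr Critical relative membrane area (> 1).
#' @param delta_gamma Half-width of the partial-survival band (> 0).
#' @return An object of class `survival_parameters`.
#' @examples
#' survival_parameters()
#' @export
survival_parameters <- function(gamma_cr = 1.5, delta_gamma = 0.5) {
  if (!is.numeric(gamma_cr) || length(gamma_cr) != 1 || gamma_cr <= 1) {
    stop("gamma_cr must be a single value > 1", call. = FALSE)
  }
  stop_if_not_positive(delta_gamma, "delta_gamma")
  structure(list(gamma_cr = gamma_cr, delta_gamma = delta_gamma),
            class = "survival_parameters")
}

#' Fitted constants of the impact model
#'
#' @param C0 Cushioning fit constant of the compound-droplet deformation
#'   equation (dimensionless; default 5).
#' @param C1 Stiffness fit constant mapping gelatin mass fraction to substrate
#'   stiffness, S = C1 * C_g (default 5).
#' @param We_low Weber number below which a small, constant cell deformation
#'   is assumed (default 5).
#' @param spread_coef Prefactor of the capillary-regime maximal-spreading law
#'   D_max/D = spread_coef * We^(1/4) (default 0.9).
#' @return An object of class `model_constants`.
#' @examples
#' model_constants()
#' @export
model_constants <- function(C0 = 5, C1 = 5, We_low = 5, spread_coef = 0.9) {
  stop_if_not_positive(C0, "C0")
  stop_if_not_positive(C1, "C1")
  stop_if_not_positive(We_low, "We_low")
  stop_if_not_positive(spread_coef, "spread_coef")
  structure(list(C0 = C0, C1 = C1, We_low = We_low, spread_coef = spread_coef),
            class = "model_constants")
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    stop(name, " must be a single positive number", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.cell_properties <- function(x, ...) {
  cat("Cell (liquid-sphere model):\n")
  cat(sprintf("  diameter        D_c     = %g um\n", x$diameter * 1e6))
  cat(sprintf("  viscosity       mu_c    = %g mPa s\n", x$viscosity * 1e3))
  cat(sprintf("  density         rho_c   = %g kg/m^3\n", x$density))
  cat(sprintf("  surface tension sigma_c = %g N/m\n", x$surface_tension))
  invisible(x)
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Carrier liquid (bio-ink):\n")
  cat(sprintf("  viscosity       mu_0    = %g mPa s\n", x$viscosity * 1e3))
  cat(sprintf("  density         rho_0   = %g kg/m^3\n", x$density))
  cat(sprintf("  surface tension sigma_0 = %g N/m\n", x$surface_tension))
  invisible(x)
}

#' @export
print.substrate_properties <- function(x, ...) {
  cat(sprintf("Substrate: stiffness S = %g", x$stiffness))
  if (!is.na(x$gelatin_fraction)) {
    cat(sprintf(" (gelatin mass fraction C_g = %g)", x$gelatin_fraction))
  }
  cat("\n")
  invisible(x)
}
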