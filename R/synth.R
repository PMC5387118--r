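#' Configuration of the synthetic spray generator
#'
#' A seeded statistical stand-in for measured two-phase-nozzle spray spectra.
#' It emulates their key structure: highly polydisperse, right-skewed droplet
#' sizes whose median shrinks with driving pressure, and velocities that rise
#' with pressure and decay with distance from the nozzle. Droplet diameters
#' follow a log-normal law with median `d_ref * (p_ref / P)^d_exp`; velocities
#' follow `v_coef * (P / p_ref)^v_exp * exp(-h / decay_length)` with
#' multiplicative Gaussian noise and a weak positive size-velocity coupling
#' (small droplets decelerate faster in air). All coefficients are synthetic
#' stand-ins, not fitted to any measured spectrum; measured tables can be used
#' instead via [read_droplet_table()].
#'
#' @param pressure Driving air pressure P in Pa (> 0).
#' @param distance Nozzle-substrate distance h in m (> 0).
#' @param viscosity Liquid viscosity in Pa s (metadata only; the spray
#'   spectrum is taken to be viscosity-independent).
#' @param d_ref Median droplet diameter at the reference pressure, m.
#' @param p_ref Reference pressure, Pa.
#' @param d_exp Exponent of the median-diameter shrinkage with pressure.
#' @param sdlog Log-scale standard deviation of the diameter law (> 0).
#' @param v_coef Velocity scale at the reference pressure and zero distance,
#'   m/s.
#' @param v_exp Exponent of the velocity growth with pressure.
#' @param decay_length Exponential decay length of velocity with distance, m.
#' @param noise Relative standard deviation of the velocity noise.
#' @param size_vel_corr Exponent coupling velocity to relative droplet size.
#' @param seed Default integer seed used by [generate_spray()].
#' @return An object of class `spray_config`.
#' @examples
#' spray_config()
#' spray_preset("reference")
#' @export
spray_config <- function(pressure = 0.4e5,
                         distance = 0.03,
                         viscosity = 0.001,
                         d_ref = 30e-6,
                         p_ref = 0.4e5,
                         d_exp = 0.4,
                         sdlog = 0.5,
                         v_coef = 12,
                         v_exp = 0.6,
                         decay_length = 0.1,
                         noise = 0.25,
                         size_vel_corr = 0.15,
                         seed = 1L) {
  stop_if_not_positive(pressure, "pressure")
  stop_if_not_positive(distance, "distance")
  stop_if_not_positive(viscosity, "viscosity")
  stop_if_not_positive(d_ref, "d_ref")
  stop_if_not_positive(p_ref, "p_ref")
  stop_if_not_positive(sdlog, "sdlog")
  stop_if_not_positive(v_coef, "v_coef")
  stop_if_not_positive(decay_length, "decay_length")
  if (!is.numeric(noise) || noise < 0) stop("noise must be >= 0", call. = FALSE)
  structure(
    list(pressure = pressure, distance = distance, viscosity = viscosity,
         d_ref = d_ref, p_ref = p_ref, d_exp = d_exp, sdlog = sdlog,
         v_coef = v_coef, v_exp = v_exp, decay_length = decay_length,
         noise = noise, size_vel_corr = size_vel_corr,
         seed = as.integer(seed)),
    class = "spray_config"
  )
}

#' @export
print.spray_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic spray generator: P = %g x 10^5 Pa, ",
                     "h = %g mm, mu = %g mPa s (seed %d)\n"),
              x$pressure / 1e5, x$distance * 1e3, x$viscosity * 1e3, x$seed))
  invisible(x)
}

#' Named presets of the spray generator
#'
#' `"reference"` encodes the reference spray setting (P = 0.4e5 Pa,
#' mu = 1 mPa s, h = 3 cm). Pressure presets `"pressure_0.2"` ...
#' `"pressure_1.0"` span the measured pressure series in units of 1e5 Pa;
#' distance presets `"distance_30"` ... `"distance_150"` span the
#' nozzle-distance series in mm, all other settings at reference.
#'
#' @param name Preset name.
#' @return A [spray_config()].
#' @examples
#' spray_preset("reference")
#' spray_preset("distance_150")
#' @export
spray_preset <- function(name) {
  presets <- c("reference",
               paste0("pressure_", c("0.2", "0.4", "0.6", "0.8", "1.0")),
               paste0("distance_", c("30", "50", "100", "150")))
  if (length(name) != 1 || !name %in% presets) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(presets, collapse = ", "),
         call. = FALSE)
  }
  if (name == "reference") return(spray_config())
  value <- as.numeric(sub("^[a-z]+_", "", name))
  if (startsWith(name, "pressure_")) {
    spray_config(pressure = value * 1e5)
  } else {
    spray_config(distance = value * 1e-3)
  }
}

#' Generate a synthetic spray sample
#'
#' Draws `n` droplets from the statistical model described in
#' [spray_config()]. Diameters are clipped to the 1-100 um range of the
#' shadowgraph detection; velocities are non-negative. Identical seeds give
#' identical samples; the caller's RNG state is left untouched.
#'
#' @param config A [spray_config()].
#' @param n Number of droplets (>= 1).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A [spray_sample()] carrying the generator's pressure, distance and
#'   viscosity as metadata.
#' @examples
#' s <- generate_spray(spray_preset("reference"), n = 500)
#' s
#' @export
generate_spray <- function(config = spray_config(), n, seed = config$seed) {
  if (!inherits(config, "spray_config")) {
    stop("config must be a spray_config object", call. = FALSE)
  }
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)

  with_seed(seed, {
    median_d <- config$d_ref * (config$p_ref / config$pressure)^config$d_exp
    D <- stats::rlnorm(n, meanlog = log(median_d), sdlog = config$sdlog)
    D <- pmin(pmax(D, 1e-6), 100e-6)

    v_mean <- config$v_coef *
      (config$pressure / config$p_ref)^config$v_exp *
      exp(-config$distance / config$decay_length)
    eps <- stats::rnorm(n, 0, config$noise)
    V <- v_mean * (D / median_d)^config$size_vel_corr * (1 + eps)
    V <- pmax(V, 0)

    spray_sample(D_0 = D, V_0 = V,
                 pressure = config$pressure, distance = config$distance,
                 viscosity = config$viscosity,
                 label = sprintf("synthetic seed %d", as.integer(seed)))
  })
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
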