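#' Construct a spray sample
#'
#' A spray sample is a weighted collection of droplet observations
#' (diameter, velocity) together with the spray metadata that produced it.
#'
#' @param D_0 Droplet diameters in m (> 0).
#' @param V_0 Impact velocities in m/s (>= 0), same length.
#' @param weight Non-negative relative frequencies (default all 1).
#' @param pressure Driving air pressure in Pa (metadata, optional).
#' @param distance Nozzle-substrate distance in m (metadata, optional).
#' @param viscosity Liquid viscosity in Pa s (metadata, optional).
#' @param label Free-text label (metadata, optional).
#' @return An object of class `spray_sample` with a data.frame
#'   `observations` (columns `D_0`, `V_0`, `weight`) and a `metadata` list.
#' @examples
#' spray_sample(D_0 = c(30e-6, 45e-6), V_0 = c(10, 6))
#' @export
spray_sample <- function(D_0, V_0, weight = NULL,
                         pressure = NA_real_, distance = NA_real_,
                         viscosity = NA_real_, label = NA_character_) {
  n <- length(D_0)
  if (n == 0) stop("a spray sample must contain at least one droplet",
                   call. = FALSE)
  if (length(V_0) != n) stop("D_0 and V_0 must have equal length",
                             call. = FALSE)
  if (is.null(weight)) weight <- rep(1, n)
  if (length(weight) != n) stop("weight must match the number of droplets",
                                call. = FALSE)
  if (any(!is.finite(D_0)) || any(D_0 <= 0)) {
    stop("all droplet diameters must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(V_0)) || any(V_0 < 0)) {
    stop("all velocities must be non-negative and finite", call. = FALSE)
  }
  if (any(weight < 0) || sum(weight) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  structure(
    list(
      observations = data.frame(D_0 = D_0, V_0 = V_0, weight = weight),
      metadata = list(pressure = pressure, distance = distance,
                      viscosity = viscosity, label = label)
    ),
    class = "spray_sample"
  )
}

#' @export
print.spray_sample <- function(x, ...) {
  obs <- x$observations
  cat(sprintf("Spray sample: %d droplets\n", nrow(obs)))
  cat(sprintf("  diameter: %.1f-%.1f um (mean %.1f)\n",
              min(obs$D_0) * 1e6, max(obs$D_0) * 1e6,
              stats::weighted.mean(obs$D_0, obs$weight) * 1e6))
  cat(sprintf("  velocity: %.2f-%.2f m/s (mean %.2f)\n",
              min(obs$V_0), max(obs$V_0),
              stats::weighted.mean(obs$V_0, obs$weight)))
  md <- x$metadata
  shown <- !vapply(md, function(v) is.na(v[1]), logical(1))
  if (any(shown)) {
    cat("  metadata:",
        paste(names(md)[shown], unlist(md[shown]), sep = " = ",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict the viability distribution of a spray
#'
#' Applies the single-droplet impact model to every observation of a spray
#' sample, bins the resulting survival probabilities (mirroring the
#' relative-incidence histograms used to summarise spray spectra), and
#' averages them into one expected post-spray viability.
#'
#' Droplets smaller than the cell cannot carry a cell. By default
#' (`small_droplets = "exclude"`) they are removed from the average and
#' reported via `excluded_fraction`; with `small_droplets = "bare_cell"` they
#' are treated as bare-cell impacts (D_0 = D_c).
#'
#' @param sample A [spray_sample()].
#' @param cell,fluid,substrate,params,constants Model inputs as in
#'   [predict_impact()].
#' @param bins Number of uniform probability bins on [0, 1] (default 20).
#' @param small_droplets `"exclude"` (default) or `"bare_cell"`.
#' @param clamp Spreading-clamp semantics; see [clamp_spreading()].
#' @param warn Emit one aggregated `cellspray_validity` warning when part of
#'   the spectrum falls outside the spreading-law validity regime?
#' @return An object of class `viability_distribution`: list with
#'   `per_droplet_eta`, `weights`, `bin_edges`, `bin_frequencies` (summing to
#'   1), `mean_eta`, `excluded_fraction`, and the per-droplet `chain`
#'   data.frame of intermediates.
#' @examples
#' s <- spray_sample(D_0 = c(20e-6, 40e-6, 60e-6), V_0 = c(15, 10, 5))
#' d <- predict_ensemble(s)
#' d$mean_eta
#' @export
predict_ensemble <- function(sample,
                             cell = cell_properties(),
                             fluid = fluid_properties(),
                             substrate = substrate_properties(),
                             params = survival_parameters(),
                             constants = model_constants(),
                             bins = 20,
                             small_droplets = c("exclude", "bare_cell"),
                             clamp = c("cushioned", "literal"),
                             warn = TRUE) {
  if (!inherits(sample, "spray_sample")) {
    stop("sample must be a spray_sample object", call. = FALSE)
  }
  small_droplets <- match.arg(small_droplets)
  obs <- sample$observations
  small <- obs$D_0 < cell$diameter
  excluded_fraction <- 0
  if (any(small)) {
    if (small_droplets == "exclude") {
      excluded_fraction <- sum(obs$weight[small]) / sum(obs$weight)
      obs <- obs[!small, , drop = FALSE]
      if (nrow(obs) == 0) {
        stop("every droplet in the sample is smaller than the cell",
             call. = FALSE)
      }
    } else {
      obs$D_0[small] <- cell$diameter
    }
  }

  chain <- impact_chain(obs$D_0, obs$V_0, cell, fluid, substrate,
                        params, constants, clamp = match.arg(clamp))
  n_invalid <- sum(!chain$valid_cell | !chain$valid_drop)
  if (warn && n_invalid > 0) {
    warning(warningCondition(
      sprintf("spreading law outside capillary-regime validity for %d of %d droplets",
              n_invalid, nrow(chain)),
      class = c("cellspray_validity", "warning")
    ))
  }

  eta <- chain$eta
  w <- obs$weight
  mean_eta <- stats::weighted.mean(eta, w)

  edges <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(findInterval(eta, edges, rightmost.closed = TRUE), bins)
  freq <- vapply(seq_len(bins), function(b) sum(w[idx == b]), numeric(1))
  freq <- freq / sum(w)

  structure(
    list(per_droplet_eta = eta, weights = w,
         bin_edges = edges, bin_frequencies = freq,
         mean_eta = mean_eta, excluded_fraction = excluded_fraction,
         chain = chain),
    class = "viability_distribution"
  )
}

#' @export
print.viability_distribution <- function(x, ...) {
  cat(sprintf("Viability distribution over %d droplets\n",
              length(x$per_droplet_eta)))
  cat(sprintf("  expected post-spray viability: %.3f\n", x$mean_eta))
  cat(sprintf("  per-droplet eta range: [%.3f, %.3f]\n",
              min(x$per_droplet_eta), max(x$per_droplet_eta)))
  if (x$excluded_fraction > 0) {
    cat(sprintf("  excluded (droplet smaller than cell): %.1f%% by weight\n",
                100 * x$excluded_fraction))
  }
  invisible(x)
}

#' Viability map over droplet diameter and velocity
#'
#' Evaluates the single-droplet survival probability on a (D_0, V_0) grid,
#' giving the contour maps used to read off which regions of a spray spectrum
#' are lethal. Grid points with D_0 below the cell diameter are `NA` (no
#' cell-carrying droplet exists there).
#'
#' @param D_grid Ascending droplet diameters in m.
#' @param V_grid Ascending impact velocities in m/s.
#' @param cell,fluid,substrate,params,constants,clamp As in
#'   [predict_impact()].
#' @return An object of class `viability_map`: list with `D_grid`, `V_grid`
#'   and the `eta` matrix (rows = diameters, columns = velocities).
#' @examples
#' m <- viability_map(seq(15e-6, 60e-6, length.out = 10), seq(0, 30, 2))
#' range(m$eta)
#' @export
viability_map <- function(D_grid, V_grid,
                          cell = cell_properties(),
                          fluid = fluid_properties(),
                          substrate = substrate_properties(),
                          params = survival_parameters(),
                          constants = model_constants(),
                          clamp = c("cushioned", "literal")) {
  if (is.unsorted(D_grid) || is.unsorted(V_grid)) {
    stop("grids must be sorted ascending", call. = FALSE)
  }
  clamp <- match.arg(clamp)
  eta <- matrix(NA_real_, length(D_grid), length(V_grid),
                dimnames = list(NULL, NULL))
  ok <- D_grid >= cell$diameter
  if (any(ok)) {
    g <- expand.grid(D = D_grid[ok], V = V_grid)
    ch <- impact_chain(g$D, g$V, cell, fluid, substrate, params, constants,
                       clamp = clamp)
    eta[ok, ] <- matrix(ch$eta, sum(ok), length(V_grid))
  }
  structure(list(D_grid = D_grid, V_grid = V_grid, eta = eta),
            class = "viability_map")
}

#' Extract an iso-viability contour from a viability map
#'
#' For each diameter of the map, finds the velocity at which the survival
#' probability crosses `level`. Because eta is non-increasing in velocity the
#' crossing is unique; rows that never cross return `NA`.
#'
#' @param map A [viability_map()] result.
#' @param level Viability level in (0, 1); default 0.5.
#' @return data.frame with columns `D_0` (m) and `V_0` (m/s).
#' @examples
#' m <- viability_map(seq(15e-6, 60e-6, length.out = 10), seq(0, 40, 0.5))
#' head(viability_contour(m))
#' @export
viability_contour <- function(map, level = 0.5) {
  stopifnot(inherits(map, "viability_map"), level > 0, level < 1)
  V_at <- vapply(seq_along(map$D_grid), function(i) {
    eta <- map$eta[i, ]
    if (anyNA(eta) || eta[1] < level || min(eta) > level) return(NA_real_)
    j <- which(eta <= level)[1]
    if (eta[j] == level || j == 1) return(map$V_grid[j])
    # linear interpolation between the bracketing grid points
    v1 <- map$V_grid[j - 1]; v2 <- map$V_grid[j]
    e1 <- eta[j - 1]; e2 <- eta[j]
    v1 + (level - e1) * (v2 - v1) / (e2 - e1)
  }, numeric(1))
  data.frame(D_0 = map$D_grid, V_0 = V_at)
}

#' Sweep one spray parameter and collect mean viabilities
#'
#' Computes the expected post-spray viability as a function of one control
#' parameter: driving pressure, nozzle distance, liquid viscosity, or
#' substrate gelatin fraction. Pressure and distance act through the spray
#' spectrum (a sample per grid point, measured or generated); viscosity and
#' gelatin fraction act through the model only and may reuse one fixed
#' sample, since they do not alter droplet sizes and speeds.
#'
#' @param parameter One of `"pressure"`, `"distance"`, `"viscosity"`,
#'   `"gelatin"`.
#' @param values Grid of parameter values (Pa, m, Pa s, or mass fraction).
#' @param samples Either a single [spray_sample()] (reused for every grid
#'   point; natural for viscosity/gelatin sweeps) or a list of samples, one
#'   per value.
#' @param generator Alternative to `samples`: a function `(value) ->
#'   spray_sample` called per grid point (natural for pressure/distance
#'   sweeps with [generate_spray()]).
#' @param cell,fluid,substrate,params,constants As in [predict_impact()];
#'   `fluid$viscosity` / the substrate stiffness are overridden along
#'   viscosity / gelatin sweeps.
#' @param ... Passed on to [predict_ensemble()].
#' @return data.frame with one row per value: `parameter`, `value`,
#'   `mean_eta`, `n_droplets`, `excluded_fraction`.
#' @examples
#' s <- spray_sample(D_0 = c(20e-6, 40e-6), V_0 = c(12, 8))
#' parameter_sweep("gelatin", c(0, 0.05, 0.2), samples = s)
#' @export
parameter_sweep <- function(parameter = c("pressure", "distance",
                                          "viscosity", "gelatin"),
                            values, samples = NULL, generator = NULL,
                            cell = cell_properties(),
                            fluid = fluid_properties(),
                            substrate = substrate_properties(),
                            params = survival_parameters(),
                            constants = model_constants(), ...) {
  parameter <- match.arg(parameter)
  if (length(values) == 0) stop("values must be non-empty", call. = FALSE)

  get_sample <- function(i, value) {
    if (!is.null(generator)) return(generator(value))
    if (inherits(samples, "spray_sample")) return(samples)
    if (is.list(samples) && length(samples) >= i &&
        inherits(samples[[i]], "spray_sample")) {
      return(samples[[i]])
    }
    stop("no spray sample available for ", parameter, " = ", value,
         call. = FALSE)
  }

  rows <- lapply(seq_along(values), function(i) {
    v <- values[i]
    smp <- get_sample(i, v)
    fl <- fluid
    sb <- substrate
    if (parameter == "viscosity") fl$viscosity <- v
    if (parameter == "gelatin") {
      sb <- substrate_properties(gelatin_fraction = v, constants = constants)
    }
    dist <- predict_ensemble(smp, cell, fl, sb, params, constants, ...)
    data.frame(parameter = parameter, value = v, mean_eta = dist$mean_eta,
               n_droplets = length(dist$per_droplet_eta),
               excluded_fraction = dist$excluded_fraction)
  })
  do.call(rbind, rows)
}
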