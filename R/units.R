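#' Parse quantities with units
#'
#' Small unit helpers for the command-line interface and configuration
#' files. Internally the package is strictly SI; these functions convert
#' common lab notations on ingest. A bare number is taken to be already in
#' SI units.
#'
#' * lengths: `"30um"`, `"0.5mm"`, `"3cm"`, `"0.03m"`
#' * velocities: `"10m/s"`, `"10"`
#' * viscosities: `"1mPas"`, `"1mPa.s"`, `"0.001Pas"`, `"12cP"`
#' * pressures: `"0.4bar"`, `"0.4e5Pa"`, `"40kPa"` (the spray literature
#'   quotes pressures in units of 1e5 Pa, i.e. bar)
#'
#' @param x A single string (or number).
#' @return The value in SI units (m, m/s, Pa s, Pa).
#' @examples
#' parse_length("39um")
#' parse_viscosity("12mPas")
#' parse_pressure("0.4bar")
#' @export
parse_length <- function(x) {
  parse_unit(x, c("um" = 1e-6, "µm" = 1e-6, "mm" = 1e-3,
                  "cm" = 1e-2, "m" = 1))
}

#' @rdname parse_length
#' @export
parse_velocity <- function(x) {
  parse_unit(x, c("m/s" = 1, "mps" = 1))
}

#' @rdname parse_length
#' @export
parse_viscosity <- function(x) {
  parse_unit(x, c("mpas" = 1e-3, "mpa.s" = 1e-3, "mpa·s" = 1e-3,
                  "cp" = 1e-3, "pas" = 1, "pa.s" = 1))
}

#' @rdname parse_length
#' @export
parse_pressure <- function(x) {
  parse_unit(x, c("bar" = 1e5, "kpa" = 1e3, "mpa" = 1e6, "pa" = 1))
}

parse_unit <- function(x, units) {
  if (is.numeric(x)) return(as.numeric(x))
  s <- tolower(trimws(as.character(x)))
  m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*([a-zµ/.·]*)$", s))[[1]]
  if (length(m) != 3 || is.na(suppressWarnings(as.numeric(m[2])))) {
    stop("cannot parse quantity '", x, "'", call. = FALSE)
  }
  value <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") return(value)
  names(units) <- tolower(names(units))
  if (!unit %in% names(units)) {
    stop("unknown unit '", unit, "' in '", x, "'; expected one of: ",
         paste(names(units), collapse = ", "), call. = FALSE)
  }
  value * units[[unit]]
}
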