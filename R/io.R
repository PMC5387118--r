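#' Read a droplet table from CSV
#'
#' Reads a droplet spectrum in the package's CSV dialect: comment lines
#' starting with `#` carry `key: value` metadata (pressure_pa, distance_m,
#' viscosity_pa_s, label), followed by a header line with columns
#' `diameter_um`, `velocity_m_s` and optionally `weight`.
#'
#' @param path Path to the CSV file.
#' @return A [spray_sample()].
#' @examples
#' s <- spray_sample(D_0 = c(30e-6, 50e-6), V_0 = c(10, 5))
#' f <- tempfile(fileext = ".csv")
#' write_droplet_table(s, f)
#' read_droplet_table(f)
#' @export
read_droplet_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty droplet table: ", path, call. = FALSE)
  }
  is_comment <- grepl("^\\s*#", lines)

  meta <- list(pressure = NA_real_, distance = NA_real_,
               viscosity = NA_real_, label = NA_character_)
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- m[2]; val <- trimws(m[3])
      switch(key,
             pressure_pa = meta$pressure <- as.numeric(val),
             distance_m = meta$distance <- as.numeric(val),
             viscosity_pa_s = meta$viscosity <- as.numeric(val),
             label = meta$label <- val)
    }
  }

  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) < 1) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(trimws(lines[body_idx[1]]), ",")[[1]]
  header <- trimws(header)
  needed <- c("diameter_um", "velocity_m_s")
  if (!all(needed %in% header)) {
    stop("droplet table must have columns diameter_um and velocity_m_s ",
         "(header on line ", body_idx[1], " has: ",
         paste(header, collapse = ", "), ")", call. = FALSE)
  }
  data_idx <- body_idx[-1]
  if (length(data_idx) == 0) stop("no data rows in ", path, call. = FALSE)

  parse_row <- function(i) {
    fields <- trimws(strsplit(lines[i], ",")[[1]])
    if (length(fields) != length(header)) {
      stop("line ", i, " of ", path, ": expected ", length(header),
           " fields, found ", length(fields), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop("line ", i, " of ", path, ": non-numeric value '",
           fields[which(is.na(vals))[1]], "'", call. = FALSE)
    }
    vals
  }
  m <- t(vapply(data_idx, parse_row, numeric(length(header))))
  colnames(m) <- header

  spray_sample(
    D_0 = m[, "diameter_um"] * 1e-6,
    V_0 = m[, "velocity_m_s"],
    weight = if ("weight" %in% header) m[, "weight"] else NULL,
    pressure = meta$pressure, distance = meta$distance,
    viscosity = meta$viscosity, label = meta$label
  )
}

#' Write a droplet table to CSV
#'
#' Inverse of [read_droplet_table()]; values are written with full double
#' precision so a write-read round trip is lossless.
#'
#' @param sample A [spray_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_droplet_table <- function(sample, path) {
  stopifnot(inherits(sample, "spray_sample"))
  md <- sample$metadata
  lines <- character(0)
  fmt <- function(x) sprintf("%.17g", x)
  if (!is.na(md$pressure)) lines <- c(lines, paste0("# pressure_pa: ", fmt(md$pressure)))
  if (!is.na(md$distance)) lines <- c(lines, paste0("# distance_m: ", fmt(md$distance)))
  if (!is.na(md$viscosity)) lines <- c(lines, paste0("# viscosity_pa_s: ", fmt(md$viscosity)))
  if (!is.na(md$label)) lines <- c(lines, paste0("# label: ", md$label))
  obs <- sample$observations
  lines <- c(lines, "diameter_um,velocity_m_s,weight",
             sprintf("%.17g,%.17g,%.17g", obs$D_0 * 1e6, obs$V_0, obs$weight))
  writeLines(lines, path)
  invisible(path)
}

#' Read and resolve a run configuration
#'
#' Reads a JSON configuration with optional sections `cell`, `fluid`,
#' `substrate`, `survival`, `constants`, `generator` and `seed`; every field
#' omitted falls back to the package default. Field names follow the
#' constructor arguments ([cell_properties()], [fluid_properties()], ...).
#'
#' @param path Path to a JSON config file, or `NULL` for pure defaults.
#' @param overrides Named list merged on top of the file (deepest wins), used
#'   by the CLI to apply command-line flags.
#' @return A list of resolved model objects: `cell`, `fluid`, `substrate`,
#'   `params`, `constants`, `generator` (a [spray_config()]), `seed`.
#' @examples
#' cfg <- read_run_config(NULL)
#' cfg$cell$diameter
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    list()
  }
  raw <- modify_deep(raw, overrides)

  build <- function(fun, section) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    do.call(fun, as.list(args))
  }
  constants <- build(model_constants, "constants")
  substrate_args <- if (is.null(raw$substrate)) list() else as.list(raw$substrate)
  substrate_args$constants <- constants
  list(
    cell = build(cell_properties, "cell"),
    fluid = build(fluid_properties, "fluid"),
    substrate = do.call(substrate_properties, substrate_args),
    params = build(survival_parameters, "survival"),
    constants = constants,
    generator = build(spray_config, "generator"),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  )
}

#' Serialise a resolved run configuration
#'
#' Writes the resolved configuration next to every CLI output for
#' provenance.
#'
#' @param config A list as returned by [read_run_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

modify_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}
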