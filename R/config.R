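# Flat key-value scenario configuration files.
#
# Schema: one `group.field = value [unit]` per line; `#` starts a comment.
# Groups and fields mirror the constructor arguments in params.R, e.g.
#     tissue.Lp       = 2.10e-11 m/Pa/s     # unit suffix optional
#     particle.radius_a = 100 nm
#     magnet.B_rem    = 1.5 T
# Unknown unit suffixes are rejected; missing fields take package defaults.

.config_groups <- c("tissue", "kinetics", "vascular", "magnet", "particle",
                    "geometry", "bc", "solver")

.group_ctor <- function(group) {
  switch(group,
    tissue = tissue_params, kinetics = kinetic_params,
    vascular = vascular_params, magnet = magnet_spec,
    particle = nanoparticle_spec, geometry = geometry_spec,
    bc = boundary_conditions, solver = solver_settings)
}

# units understood as suffixes in config files (others go through
# normalize_units and error there if unknown)
.parse_config_value <- function(raw, key) {
  raw <- trimws(raw)
  parts <- strsplit(raw, "\\s+")[[1]]
  v <- suppressWarnings(as.numeric(parts[1]))
  if (is.na(v)) {
    stop("config: value for '", key, "' is not numeric: '", raw, "'",
         call. = FALSE)
  }
  if (length(parts) > 1) v <- normalize_units(v, paste(parts[-1], collapse = ""))
  v
}

#' Load a scenario configuration file
#'
#' Reads a flat key-value file (see the package README for the schema),
#' fills every missing field with the package defaults, normalizes all
#' values to SI, and validates every invariant. Validation failures report
#' every violated field at once.
#'
#' @param path path to the configuration file
#' @param overrides optional named character/numeric vector of
#'   `group.field = value` overrides applied after the file (CLI `--param`)
#' @return an [scenario_config()] object
#' @export
load_config <- function(path, overrides = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) {
      stop("config: cannot parse line: '", ln, "'", call. = FALSE)
    }
    kv[[m[2]]] <- m[3]
  }
  if (!is.null(overrides)) {
    ov <- as.list(overrides)
    for (k in names(ov)) kv[[k]] <- as.character(ov[[k]])
  }
  config_from_pairs(kv)
}

config_from_pairs <- function(kv) {
  grouped <- list()
  label <- "scenario"
  has_magnet_keys <- FALSE
  for (key in names(kv)) {
    if (key == "label") { label <- trimws(kv[[key]]); next }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !(parts[1] %in% .config_groups)) {
      stop("config: unknown key '", key, "' (expected group.field with group ",
           "in: ", paste(.config_groups, collapse = ", "), ")", call. = FALSE)
    }
    if (parts[1] == "magnet") has_magnet_keys <- TRUE
    grouped[[parts[1]]][[parts[2]]] <-
      if (parts[2] == "center") {
        as.numeric(strsplit(trimws(kv[[key]]), "[ ,]+")[[1]])
      } else {
        .parse_config_value(kv[[key]], key)
      }
  }
  args <- list(label = label)
  errors <- character()
  for (g in .config_groups) {
    if (g == "magnet" && !has_magnet_keys) next  # no magnet block: conventional
    ctor <- .group_ctor(g)
    fields <- grouped[[g]] %||% list()
    bad <- setdiff(names(fields), names(formals(ctor)))
    if (length(bad)) {
      errors <- c(errors, paste0("unknown field(s) in group '", g, "': ",
                                 paste(bad, collapse = ", ")))
      fields <- fields[setdiff(names(fields), bad)]
    }
    obj <- tryCatch(do.call(ctor, fields), error = function(e) e)
    if (inherits(obj, "error")) {
      errors <- c(errors, paste0(g, ": ", conditionMessage(obj)))
    } else {
      args[[g]] <- obj
    }
  }
  stop_invalid(errors)
  do.call(scenario_config, args)
}

#' Write a scenario configuration file
#'
#' Serializes a scenario to the flat key-value schema in SI units, so that
#' `load_config(write_config(s, f))` reproduces `s` field for field.
#' Used for run provenance snapshots.
#'
#' @param config an [scenario_config()] object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mcdt_scenario"))
  lines <- c(paste("label =", config$label))
  for (g in .config_groups) {
    obj <- config[[g]]
    if (is.null(obj)) next
    ctor_fields <- names(formals(.group_ctor(g)))
    for (f in ctor_fields) {
      val <- obj[[f]]
      if (is.null(val)) next
      lines <- c(lines, sprintf("%s.%s = %s", g, f,
                                paste(format(val, digits = 17), collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Effective diffusion coefficient of a carrier in tumor tissue
#'
#' Size-dependent effective diffusivity
#' `D(a) = D_eff * (a_ref / a) * exp(-(a - a_ref) / L)`,
#' with reference radius `a_ref` = 100 nm: the `1/a` factor is free Stokes-
#' Einstein scaling, and the exponential is the extracellular-matrix hindrance
#' of large carriers relative to the matrix pore size (length scale `L`,
#' see [nanoparticle_spec()]). `D(a_ref) = D_eff` exactly, and `D` is strictly
#' decreasing in `a`.
#'
#' @param particle a [nanoparticle_spec()]
#' @param kinetics a [kinetic_params()] (supplies `D_eff`)
#' @param hindrance_scale hindrance length `L` (m); defaults to the particle's
#' @return effective diffusivity (m^2 s^-1)
#' @export
nanoparticle_diffusivity <- function(particle, kinetics = kinetic_params(),
                                     hindrance_scale = particle$hindrance_scale) {
  a <- particle$radius_a
  if (a <= 0) stop("radius_a must be > 0", call. = FALSE)
  if (hindrance_scale <= 0) stop("hindrance_scale must be > 0", call. = FALSE)
  a_ref <- 100e-9
  kinetics$D_eff * (a_ref / a) * exp(-(a - a_ref) / hindrance_scale)
}

#' Tissue hindrance factor for carrier drift
#'
#' The same exponential hindrance that reduces the carrier's diffusivity
#' (see [nanoparticle_diffusivity()]) reduces its force-driven drift: both are
#' inversely proportional to the tissue drag coefficient
#' `6 pi a eta exp((a - a_ref)/L)`.
#'
#' @param particle a [nanoparticle_spec()]
#' @return dimensionless factor in (0, 1\] for `a >= a_ref`, > 1 for smaller
#'   carriers
#' @export
hindrance_factor <- function(particle) {
  a_ref <- 100e-9
  exp(-(particle$radius_a - a_ref) / particle$hindrance_scale)
}
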