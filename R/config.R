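# Unit-suffixed quantity parsing. Dimensional config entries must carry a
# unit ("1.1 mm", "660 kHz", "60 V"); bare numbers are only accepted for
# dimensionless fields.

unit_table <- c(
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6, "nm" = 1e-9,
  "Hz" = 1, "kHz" = 1e3, "MHz" = 1e6,
  "V" = 1, "kV" = 1e3,
  "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6,
  "Pa.s/m" = 1, "MPa.s/m" = 1e6,
  "kg/m3" = 1, "Pa-1" = 1, "1/Pa" = 1, "m/s" = 1, "Pa.s" = 1,
  "nm/V" = 1e-9, "s" = 1)

#' Parse a unit-suffixed quantity to SI
#'
#' @param text A string like `"1.1 mm"`, `"660 kHz"`, `"17 MPa.s/m"`.
#' @param dimensionless If `TRUE`, a bare number is accepted.
#' @return Numeric value in SI units.
#' @examples
#' parse_quantity("1.1 mm")    # 0.0011
#' parse_quantity("660 kHz")   # 660000
#' @export
parse_quantity <- function(text, dimensionless = FALSE) {
  text <- trimws(text)
  if (text %in% c("Inf", "inf")) return(Inf)
  m <- regmatches(text, regexec(
    "^([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*(\\S*)$", text))[[1]]
  if (length(m) == 0) stop("cannot parse quantity: '", text, "'")
  val <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") {
    if (dimensionless) return(val)
    stop("missing unit on dimensional quantity: '", text, "'")
  }
  if (!unit %in% names(unit_table))
    stop("unknown unit '", unit, "' in '", text, "'")
  val * unit_table[[unit]]
}

#' Read a chamber/transducer/drive/particle configuration file
#'
#' INI-style key/value text with sections `[chamber]`, `[transducer]`,
#' `[drive]`, `[particle]`; `#` starts a comment; every dimensional entry
#' must carry a unit suffix. Unspecified entries fall back to the model A
#' defaults. The `[transducer]` section accepts either `units = model_A` /
#' `model_B` or per-unit entries like `unit_B2 = 1.7 nm/V`.
#'
#' @param path Path to the config file.
#' @return A list with `chamber` (`al_chamber`), `map`
#'   (`al_transducer_map`) and `particle` (`al_particle`).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  kv <- list(chamber = list(), transducer = list(), drive = list(),
             particle = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(kv))
        stop("unknown config section [", section, "]")
      next
    }
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2 || section == "")
      stop("malformed config line: '", ln, "'")
    key <- trimws(parts[1])
    kv[[section]][[key]] <- trimws(paste(parts[-1], collapse = "="))
  }
  g <- function(sec, key, default = NULL, dimensionless = FALSE) {
    v <- kv[[sec]][[key]]
    if (is.null(v)) return(default)
    parse_quantity(v, dimensionless)
  }
  fluid <- make_material(
    kv$chamber$fluid %||% "water",
    g("chamber", "fluid_density", 1000),
    g("chamber", "fluid_sound_speed", 1480))
  chamber <- chamber_config(
    lateral_size = c(g("chamber", "lx", 10e-3), g("chamber", "ly", 10e-3)),
    fluid_height = g("chamber", "height", 1.1e-3),
    fluid = fluid,
    top_impedance = g("chamber", "top_impedance", 13e6),
    side_impedance = g("chamber", "side_impedance", 17e6))
  base <- switch(kv$transducer$units %||% "model_A",
                 model_A = model_a_config()$map,
                 model_B = model_b_config()$map,
                 stop("transducer 'units' must be model_A or model_B"))
  units <- base$units
  for (key in names(kv$transducer)) {
    if (grepl("^unit_[A-Z][0-9]+$", key)) {
      lab <- sub("^unit_", "", key)
      i <- match(substr(lab, 1, 1), LETTERS)
      j <- as.integer(substr(lab, 2, nchar(lab)))
      units[i, j] <- parse_quantity(kv$transducer[[key]])
    }
  }
  map <- transducer_map(
    units = units,
    epoxy = g("transducer", "epoxy", base$epoxy),
    unit_size = g("transducer", "unit_size", base$unit_size),
    pitch = g("transducer", "pitch", base$pitch),
    drive_voltage = g("drive", "voltage", 60),
    frequency = g("drive", "frequency", 660e3))
  particle <- particle_spec(
    radius = g("particle", "radius", 75e-6),
    density = g("particle", "density", 1099),
    compressibility = g("particle", "compressibility", 4.0e-10))
  list(chamber = chamber, map = map, particle = particle)
}
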