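# Stokes-Einstein conversion between viscosity and diffusivity:
# D = kB T / (6 pi eta R). Experimental diffusion coefficients are derived
# from measured viscosities with NMR-based hydrodynamic radii held fixed
# across the alcoholic degree at each temperature.

#' Stokes-Einstein diffusion coefficient
#'
#' @param temperature temperature, K.
#' @param viscosity dynamic viscosity, Pa s.
#' @param radius hydrodynamic radius, Angstrom.
#' @return D in m^2 s^-1.
#' @examples
#' se_diffusion(293, 1.002e-3, 1.03)
#' @export
se_diffusion <- function(temperature, viscosity, radius) {
  if (any(temperature <= 0) || any(viscosity <= 0) || any(radius <= 0))
    stop("temperature, viscosity and radius must be positive")
  .kB * temperature / (6 * pi * viscosity * radius * 1e-10)
}

#' Hydrodynamic radius from a measured diffusion coefficient
#'
#' Algebraic inverse of [se_diffusion()]; this is how NMR-based radii are
#' obtained from measured diffusivities and viscosities.
#'
#' @param temperature temperature, K.
#' @param viscosity dynamic viscosity, Pa s.
#' @param diffusion diffusion coefficient, m^2 s^-1.
#' @return radius in Angstrom.
#' @export
se_radius <- function(temperature, viscosity, diffusion) {
  if (any(temperature <= 0) || any(viscosity <= 0) || any(diffusion <= 0))
    stop("temperature, viscosity and diffusion must be positive")
  .kB * temperature / (6 * pi * viscosity * diffusion) / 1e-10
}

#' Hydrodynamic radii table
#'
#' The default `"nmr"` source returns the reference radii derived from
#' 13C NMR diffusivities at 277/285/293 K: CO2 0.95/1.03/1.03 A and
#' EtOH 1.81/1.85/1.80 A. The `"rms"` and `"gyration"` sources return the
#' structural radii of the built-in geometries, constant in temperature —
#' the alternates used to probe the sensitivity of experimental
#' diffusivities to the radius definition.
#'
#' @param source `"nmr"`, `"rms"` or `"gyration"`.
#' @return data.frame with columns species, temperature_K, radius_A.
#' @export
hydrodynamic_radii <- function(source = c("nmr", "rms", "gyration")) {
  source <- match.arg(source)
  temps <- c(277, 285, 293)
  if (source == "nmr") {
    return(data.frame(
      species = rep(c("CO2", "EtOH"), each = 3),
      temperature_K = rep(temps, 2),
      radius_A = c(0.95, 1.03, 1.03, 1.81, 1.85, 1.80)))
  }
  f <- if (source == "rms") rms_radius else gyration_radius
  data.frame(
    species = rep(c("CO2", "EtOH"), each = 3),
    temperature_K = rep(temps, 2),
    radius_A = rep(c(f(co2_geometry("epm2")), f(ethanol_geometry())),
                   each = 3))
}

#' Read a viscosity table from delimited text
#'
#' Expected header: `temperature_K`, `pct_vol` and either `viscosity_mPas`
#' or `viscosity_Pas`. Values are converted to SI (Pa s) internally.
#'
#' @param path file path (tab- or whitespace-delimited, `#` comments).
#' @param unit unit of a bare `viscosity` column, if present.
#' @return data.frame with temperature_K, pct_vol, viscosity_Pas.
#' @export
read_viscosity_table <- function(path, unit = c("mPas", "Pas")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, comment.char = "#")
  if (!is.null(df$viscosity_mPas)) {
    df$viscosity_Pas <- df$viscosity_mPas * 1e-3
  } else if (is.null(df$viscosity_Pas) && !is.null(df$viscosity)) {
    df$viscosity_Pas <- df$viscosity * if (unit == "mPas") 1e-3 else 1
  }
  if (is.null(df$viscosity_Pas) || is.null(df$temperature_K) ||
      is.null(df$pct_vol))
    stop("viscosity table needs temperature_K, pct_vol and a viscosity column")
  if (any(df$viscosity_Pas <= 0) || any(df$temperature_K <= 0))
    stop("viscosities and temperatures must be positive")
  df[c("temperature_K", "pct_vol", "viscosity_Pas")]
}

#' Bundled synthetic viscosity table
#'
#' A plausible, clearly non-authoritative stand-in for measured
#' water-ethanol viscosities: anchored at pure-water values and monotone
#' increasing in the alcoholic degree, decreasing in temperature. Shipped
#' because the measured values behind the published figures are not
#' printed numerically.
#'
#' @return data.frame with temperature_K, pct_vol, viscosity_Pas.
#' @export
synthetic_viscosity_table <- function() {
  read_viscosity_table(system.file("extdata", "viscosity_synthetic.tsv",
                                   package = "fizzdiff", mustWork = TRUE))
}

#' Experimental diffusion coefficients from viscosities
#'
#' Applies the Stokes-Einstein relation to each viscosity record, looking
#' the hydrodynamic radius up by (species, temperature) in the radii
#' table. The radius is held fixed across the alcoholic degree at each
#' temperature; radii at unlisted temperatures are an error (no
#' interpolation — radius tables are sparse and extrapolation would be
#' silent guessing).
#'
#' @param viscosities data.frame with temperature_K, pct_vol,
#'   viscosity_Pas (see [read_viscosity_table()]).
#' @param radii radii table as from [hydrodynamic_radii()].
#' @param species species name to look up (e.g. `"CO2"`).
#' @return data.frame with pct_vol, temperature_K, species, D_m2s, ordered
#'   by temperature then pct_vol.
#' @export
experimental_diffusion_table <- function(viscosities,
                                         radii = hydrodynamic_radii("nmr"),
                                         species) {
  rad <- radii[radii$species == species, ]
  key <- match(viscosities$temperature_K, rad$temperature_K)
  if (anyNA(key)) {
    missing <- unique(viscosities$temperature_K[is.na(key)])
    stop("no ", species, " radius for temperature(s): ",
         paste(missing, collapse = ", "), " K")
  }
  out <- data.frame(
    pct_vol = viscosities$pct_vol,
    temperature_K = viscosities$temperature_K,
    species = species,
    D_m2s = se_diffusion(viscosities$temperature_K,
                         viscosities$viscosity_Pas,
                         rad$radius_A[key]))
  out[order(out$temperature_K, out$pct_vol), , drop = FALSE]
}

#' Write a diffusion table as TSV
#' @param table data.frame from [experimental_diffusion_table()].
#' @param path output file.
#' @export
write_diffusion_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
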