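# Diffusion-limited growth of small CO2 bubbles rising in-line in a
# supersaturated liquid: the radius grows linearly with a rate
#   k = dr/dt = 0.63 (R T / P) D^(2/3) (2 rho g / (9 eta))^(1/3) (cL - c0),
# where cL is the bulk dissolved-CO2 concentration and c0 the interfacial
# concentration in Henry equilibrium with the gas in the bubble.

#' Bubble growth parameters
#'
#' @param temperature liquid temperature, K.
#' @param diffusion bulk CO2 diffusion coefficient, m^2 s^-1.
#' @param viscosity liquid dynamic viscosity, Pa s.
#' @param liquid_density liquid density, kg m^-3.
#' @param c_bulk bulk dissolved-CO2 concentration cL, mol m^-3.
#' @param c_interface interfacial concentration c0 (Henry equilibrium),
#'   mol m^-3.
#' @param pressure CO2 partial pressure in the bubble, Pa (~1e5).
#' @param gas_constant ideal gas constant, J K^-1 mol^-1.
#' @param gravity gravitational acceleration, m s^-2.
#' @return object of class `bubble_params`.
#' @export
bubble_params <- function(temperature, diffusion, viscosity,
                          liquid_density, c_bulk, c_interface,
                          pressure = 1e5, gas_constant = 8.314,
                          gravity = 9.8) {
  p <- structure(list(gas_constant = gas_constant, temperature = temperature,
                      pressure = pressure, diffusion = diffusion,
                      liquid_density = liquid_density, gravity = gravity,
                      viscosity = viscosity, c_bulk = c_bulk,
                      c_interface = c_interface),
                 class = "bubble_params")
  pos <- c("gas_constant", "temperature", "pressure", "diffusion",
           "liquid_density", "gravity", "viscosity", "c_bulk",
           "c_interface")
  bad <- pos[vapply(p[pos], function(v) !is.finite(v) || v <= 0, TRUE)]
  if (length(bad))
    stop("bubble parameters must be positive: ", paste(bad, collapse = ", "))
  p
}

#' Bubble growth rate
#'
#' Evaluates the diffusion-limited growth rate k (m s^-1); negative when
#' the liquid is undersaturated (cL < c0). Note the scalings: k ~ D^(2/3)
#' and k ~ eta^(-1/3).
#'
#' @param params a [bubble_params()].
#' @return k in m s^-1.
#' @examples
#' p <- bubble_params(293, 2e-9, 1e-3, 998, c_bulk = 20, c_interface = 10)
#' growth_rate(p)
#' @export
growth_rate <- function(params) {
  with(params,
       0.63 * (gas_constant * temperature / pressure) * diffusion^(2 / 3) *
         (2 * liquid_density * gravity / (9 * viscosity))^(1 / 3) *
         (c_bulk - c_interface))
}

#' Bubble radius as a function of time
#'
#' Constant-parameter integration of dr/dt = k: `r(t) = r0 + k t`. For a
#' shrinking bubble (k < 0) the curve is truncated where the radius
#' reaches zero: later entries are NA and the result carries a
#' `"truncated"` attribute.
#'
#' @param r0 initial radius, m (> 0).
#' @param params a [bubble_params()].
#' @param times increasing time points, s.
#' @return numeric vector of radii, m.
#' @export
radius_vs_time <- function(r0, params, times) {
  if (r0 <= 0) stop("r0 must be positive")
  if (is.unsorted(times, strictly = FALSE)) stop("times must be increasing")
  r <- r0 + growth_rate(params) * times
  truncated <- FALSE
  if (any(r <= 0)) {
    r[r <= 0] <- NA_real_
    truncated <- TRUE
  }
  structure(r, truncated = truncated)
}

#' Interfacial concentration from Henry's law
#'
#' c0 = kH * P: the dissolved-gas concentration in equilibrium with the
#' gas phase at partial pressure P. The Henry constant is user input.
#'
#' @param henry_constant Henry solubility constant, mol m^-3 Pa^-1.
#' @param pressure CO2 partial pressure, Pa.
#' @return concentration in mol m^-3.
#' @export
henry_interface_concentration <- function(henry_constant, pressure) {
  if (henry_constant <= 0 || pressure <= 0)
    stop("henry_constant and pressure must be positive")
  henry_constant * pressure
}

#' Write a bubble growth curve as TSV (t_s, r_m)
#' @param times time points, s.
#' @param radii radii from [radius_vs_time()].
#' @param path output file.
#' @export
write_growth_curve <- function(times, radii, path) {
  utils::write.table(data.frame(t_s = times, r_m = as.numeric(radii)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
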