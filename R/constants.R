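# Physical constants (2019 SI exact values where defined) and default
# molecular parameters used across the package. All lengths in the public
# interface are nm (trajectories, boxes, H-bond cutoffs) or Angstrom
# (molecular radii); diffusivities are reported in m^2 s^-1.

.kB <- 1.380649e-23        # Boltzmann constant, J K^-1
.avogadro <- 6.02214076e23 # mol^-1
.xi_pbc <- 2.837297        # cubic-lattice self-interaction constant of the
                           # periodic-boundary finite-size correction

# conversion: 1 nm^2 ps^-1 = 1e-6 m^2 s^-1
.nm2ps_to_m2s <- 1e-6

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06)

.default_molar_masses <- c(water = 18.015, ethanol = 46.068, co2 = 44.009)

#' Atomic masses for element symbols
#'
#' Standard atomic weights used to resolve masses when reading XYZ
#' geometries. Unknown elements raise an error.
#'
#' @param elements character vector of element symbols (e.g. `"C"`, `"O"`).
#' @return numeric vector of masses in amu.
#' @examples
#' element_mass(c("C", "O", "O"))
#' @export
element_mass <- function(elements) {
  m <- .element_masses[elements]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
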