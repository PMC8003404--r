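# Mixture composition: from the alcoholic degree (% ethanol by volume) to
# molecule counts and the edge length of the cubic simulation box.

#' Number of ethanol molecules for a given alcoholic degree
#'
#' Computes the number of ethanol molecules N that realises a target ethanol
#' volume fraction in a box with a fixed number of water molecules:
#' \deqn{N = \frac{N_{H_2O}\,\rho_{EtOH}\,M_{H_2O}}{\rho_{H_2O}\,(r-1)\,M_{EtOH}},
#' \qquad r = 100/\mathrm{pct\_vol},}
#' where \eqn{r} is the ratio of the total mixture volume to the volume
#' occupied by ethanol. The result is rounded half away from zero; at the
#' default densities (285 K reference) and 40000 waters this yields
#' 0, 385, 795, 1232, 1699, 2199 for 0–15 %vol in steps of 3.
#'
#' @param pct_vol ethanol percent by volume, in `[0, 100)`.
#' @param n_water number of water molecules (> 0).
#' @param rho_water,rho_ethanol liquid densities, kg m^-3 (defaults: 285 K).
#' @param molar_mass_water,molar_mass_ethanol molar masses, g mol^-1.
#' @return integer count of ethanol molecules; exactly 0 for `pct_vol = 0`.
#' @examples
#' ethanol_count(12)  # 1699
#' @export
ethanol_count <- function(pct_vol, n_water = 40000,
                          rho_water = 999.49, rho_ethanol = 796.06,
                          molar_mass_water = 18.015,
                          molar_mass_ethanol = 46.068) {
  stopifnot(length(pct_vol) == 1)
  if (!is.finite(pct_vol) || pct_vol < 0 || pct_vol >= 100)
    stop("pct_vol must lie in [0, 100)")
  if (n_water <= 0 || rho_water <= 0 || rho_ethanol <= 0 ||
      molar_mass_water <= 0 || molar_mass_ethanol <= 0)
    stop("counts, densities and molar masses must be positive")
  if (pct_vol == 0) return(0L)
  r <- 100 / pct_vol
  n <- n_water * rho_ethanol * molar_mass_water /
    (rho_water * (r - 1) * molar_mass_ethanol)
  # round half away from zero (base round() is round-half-even and would
  # miss the x.5 boundary cases)
  as.integer(floor(n + 0.5))
}

#' Mixture specification for a carbonated water-ethanol box
#'
#' A recipe for one simulation box: the alcoholic degree, temperature,
#' molecule counts and the reference densities/molar masses used to derive
#' the ethanol count and the box size. If `n_ethanol` is not supplied it is
#' computed with [ethanol_count()].
#'
#' @param pct_vol ethanol percent by volume in `[0, 100)`.
#' @param temperature temperature, K.
#' @param n_water,n_co2 molecule counts.
#' @param rho_water,rho_ethanol densities, kg m^-3.
#' @param molar_mass_water,molar_mass_ethanol molar masses, g mol^-1.
#' @param n_ethanol optional explicit ethanol count; must be 0 exactly when
#'   `pct_vol` is 0.
#' @return an object of class `mixture_spec`.
#' @examples
#' mixture_spec(3)
#' @export
mixture_spec <- function(pct_vol, temperature = 285, n_water = 40000,
                         n_co2 = 200, rho_water = 999.49,
                         rho_ethanol = 796.06, molar_mass_water = 18.015,
                         molar_mass_ethanol = 46.068, n_ethanol = NULL) {
  if (is.null(n_ethanol)) {
    n_ethanol <- ethanol_count(pct_vol, n_water, rho_water, rho_ethanol,
                               molar_mass_water, molar_mass_ethanol)
  }
  spec <- structure(
    list(pct_vol = pct_vol, temperature = temperature,
         n_water = as.integer(n_water), n_co2 = as.integer(n_co2),
         n_ethanol = as.integer(n_ethanol),
         rho_water = rho_water, rho_ethanol = rho_ethanol,
         molar_mass_water = molar_mass_water,
         molar_mass_ethanol = molar_mass_ethanol),
    class = "mixture_spec")
  validate_mixture_spec(spec)
  spec
}

validate_mixture_spec <- function(spec) {
  with(spec, {
    if (pct_vol < 0 || pct_vol >= 100) stop("pct_vol must lie in [0, 100)")
    if (temperature <= 0) stop("temperature must be positive")
    if (n_water < 0 || n_co2 < 0 || n_ethanol < 0)
      stop("molecule counts must be non-negative")
    if (rho_water <= 0 || rho_ethanol <= 0) stop("densities must be positive")
    if ((pct_vol == 0) != (n_ethanol == 0))
      stop("n_ethanol must be 0 exactly when pct_vol is 0")
  })
  invisible(spec)
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("Mixture: %.3g %%vol ethanol at %g K\n", x$pct_vol,
              x$temperature))
  cat(sprintf("  %d H2O + %d CO2 + %d EtOH\n", x$n_water, x$n_co2,
              x$n_ethanol))
  invisible(x)
}

#' Estimate the cubic box side length of a mixture
#'
#' Converts molecule counts into an estimated box volume and returns its
#' cube root. `water_density_only` divides the total water + CO2 mass by the
#' water density; `ideal_volume_mixing` additionally adds the ethanol
#' partial volume from the ethanol density (ideal, non-excess mixing). For
#' the reference compositions this spans ~10.6 nm at 0 %vol to ~11.2 nm at
#' 15 %vol.
#'
#' @param spec a [mixture_spec()].
#' @param mixing volume model; see Details.
#' @param molar_mass_co2 CO2 molar mass, g mol^-1.
#' @return box side length in nm.
#' @examples
#' box_side_estimate(mixture_spec(0), "water_density_only")
#' @export
box_side_estimate <- function(spec,
                              mixing = c("ideal_volume_mixing",
                                         "water_density_only"),
                              molar_mass_co2 = 44.009) {
  mixing <- match.arg(mixing)
  validate_mixture_spec(spec)
  if (spec$rho_water <= 0 || spec$rho_ethanol <= 0)
    stop("densities must be positive")
  # mass in kg: n * M [g/mol] / N_A / 1000
  m_wc <- (spec$n_water * spec$molar_mass_water +
             spec$n_co2 * molar_mass_co2) / .avogadro / 1000
  vol <- m_wc / spec$rho_water # m^3
  if (mixing == "ideal_volume_mixing" && spec$n_ethanol > 0) {
    m_eth <- spec$n_ethanol * spec$molar_mass_ethanol / .avogadro / 1000
    vol <- vol + m_eth / spec$rho_ethanol
  }
  (vol * 1e27)^(1 / 3) # nm
}

#' Composition report over a grid of alcoholic degrees
#'
#' @param pct_vol_levels numeric vector of %vol levels.
#' @param temperature temperature, K (box sizing uses the spec densities).
#' @param ... passed to [mixture_spec()].
#' @return data.frame with columns pct_vol, temperature_K, n_water, n_co2,
#'   n_ethanol, box_nm.
#' @export
composition_report <- function(pct_vol_levels = seq(0, 15, by = 3),
                               temperature = 285, ...) {
  rows <- lapply(pct_vol_levels, function(pv) {
    spec <- mixture_spec(pv, temperature = temperature, ...)
    data.frame(pct_vol = pv, temperature_K = temperature,
               n_water = spec$n_water, n_co2 = spec$n_co2,
               n_ethanol = spec$n_ethanol,
               box_nm = box_side_estimate(spec))
  })
  do.call(rbind, rows)
}

#' Write a composition report as TSV
#'
#' @param report data.frame from [composition_report()].
#' @param path output file.
#' @export
write_composition_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a geometric box structure for a mixture
#'
#' Places whole molecules (water, CO2, ethanol) at random positions and
#' orientations inside the cubic box estimated from the spec, enforcing a
#' minimum centre-of-mass separation under the minimum-image convention via
#' a cell grid. This is fixture plumbing: no energetics, minimisation or
#' topology — the output is only guaranteed to be geometrically sane.
#'
#' @param spec a [mixture_spec()].
#' @param geometries named list of [mol_geometry()] objects for `water`,
#'   `co2` and `ethanol`.
#' @param seed integer seed; the same seed reproduces the same structure.
#' @param min_dist minimum centre-of-mass separation, nm.
#' @param max_attempts placement attempts per molecule before giving up.
#' @return an object of class `box_structure` with an `atoms` data.frame
#'   (mol_id, resname, atom, element, x, y, z in nm) and `box_side`.
#' @export
build_box_structure <- function(spec, geometries = default_geometries(),
                                seed = 1L, min_dist = 0.25,
                                max_attempts = 200L) {
  validate_mixture_spec(spec)
  stopifnot(min_dist > 0)
  L <- box_side_estimate(spec)
  set.seed(as.integer(seed))

  resnames <- c(rep("SOL", spec$n_water), rep("CO2", spec$n_co2),
                rep("ETH", spec$n_ethanol))
  geom_of <- c(SOL = "water", CO2 = "co2", ETH = "ethanol")
  n_mol <- length(resnames)
  if (n_mol == 0) stop("empty mixture")

  # cell grid for neighbour lookups; cell width >= min_dist
  ncell <- max(1L, floor(L / min_dist))
  cell_w <- L / ncell
  cells <- new.env(hash = TRUE, parent = emptyenv())
  com <- matrix(NA_real_, n_mol, 3)
  cell_key <- function(ix) paste(ix, collapse = ",")
  neighbour_idx <- function(ix) {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    t((t(offs) + ix) %% ncell)
  }

  for (i in seq_len(n_mol)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- stats::runif(3, 0, L)
      ix <- pmin(floor(p / cell_w), ncell - 1)
      ok <- TRUE
      for (k in seq_len(27)) {
        key <- cell_key(neighbour_idx(ix)[k, ])
        others <- cells[[key]]
        if (!is.null(others)) {
          d <- sweep(com[others, , drop = FALSE], 2, p)
          d <- d - L * round(d / L)
          if (any(rowSums(d^2) < min_dist^2)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        com[i, ] <- p
        key <- cell_key(ix)
        cells[[key]] <- c(cells[[key]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement failure: could not insert molecule ", i, " after ",
           max_attempts, " attempts (box too crowded for min_dist)")
  }

  # expand molecules to atoms: centred geometry offsets (A -> nm), random
  # rotation, wrapped into [0, L)
  atom_rows <- vector("list", n_mol)
  for (i in seq_len(n_mol)) {
    g <- geometries[[geom_of[resnames[i]]]]
    offs <- sweep(g$xyz, 2, center_of_mass(g)) / 10
    rot <- random_rotation()
    pos <- sweep(offs %*% t(rot), 2, com[i, ], "+") %% L
    atom_rows[[i]] <- data.frame(
      mol_id = i, resname = resnames[i],
      atom = paste0(g$elements, seq_along(g$elements)),
      element = g$elements,
      x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }
  structure(list(atoms = do.call(rbind, atom_rows), com = com,
                 box_side = L, spec = spec, seed = as.integer(seed)),
            class = "box_structure")
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

#' @export
print.box_structure <- function(x, ...) {
  cat(sprintf("Box structure: %d molecules / %d atoms, L = %.3f nm\n",
              max(x$atoms$mol_id), nrow(x$atoms), x$box_side))
  invisible(x)
}

#' Number of molecules in a box structure
#' @param structure a `box_structure`.
#' @return integer count.
#' @export
n_molecules <- function(structure) max(structure$atoms$mol_id)
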