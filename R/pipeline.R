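# End-to-end orchestration: compose a mixture grid, synthesise trajectories,
# estimate finite-size-corrected diffusion coefficients, derive experimental
# Stokes-Einstein values from the viscosity table, and juxtapose the two in
# a comparison report (one row per species x temperature x alcoholic
# degree).

#' Pipeline run configuration
#'
#' All randomness flows from the single top-level `seed`: run i of the grid
#' uses `seed + i` for its trajectory (documented derivation, kept below
#' 2^31). Ground-truth diffusion coefficients for the synthetic
#' trajectories either close the loop on the Stokes-Einstein experimental
#' values (`d_true = "stokes_einstein"`, the default — theory and
#' experiment columns then agree up to fit noise) or are fixed per species
#' via a named list.
#'
#' @param temperatures temperatures, K.
#' @param pct_vol_levels alcoholic degrees, %vol.
#' @param species named list; each entry a list with `n_particles` and
#'   optionally `d_true` (m^2 s^-1) overriding the global scheme.
#' @param seed top-level integer seed.
#' @param n_frames,dt trajectory length (frames) and spacing (ps).
#' @param d_true `"stokes_einstein"` or a named list of per-species values.
#' @param radius_source radius used for the finite-size correction and the
#'   experimental values: `"nmr"`, `"rms"` or `"gyration"`.
#' @param viscosities viscosity data.frame (default: the bundled synthetic
#'   table).
#' @param fit_window,origin_stride,n_blocks analysis knobs; see
#'   [estimate_diffusion()].
#' @return object of class `run_config`.
#' @export
run_config <- function(temperatures = c(277, 285, 293),
                       pct_vol_levels = seq(0, 15, by = 3),
                       species = list(CO2 = list(n_particles = 200),
                                      EtOH = list(n_particles = 200)),
                       seed = 1L, n_frames = 2000L, dt = 1,
                       d_true = "stokes_einstein",
                       radius_source = c("nmr", "rms", "gyration"),
                       viscosities = synthetic_viscosity_table(),
                       fit_window = NULL, origin_stride = 1L,
                       n_blocks = NULL) {
  radius_source <- match.arg(radius_source)
  if (is.null(names(species)) || any(!nzchar(names(species))))
    stop("species must be a named list")
  radii <- hydrodynamic_radii(radius_source)
  for (sp in names(species)) {
    if (!sp %in% radii$species)
      stop("no ", radius_source, " radius available for species ", sp)
    if (is.null(species[[sp]]$n_particles))
      stop("species ", sp, " needs n_particles")
  }
  structure(list(temperatures = temperatures,
                 pct_vol_levels = pct_vol_levels, species = species,
                 seed = as.integer(seed), n_frames = as.integer(n_frames),
                 dt = dt, d_true = d_true, radius_source = radius_source,
                 viscosities = viscosities, fit_window = fit_window,
                 origin_stride = as.integer(origin_stride),
                 n_blocks = n_blocks),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the [run_config()] arguments; a
#' `viscosity_table` key may point to a delimited file readable by
#' [read_viscosity_table()].
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("temperatures", "pct_vol_levels", "seed", "n_frames", "dt",
              "d_true", "radius_source", "fit_window", "origin_stride",
              "n_blocks", "species"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$viscosity_table))
    args$viscosities <- read_viscosity_table(y$viscosity_table)
  if (!is.null(args$temperatures)) args$temperatures <-
    as.numeric(args$temperatures)
  if (!is.null(args$pct_vol_levels)) args$pct_vol_levels <-
    as.numeric(args$pct_vol_levels)
  do.call(run_config, args)
}

#' Run the full compare pipeline over a mixture grid
#'
#' For every (species, temperature, %vol) grid point: estimates the box
#' side from the composition, generates a Brownian trajectory at the
#' configured ground-truth D, runs the MSD pipeline with the finite-size
#' correction, and computes the experimental Stokes-Einstein value from
#' the viscosity table. Rows are ordered by species, then temperature,
#' then %vol. With `outdir` set, the report (TSV), a JSON summary carrying
#' the seed and all knobs in effect, and per-run MSD curves are persisted;
#' identical config + seed reproduce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @param verbose print one line per grid point.
#' @return `comparison_report` data.frame with columns species,
#'   temperature_K, pct_vol, d_theory, d_theory_corrected, d_experiment,
#'   uncertainty (all diffusivities in m^2 s^-1).
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  radii <- hydrodynamic_radii(config$radius_source)
  nmr <- hydrodynamic_radii("nmr")
  grid <- expand.grid(pct_vol = sort(config$pct_vol_levels),
                      temperature_K = sort(config$temperatures),
                      species = sort(names(config$species)),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$species, grid$temperature_K, grid$pct_vol), ]
  rows <- vector("list", nrow(grid))
  curves <- vector("list", nrow(grid))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  for (i in seq_len(nrow(grid))) {
    sp <- grid$species[i]; tK <- grid$temperature_K[i]
    pv <- grid$pct_vol[i]
    eta <- config$viscosities$viscosity_Pas[
      config$viscosities$temperature_K == tK &
        config$viscosities$pct_vol == pv]
    if (length(eta) != 1)
      stop("pipeline stage 'viscosity lookup' failed at (", sp, ", ", tK,
           " K, ", pv, " %vol)")
    r_corr <- radii$radius_A[radii$species == sp &
                               radii$temperature_K == tK]
    r_exp <- nmr$radius_A[nmr$species == sp & nmr$temperature_K == tK]
    if (length(r_corr) != 1 || length(r_exp) != 1)
      stop("pipeline stage 'radius lookup' failed at (", sp, ", ", tK,
           " K, ", pv, " %vol)")
    d_exp <- se_diffusion(tK, eta, r_exp)
    d_true <- config$species[[sp]]$d_true %||%
      (if (identical(config$d_true, "stokes_einstein")) d_exp
       else config$d_true[[sp]] %||%
         stop("no d_true for species ", sp))
    L <- box_side_estimate(mixture_spec(pv, temperature = tK))
    traj <- brownian_trajectory(config$species[[sp]]$n_particles, d_true,
                                box_side = L, dt = config$dt,
                                n_frames = config$n_frames,
                                seed = config$seed + i, species = sp)
    est <- estimate_diffusion(traj, radius = r_corr,
                              fit_window = config$fit_window,
                              origin_stride = config$origin_stride,
                              n_blocks = config$n_blocks)
    rows[[i]] <- data.frame(species = sp, temperature_K = tK, pct_vol = pv,
                            d_theory = est$d_pbc,
                            d_theory_corrected = est$d_corrected,
                            d_experiment = d_exp,
                            uncertainty = est$uncertainty)
    curves[[i]] <- est$curve
    if (verbose)
      message(sprintf("[%s %g K %g%%vol] D_PBC=%.3g D0=%.3g D_exp=%.3g",
                      sp, tK, pv, est$d_pbc, est$d_corrected, d_exp))
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  class(report) <- c("comparison_report", "data.frame")
  if (!is.null(outdir)) {
    write_comparison_report(report, file.path(outdir, "report.tsv"))
    for (i in seq_len(nrow(grid)))
      write_msd_tsv(curves[[i]], file.path(outdir,
        sprintf("msd_%s_%gK_%gpct.tsv", grid$species[i],
                grid$temperature_K[i], grid$pct_vol[i])))
    jsonlite::write_json(
      list(seed = config$seed, n_frames = config$n_frames, dt = config$dt,
           radius_source = config$radius_source,
           d_true = if (is.character(config$d_true)) config$d_true
                    else as.list(config$d_true),
           origin_stride = config$origin_stride,
           config_hash = config_hash(config)),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  report
}

#' Write a comparison report as TSV
#' @param report a `comparison_report`.
#' @param path output file.
#' @export
write_comparison_report <- function(report, path) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.10e", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 32-bit FNV-1a hash of the deparsed config, for output provenance
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor only touches the low byte (b < 256); keep h a double mod 2^32
    low <- bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- h - (h %% 256) + low
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}
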