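# Diffusion estimation from mean-squared displacements. The MSD is
# averaged over particles and all admissible time origins; in the Fickian
# regime MSD(t) = 6 D t at long times, so D is the fitted slope / 6.
# Periodic-boundary estimates are then corrected for system-size
# dependence: D0 = D_PBC + xi kB T / (6 pi eta L), or equivalently (via the
# Stokes-Einstein substitution for eta) D0 ~= D_PBC (1 - xi R / L)^-1 with
# xi = 2.837297.

#' Multi-origin mean-squared displacement of a trajectory
#'
#' For each lag tau (in frames up to `max_lag`), averages
#' `|r(t0 + tau) - r(t0)|^2` over all particles and every admissible
#' origin t0 taken each `origin_stride` frames. The `"fft"` method computes
#' all-origin averages in O(N log N) per particle via the autocorrelation
#' identity; `"direct"` evaluates the sums explicitly and supports origin
#' strides > 1. Both give the same values (the O(N^2) double loop is the
#' test oracle).
#'
#' @param traj an unwrapped [trajectory()] (unwrap first; see
#'   [unwrap_trajectory()]).
#' @param max_lag largest lag, ps; defaults to half the trajectory
#'   duration.
#' @param origin_stride take a time origin every this many frames
#'   (1 = every stored frame).
#' @param method `"auto"`, `"fft"` or `"direct"`.
#' @return object of class `msd_curve` with fields `lags` (ps, starting at
#'   0), `msd` (nm^2), `n_origins`, `n_particles`.
#' @export
msd <- function(traj, max_lag = NULL, origin_stride = 1L,
                method = c("auto", "fft", "direct")) {
  method <- match.arg(method)
  if (traj$wrapped)
    stop("trajectory is wrapped: unwrap before computing the MSD")
  dt <- traj$times[2] - traj$times[1]
  duration <- traj$times[length(traj$times)] - traj$times[1]
  if (is.null(max_lag)) max_lag <- duration / 2
  if (max_lag > duration) stop("max_lag exceeds the trajectory duration")
  if (origin_stride < 1) stop("origin_stride must be >= 1")
  K <- floor(max_lag / dt + 1e-9)
  if (K < 1) stop("max_lag shorter than one frame")
  N <- n_frames(traj); P <- n_particles(traj)
  X <- matrix(traj$positions, N, P * 3)

  if (method == "auto")
    method <- if (origin_stride == 1L && as.double(N) * K > 2e6) "fft"
              else "direct"
  if (method == "fft" && origin_stride != 1L)
    stop("the fft method requires origin_stride = 1")

  vals <- if (method == "fft") msd_fft(X, K, P) else
    msd_direct(X, K, P, origin_stride)
  structure(list(lags = (0:K) * dt, msd = vals,
                 n_origins = length(seq(1L, N, by = origin_stride)),
                 n_particles = P),
            class = "msd_curve")
}

# all-origin MSD via cumulative sums + FFT autocorrelation
msd_fft <- function(X, K, P) {
  N <- nrow(X); C <- ncol(X)
  sq <- X^2
  csum <- apply(sq, 2, cumsum)
  Q <- csum[N, ]
  S1 <- matrix(0, K + 1, C)
  for (tau in 0:K) {
    below <- if (tau == 0) rep(0, C) else csum[tau, ]
    S1[tau + 1, ] <- csum[N - tau, ] + (Q - below)
  }
  M <- 2^ceiling(log2(2 * N))
  Ccorr <- matrix(0, K + 1, C)
  chunks <- split(seq_len(C), ceiling(seq_len(C) / 128))
  for (ii in chunks) {
    Xp <- rbind(X[, ii, drop = FALSE], matrix(0, M - N, length(ii)))
    F <- stats::mvfft(Xp)
    ac <- Re(stats::mvfft(F * Conj(F), inverse = TRUE)) / M
    Ccorr[, ii] <- ac[1:(K + 1), , drop = FALSE]
  }
  (rowSums(S1) - 2 * rowSums(Ccorr)) / ((N - 0:K) * P)
}

# strided-origin MSD, vectorised over origins and particles per lag
msd_direct <- function(X, K, P, stride) {
  N <- nrow(X)
  vals <- numeric(K + 1)
  for (tau in 0:K) {
    origins <- seq(1L, N - tau, by = stride)
    d <- X[origins + tau, , drop = FALSE] - X[origins, , drop = FALSE]
    vals[tau + 1] <- sum(d^2) / (length(origins) * P)
  }
  vals
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags (0..%g ps), %d particles, %d origins\n",
              length(x$lags), max(x$lags), x$n_particles, x$n_origins))
  invisible(x)
}

#' Write an MSD curve as TSV (lag_ps, msd_nm2)
#' @param curve an `msd_curve`.
#' @param path output file.
#' @export
write_msd_tsv <- function(curve, path) {
  utils::write.table(
    data.frame(lag_ps = curve$lags, msd_nm2 = curve$msd),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit a diffusion coefficient to the linear regime of an MSD curve
#'
#' Unweighted least squares of MSD against lag over the fit window;
#' D = slope / 6 converted from nm^2 ps^-1 to m^2 s^-1. The default window
#' spans 10 % to 50 % of the largest lag, excluding the short-time regime
#' while keeping well-averaged lags.
#'
#' @param curve an `msd_curve`.
#' @param fit_window `c(lo, hi)` in ps; lags in `[lo, hi]` are used.
#' @return D in m^2 s^-1, with the window, slope and intercept attached as
#'   attributes.
#' @export
fit_diffusion <- function(curve, fit_window = NULL) {
  if (is.null(fit_window))
    fit_window <- c(0.1, 0.5) * max(curve$lags)
  if (length(fit_window) != 2 || fit_window[1] >= fit_window[2])
    stop("fit_window must be c(lo, hi) with lo < hi")
  sel <- curve$lags >= fit_window[1] & curve$lags <= fit_window[2]
  if (sum(sel) < 3) stop("fewer than 3 MSD points in the fit window")
  fit <- stats::lm.fit(cbind(1, curve$lags[sel]), curve$msd[sel])
  slope <- fit$coefficients[2]
  d <- unname(slope / 6 * .nm2ps_to_m2s)
  structure(d, fit_window = fit_window, slope_nm2ps = unname(slope),
            intercept_nm2 = unname(fit$coefficients[1]))
}

#' Finite-size correction for periodic-boundary diffusion coefficients
#'
#' Diffusion coefficients from periodic boxes underestimate the
#' infinite-dilution value. The exact additive form is
#' `D0 = D_PBC + xi kB T / (6 pi eta L)`; substituting the Stokes-Einstein
#' viscosity gives the viscosity-free approximate form
#' `D0 = D_PBC / (1 - xi R / L)` used by default, with R a hydrodynamic
#' (here: structural rms) radius.
#'
#' @param d_pbc uncorrected diffusion coefficient, m^2 s^-1.
#' @param box_side box edge L, nm.
#' @param radius hydrodynamic radius R, Angstrom (approximate form).
#' @param form `"approximate"` or `"exact"`.
#' @param temperature temperature K (exact form).
#' @param viscosity dynamic viscosity, Pa s (exact form).
#' @param xi lattice constant of the correction (2.837297 for a cubic
#'   box).
#' @return corrected D0 in m^2 s^-1.
#' @examples
#' finite_size_correction(2e-9, 10.6, radius = 1.0)
#' @export
finite_size_correction <- function(d_pbc, box_side, radius = NULL,
                                   form = c("approximate", "exact"),
                                   temperature = NULL, viscosity = NULL,
                                   xi = 2.837297) {
  form <- match.arg(form)
  if (box_side <= 0) stop("box_side must be positive")
  if (form == "approximate") {
    if (is.null(radius) || radius < 0)
      stop("approximate form needs a non-negative radius (Angstrom)")
    ratio <- xi * (radius / 10) / box_side
    if (ratio >= 1)
      stop("xi * R / L >= 1: approximate correction diverges")
    d_pbc / (1 - ratio)
  } else {
    if (is.null(viscosity) || is.null(temperature))
      stop("exact form needs temperature and viscosity")
    if (viscosity <= 0 || temperature <= 0)
      stop("temperature and viscosity must be positive")
    d_pbc + xi * .kB * temperature / (6 * pi * viscosity * (box_side * 1e-9))
  }
}

#' Block-average uncertainty of a diffusion estimate
#'
#' Splits the trajectory into `n_blocks` contiguous blocks, estimates D in
#' each (same MSD pipeline, windows scaled to the block length) and
#' returns the standard error of the block estimates.
#'
#' With the default lag window, which scales with the block length, the
#' per-block relative error is roughly independent of the block length;
#' supply a fixed `max_lag`/`fit_window` to see the uncertainty shrink as
#' more data accumulate.
#'
#' @param traj an unwrapped [trajectory()].
#' @param n_blocks number of blocks (>= 2, each >= 10 frames).
#' @param origin_stride passed to [msd()].
#' @param max_lag,fit_window fixed lag range for the per-block fits;
#'   defaults scale with the block length.
#' @return standard error in m^2 s^-1.
#' @export
block_uncertainty <- function(traj, n_blocks = 5L, origin_stride = 1L,
                              max_lag = NULL, fit_window = NULL) {
  if (traj$wrapped) stop("unwrap the trajectory first")
  if (n_blocks < 2) stop("need at least 2 blocks")
  N <- n_frames(traj)
  size <- floor(N / n_blocks)
  if (size < 10) stop("too few frames per block (need >= 10)")
  dt <- traj$times[2] - traj$times[1]
  d_blocks <- vapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1) * size + 1):(b * size)
    sub <- trajectory(traj$positions[idx, , , drop = FALSE],
                      box_side = traj$box_side, dt = dt, wrapped = FALSE,
                      species = traj$species)
    as.numeric(fit_diffusion(msd(sub, max_lag = max_lag,
                                 origin_stride = origin_stride),
                             fit_window = fit_window))
  }, numeric(1))
  stats::sd(d_blocks) / sqrt(n_blocks)
}

#' Estimate a finite-size-corrected diffusion coefficient from a trajectory
#'
#' Convenience wrapper chaining [unwrap_trajectory()], [msd()],
#' [fit_diffusion()], [finite_size_correction()] and (optionally)
#' [block_uncertainty()].
#'
#' @param traj a [trajectory()] (wrapped input is unwrapped first).
#' @param radius hydrodynamic radius used in the correction, Angstrom;
#'   `NULL` skips the correction.
#' @param max_lag,origin_stride,method passed to [msd()].
#' @param fit_window passed to [fit_diffusion()].
#' @param n_blocks blocks for the uncertainty; `NULL` skips it.
#' @param correction_form,temperature,viscosity,xi passed to
#'   [finite_size_correction()].
#' @return object of class `diffusion_estimate` with `d_pbc`,
#'   `d_corrected`, `uncertainty`, `fit_window`, `box_side`, `radius`,
#'   `xi`, `temperature` and the MSD curve.
#' @export
estimate_diffusion <- function(traj, radius = NULL, max_lag = NULL,
                               origin_stride = 1L,
                               method = c("auto", "fft", "direct"),
                               fit_window = NULL, n_blocks = NULL,
                               correction_form = c("approximate", "exact"),
                               temperature = NULL, viscosity = NULL,
                               xi = 2.837297) {
  correction_form <- match.arg(correction_form)
  if (traj$wrapped) traj <- unwrap_trajectory(traj)
  curve <- msd(traj, max_lag = max_lag, origin_stride = origin_stride,
               method = match.arg(method))
  d_pbc <- fit_diffusion(curve, fit_window = fit_window)
  d_corr <- if (is.null(radius) && correction_form == "approximate")
    as.numeric(d_pbc)
  else finite_size_correction(as.numeric(d_pbc), traj$box_side,
                              radius = radius, form = correction_form,
                              temperature = temperature,
                              viscosity = viscosity, xi = xi)
  unc <- if (!is.null(n_blocks)) block_uncertainty(traj, n_blocks) else NA_real_
  structure(list(d_pbc = as.numeric(d_pbc), d_corrected = d_corr,
                 uncertainty = unc,
                 fit_window = attr(d_pbc, "fit_window"),
                 box_side = traj$box_side, radius = radius, xi = xi,
                 temperature = temperature, species = traj$species,
                 n_origins = curve$n_origins, curve = curve),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("Diffusion estimate%s:\n",
              if (nzchar(x$species)) paste0(" [", x$species, "]") else ""))
  cat(sprintf("  D_PBC       = %.4g m^2/s\n", x$d_pbc))
  cat(sprintf("  D_corrected = %.4g m^2/s (L = %.3f nm%s)\n", x$d_corrected,
              x$box_side,
              if (!is.null(x$radius)) sprintf(", R = %.2f A", x$radius)
              else ""))
  if (is.finite(x$uncertainty))
    cat(sprintf("  uncertainty = %.2g m^2/s\n", x$uncertainty))
  cat(sprintf("  fit window  = [%g, %g] ps\n", x$fit_window[1],
              x$fit_window[2]))
  invisible(x)
}

#' Write a diffusion estimate summary as JSON
#' @param estimate a `diffusion_estimate`.
#' @param path output file.
#' @export
write_diffusion_summary <- function(estimate, path) {
  jsonlite::write_json(
    list(d_pbc = estimate$d_pbc, d_corrected = estimate$d_corrected,
         uncertainty = estimate$uncertainty,
         fit_window_ps = estimate$fit_window,
         n_origins = estimate$n_origins, R_used_A = estimate$radius,
         L_nm = estimate$box_side, xi = estimate$xi),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
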