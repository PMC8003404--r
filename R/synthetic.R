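# Synthetic data generators. Brownian (ideal Fickian) tracer trajectories
# with a known ground-truth diffusion coefficient stand in for the
# cluster-scale MD production runs; constructed donor/acceptor frames
# straddle the hydrogen-bond thresholds with a known bond count.

#' Generate a Brownian trajectory with known diffusion coefficient
#'
#' Each tracer is a molecular centre of mass performing an independent
#' isotropic random walk: per-step displacements are zero-mean Gaussians
#' with variance `2 * d_true * dt` per Cartesian component (d_true
#' converted internally to nm^2/ps; 1 nm^2 ps^-1 = 1e-6 m^2 s^-1). This is
#' the ideal Fickian regime the MSD estimator assumes — no hydrodynamic
#' interactions, crowding, or intramolecular dynamics. Defaults mirror a
#' production run: 10^4 frames stored every 1 ps (10 ns).
#'
#' @param n_particles number of tracers (e.g. 200 CO2-like, up to 2199
#'   EtOH-like).
#' @param d_true true diffusion coefficient, m^2 s^-1 (>= 0).
#' @param box_side cubic box edge, nm.
#' @param dt frame spacing, ps.
#' @param n_frames number of stored frames (>= 2).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param wrap fold coordinates into `[0, box_side)`? The unwrapped truth
#'   is retained in the `"unwrapped"` attribute for oracle tests.
#' @param species species label.
#' @return a [trajectory()] with `d_true` recorded and the seed stored in
#'   the `"seed"` attribute.
#' @examples
#' tr <- brownian_trajectory(5, 2e-9, 10.6, n_frames = 100, seed = 1)
#' @export
brownian_trajectory <- function(n_particles, d_true, box_side, dt = 1,
                                n_frames = 10000L, seed = 1L, wrap = FALSE,
                                species = "") {
  if (d_true < 0) stop("d_true must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (n_frames < 2) stop("at least two frames required")
  if (n_particles < 1) stop("at least one particle required")
  set.seed(as.integer(seed))
  d_nm <- d_true / .nm2ps_to_m2s        # nm^2 / ps
  sigma <- sqrt(2 * d_nm * dt)          # per-component step sd, nm
  ncol3 <- n_particles * 3
  pos <- matrix(0, n_frames, ncol3)
  pos[1, ] <- stats::runif(ncol3, 0, box_side)
  if (n_frames > 1) {
    steps <- matrix(stats::rnorm((n_frames - 1) * ncol3, 0, sigma),
                    n_frames - 1, ncol3)
    pos[-1, ] <- sweep(apply(steps, 2, cumsum), 2, pos[1, ], "+")
  }
  arr <- array(pos, c(n_frames, n_particles, 3))
  tr <- trajectory(arr, box_side = box_side, dt = dt, wrapped = FALSE,
                   species = species, d_true = d_true)
  attr(tr, "seed") <- as.integer(seed)
  if (wrap) {
    tr <- wrap_trajectory(tr)
    attr(tr, "seed") <- as.integer(seed)
  }
  tr
}

#' Construct a donor/acceptor frame with a known hydrogen-bond count
#'
#' Builds `n_bonded` donor-acceptor pairs satisfying both criteria
#' (O-O distance < cutoff and H-Od-Oa angle <= cutoff), plus pairs that
#' violate exactly one criterion: `n_near_miss_distance` pairs with a good
#' angle but O-O just beyond the distance cutoff, and `n_near_miss_angle`
#' pairs within distance but past the angle cutoff. Pair centres are kept
#' at least 1 nm apart (minimum image) so no accidental cross-pair bonds
#' arise; all coordinates are wrapped, so pairs may legitimately straddle
#' the periodic boundary.
#'
#' @param n_bonded,n_near_miss_distance,n_near_miss_angle pair counts.
#' @param box_side cubic box edge, nm.
#' @param seed integer seed.
#' @param criterion a [hbond_criterion()].
#' @param donor_species,acceptor_species species tags for the generated
#'   sites.
#' @return list with `frame` (a [donor_acceptor_frame()]) and
#'   `expected_count` (= `n_bonded`).
#' @export
hbond_fixture <- function(n_bonded, n_near_miss_distance = 0,
                          n_near_miss_angle = 0, box_side = 5, seed = 1L,
                          criterion = hbond_criterion(),
                          donor_species = "DON", acceptor_species = "ACC") {
  stopifnot(n_bonded >= 0, n_near_miss_distance >= 0, n_near_miss_angle >= 0)
  set.seed(as.integer(seed))
  n_pairs <- n_bonded + n_near_miss_distance + n_near_miss_angle
  if (n_pairs == 0) stop("at least one pair required")
  sep <- 1.0
  if (n_pairs * (4 / 3) * pi * (sep / 2)^3 > 0.55 * box_side^3)
    stop("placement failure: box too small for the requested pair count")

  # place well-separated pair centres (rejection sampling, minimum image)
  centres <- matrix(NA_real_, n_pairs, 3)
  for (i in seq_len(n_pairs)) {
    ok <- FALSE
    for (att in 1:2000) {
      p <- stats::runif(3, 0, box_side)
      if (i == 1) { ok <- TRUE } else {
        d <- sweep(centres[seq_len(i - 1), , drop = FALSE], 2, p)
        d <- d - box_side * round(d / box_side)
        ok <- all(rowSums(d^2) >= sep^2)
      }
      if (ok) { centres[i, ] <- p; break }
    }
    if (!ok) stop("placement failure: could not separate pair centres")
  }

  kind <- rep(c("bond", "near_dist", "near_angle"),
              c(n_bonded, n_near_miss_distance, n_near_miss_angle))
  d_oh <- 0.1 # donor O-H bond, nm
  od <- centres
  hh <- matrix(NA_real_, n_pairs, 3)
  oa <- matrix(NA_real_, n_pairs, 3)
  for (i in seq_len(n_pairs)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))   # O-H direction
    hh[i, ] <- od[i, ] + d_oh * u
    ang <- switch(kind[i],
                  bond = stats::runif(1, 0, 0.85 * criterion$angle_cutoff),
                  near_dist = stats::runif(1, 0, 0.85 * criterion$angle_cutoff),
                  near_angle = stats::runif(1, 1.15 * criterion$angle_cutoff,
                                            min(2.3 * criterion$angle_cutoff, 170)))
    dist <- switch(kind[i],
                   bond = stats::runif(1, 0.7 * criterion$oo_cutoff,
                                       0.95 * criterion$oo_cutoff),
                   near_dist = stats::runif(1, 1.03 * criterion$oo_cutoff,
                                            1.25 * criterion$oo_cutoff),
                   near_angle = stats::runif(1, 0.7 * criterion$oo_cutoff,
                                             0.95 * criterion$oo_cutoff))
    # rotate u by `ang` degrees about a random perpendicular axis
    perp <- stats::rnorm(3)
    perp <- perp - sum(perp * u) * u
    perp <- perp / sqrt(sum(perp^2))
    a <- ang * pi / 180
    v <- cos(a) * u + sin(a) * perp
    oa[i, ] <- od[i, ] + dist * v
  }
  frame <- donor_acceptor_frame(
    box_side = box_side,
    donor_o = od %% box_side, donor_h = hh %% box_side,
    acceptor_o = oa %% box_side,
    donor_species = rep(donor_species, n_pairs),
    acceptor_species = rep(acceptor_species, n_pairs))
  list(frame = frame, expected_count = as.integer(n_bonded))
}
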