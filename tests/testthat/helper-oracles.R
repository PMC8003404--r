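# Brute-force oracles and small fixture builders shared across tests.
# The oracles are deliberately naive (explicit loops) and independent of
# the package's optimised code paths.

# O(n^2) multi-origin MSD: double loop over origins and lags
oracle_msd <- function(traj, max_lag = NULL, origin_stride = 1L) {
  dt <- traj$times[2] - traj$times[1]
  duration <- traj$times[length(traj$times)] - traj$times[1]
  if (is.null(max_lag)) max_lag <- duration / 2
  K <- floor(max_lag / dt + 1e-9)
  N <- dim(traj$positions)[1]
  P <- dim(traj$positions)[2]
  vals <- numeric(K + 1)
  for (tau in 0:K) {
    acc <- 0
    n <- 0
    for (t0 in seq(1L, N - tau, by = origin_stride)) {
      for (p in seq_len(P)) {
        d <- traj$positions[t0 + tau, p, ] - traj$positions[t0, p, ]
        acc <- acc + sum(d^2)
        n <- n + 1
      }
    }
    vals[tau + 1] <- acc / n
  }
  vals
}

# all-pairs hydrogen-bond count with explicit loops and minimum image
oracle_hbond_count <- function(frame, criterion = hbond_criterion()) {
  L <- frame$box_side
  count <- 0L
  for (i in seq_len(nrow(frame$donor_o))) {
    for (j in seq_len(nrow(frame$acceptor_o))) {
      doa <- frame$acceptor_o[j, ] - frame$donor_o[i, ]
      doa <- doa - L * round(doa / L)
      dist <- sqrt(sum(doa^2))
      if (dist >= criterion$oo_cutoff || dist <= 1e-9) next
      oh <- frame$donor_h[i, ] - frame$donor_o[i, ]
      oh <- oh - L * round(oh / L)
      cosang <- sum(oh * doa) / (sqrt(sum(oh^2)) * dist)
      ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      if (ang <= criterion$angle_cutoff) count <- count + 1L
    }
  }
  count
}

# uniform random rotation via QR (independent of the package's quaternion
# construction)
qr_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid rotation + translation to a geometry
transform_geometry <- function(g, rot = diag(3), shift = c(0, 0, 0)) {
  mol_geometry(g$name, g$elements,
               sweep(g$xyz %*% t(rot), 2, shift, "+"), g$masses)
}

# random donor/acceptor frame (no constructed structure; for oracle
# comparisons and invariance checks)
random_da_frame <- function(n_donors, n_acceptors, box_side, seed) {
  set.seed(seed)
  od <- matrix(stats::runif(n_donors * 3, 0, box_side), n_donors)
  u <- matrix(stats::rnorm(n_donors * 3), n_donors)
  u <- u / sqrt(rowSums(u^2))
  hh <- (od + 0.1 * u) %% box_side
  oa <- matrix(stats::runif(n_acceptors * 3, 0, box_side), n_acceptors)
  donor_acceptor_frame(box_side, od, hh, oa,
                       donor_species = rep("D", n_donors),
                       acceptor_species = rep("A", n_acceptors))
}
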