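test_that("unwrapping inverts wrapping up to whole-box offsets", {
  tr <- brownian_trajectory(5, 4e-9, 3, n_frames = 300, seed = 12)
  wrapped <- wrap_trajectory(tr)
  back <- unwrap_trajectory(wrapped)
  L <- tr$box_side
  diffs <- tr$positions - back$positions
  for (p in 1:5) for (k in 1:3) {
    off <- diffs[, p, k]
    expect_lt(max(abs(off - off[1])), 1e-9)        # constant per particle
    expect_lt(abs(off[1] / L - round(off[1] / L)), 1e-9) # integer boxes
  }
  # unwrapped input is passed through untouched
  expect_identical(unwrap_trajectory(tr), tr)
})

test_that("boundary crossings accumulate whole box lengths", {
  # 1D drift crossing the +x face repeatedly: x(t) = 0.1 + 0.4 t, L = 1
  L <- 1; n <- 11
  truth <- 0.1 + 0.4 * (0:(n - 1))
  pos <- array(0.5, c(n, 1, 3))
  pos[, 1, 1] <- truth %% L
  tr <- trajectory(pos, box_side = L, dt = 1, wrapped = TRUE)
  un <- unwrap_trajectory(tr)
  expect_equal(un$positions[, 1, 1], truth, tolerance = 1e-12)
  expect_equal(un$positions[n, 1, 1] - un$positions[1, 1, 1],
               truth[n] - truth[1], tolerance = 1e-12)
})

test_that("ambiguous jumps near half the box are reported", {
  pos <- array(0, c(3, 1, 3))
  pos[, 1, 1] <- c(0.1, 0.6, 0.1)  # |step| = L/2 exactly
  tr <- trajectory(pos, box_side = 1, dt = 1, wrapped = TRUE)
  expect_warning(unwrap_trajectory(tr), "ambiguous")
  expect_error(unwrap_trajectory(tr, on_ambiguity = "error"), "ambiguous")
})

test_that("MSD closed forms: static and ballistic trajectories", {
  static <- brownian_trajectory(3, 0, 5, n_frames = 40, seed = 1)
  expect_true(all(msd(static)$msd == 0))
  # constant velocity v: MSD(tau) = |v|^2 tau^2
  v <- c(0.03, -0.01, 0.02); n <- 60
  pos <- array(NA_real_, c(n, 1, 3))
  for (k in 1:3) pos[, 1, k] <- v[k] * (0:(n - 1))
  tr <- trajectory(pos, box_side = 100, dt = 1)
  curve <- msd(tr, max_lag = 20, method = "direct")
  expect_equal(curve$msd, sum(v^2) * curve$lags^2, tolerance = 1e-12)
})

test_that("optimised MSD paths match the double-loop oracle", {
  tr <- brownian_trajectory(5, 2e-9, 10, n_frames = 50, seed = 21)
  expected <- oracle_msd(tr, max_lag = 20)
  direct <- msd(tr, max_lag = 20, method = "direct")
  fft <- msd(tr, max_lag = 20, method = "fft")
  expect_equal(direct$msd, expected, tolerance = 1e-12)
  expect_equal(fft$msd, expected, tolerance = 1e-10)
  expect_equal(direct$lags, 0:20)
  # strided origins only admit every third frame
  strided <- msd(tr, max_lag = 15, origin_stride = 3, method = "direct")
  expect_equal(strided$msd, oracle_msd(tr, max_lag = 15, origin_stride = 3),
               tolerance = 1e-12)
})

test_that("MSD is invariant under rigid translation of all coordinates", {
  tr <- brownian_trajectory(4, 2e-9, 10, n_frames = 80, seed = 3)
  shifted <- tr
  for (k in 1:3) shifted$positions[, , k] <- tr$positions[, , k] + c(5, -2, 9)[k]
  expect_equal(msd(shifted)$msd, msd(tr)$msd, tolerance = 1e-9)
})

test_that("MSD input contracts are enforced", {
  tr <- brownian_trajectory(3, 1e-9, 5, n_frames = 30, seed = 2)
  expect_error(msd(wrap_trajectory(tr)), "wrapped")
  expect_error(msd(tr, max_lag = 1e4), "duration")
  expect_error(msd(tr, origin_stride = 2, method = "fft"), "origin_stride")
})

test_that("diffusion fit recovers a noiseless linear MSD exactly", {
  d_nm <- 2e-3 # nm^2/ps, i.e. 2e-9 m^2/s
  lags <- 0:100
  curve <- structure(list(lags = lags, msd = 6 * d_nm * lags,
                          n_origins = 1L, n_particles = 1L),
                     class = "msd_curve")
  expect_equal(as.numeric(fit_diffusion(curve)), 2e-9, tolerance = 1e-12)
  flat <- curve; flat$msd <- rep(0, length(lags))
  expect_equal(as.numeric(fit_diffusion(flat)), 0)
  expect_error(fit_diffusion(curve, fit_window = c(50, 50)), "lo < hi")
  expect_error(fit_diffusion(curve, fit_window = c(98.5, 99.5)),
               "fewer than 3")
})

test_that("fit recovers the generator ground truth on a fixed seed", {
  tr <- brownian_trajectory(50, 2e-9, 10.6, n_frames = 2000, seed = 11)
  d <- as.numeric(fit_diffusion(msd(tr)))
  expect_equal(d, 2e-9, tolerance = 0.1)
})

test_that("finite-size correction follows the printed closed form", {
  # no correction at R = 0
  expect_identical(finite_size_correction(2e-9, 10.6, radius = 0), 2e-9)
  # direct evaluation of the multiplicative form
  expect_equal(finite_size_correction(2e-9, 10.6, radius = 1.0),
               2e-9 * (1 - 2.837297 * 0.1 / 10.6)^(-1), tolerance = 1e-15)
  # strictly increasing in R below the divergence
  rr <- seq(0, 30, by = 2)
  dd <- vapply(rr, function(r) finite_size_correction(1e-9, 10.6, r),
               numeric(1))
  expect_true(all(diff(dd) > 0))
  expect_error(finite_size_correction(1e-9, 1, radius = 4), "diverges")
  expect_error(finite_size_correction(1e-9, 10, form = "exact"),
               "temperature and viscosity")
})

test_that("exact and approximate corrections agree under the SE substitution", {
  # choosing eta = kB T / (6 pi D0 R) with D0 from the approximate form
  # makes the additive form land on the same D0 (algebraic identity)
  d_pbc <- 1.7e-9; L <- 10.8; r_A <- 1.6; tK <- 285
  d0 <- finite_size_correction(d_pbc, L, radius = r_A)
  eta <- 1.380649e-23 * tK / (6 * pi * d0 * r_A * 1e-10)
  d0_exact <- finite_size_correction(d_pbc, L, form = "exact",
                                     temperature = tK, viscosity = eta)
  expect_equal(d0_exact, d0, tolerance = 1e-12)
})

test_that("block uncertainty is zero for deterministic motion and guards input", {
  static <- brownian_trajectory(3, 0, 5, n_frames = 200, seed = 1)
  expect_equal(block_uncertainty(static, 5), 0)
  tr <- brownian_trajectory(10, 2e-9, 10, n_frames = 400, seed = 6)
  expect_gt(block_uncertainty(tr, 5), 0)
  expect_error(block_uncertainty(tr, n_blocks = 400), "too few frames")
  expect_error(block_uncertainty(tr, n_blocks = 1), "at least 2 blocks")
})

test_that("block uncertainty shrinks with trajectory length at a fixed window", {
  # doubling the length at a fixed fit window should shrink the standard
  # error roughly as 1/sqrt(2); pooled over seeds to tame the noise of
  # 5-block standard errors
  short <- numeric(6); long <- numeric(6)
  for (s in 1:6) {
    short[s] <- block_uncertainty(
      brownian_trajectory(8, 2e-9, 10, n_frames = 600, seed = s),
      5, max_lag = 30, fit_window = c(3, 20))
    long[s] <- block_uncertainty(
      brownian_trajectory(8, 2e-9, 10, n_frames = 1200, seed = s + 50),
      5, max_lag = 30, fit_window = c(3, 20))
  }
  expect_lt(mean(long) / mean(short), 0.9)
})

test_that("estimate_diffusion assembles a coherent summary", {
  tr <- brownian_trajectory(20, 2e-9, 10.6, n_frames = 800, seed = 4,
                            wrap = TRUE)
  est <- estimate_diffusion(tr, radius = 0.94, n_blocks = 4)
  expect_s3_class(est, "diffusion_estimate")
  expect_gt(est$d_corrected, est$d_pbc)
  expect_gte(est$uncertainty, 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_diffusion_summary(est, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$d_pbc, est$d_pbc)
  expect_equal(js$xi, 2.837297)
})
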