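test_that("Stokes-Einstein relation and its inverse compose to the identity", {
  set.seed(10)
  for (i in 1:20) {
    tK <- runif(1, 270, 310)
    eta <- runif(1, 0.5e-3, 3e-3)
    r <- runif(1, 0.5, 3)
    d <- se_diffusion(tK, eta, r)
    expect_equal(se_radius(tK, eta, d), r, tolerance = 1e-14)
    expect_equal(se_diffusion(tK, eta, se_radius(tK, eta, d)), d,
                 tolerance = 1e-14)
  }
})

test_that("Stokes-Einstein diffusivity has the right scalings and magnitude", {
  d1 <- se_diffusion(293, 1.002e-3, 1.03)
  # direct evaluation of kB T / (6 pi eta R)
  expect_equal(d1, 1.380649e-23 * 293 / (6 * pi * 1.002e-3 * 1.03e-10),
               tolerance = 1e-15)
  expect_gt(d1, 1e-9); expect_lt(d1, 3e-9) # literature CO2 order of magnitude
  expect_equal(se_diffusion(293, 2 * 1.002e-3, 1.03), d1 / 2,
               tolerance = 1e-15)
  # strictly increasing in T, decreasing in eta and R
  expect_gt(se_diffusion(294, 1e-3, 1), se_diffusion(293, 1e-3, 1))
  expect_lt(se_diffusion(293, 1.1e-3, 1), se_diffusion(293, 1e-3, 1))
  expect_lt(se_diffusion(293, 1e-3, 1.1), se_diffusion(293, 1e-3, 1))
  expect_error(se_diffusion(0, 1e-3, 1), "positive")
  expect_error(se_radius(293, 1e-3, -1), "positive")
})

test_that("reference radii table is self-consistent with the inverse relation", {
  # a viscosity chosen so that se_diffusion gives D reproduces the radius
  r_ref <- 1.85; tK <- 285; eta <- 1.4e-3
  d <- se_diffusion(tK, eta, r_ref)
  expect_equal(se_radius(tK, eta, d), r_ref, tolerance = 1e-13)
  rad <- hydrodynamic_radii("nmr")
  expect_identical(dim(rad), c(6L, 3L))
  expect_equal(rad$radius_A[rad$species == "CO2"], c(0.95, 1.03, 1.03))
  expect_equal(rad$radius_A[rad$species == "EtOH"], c(1.81, 1.85, 1.80))
})

test_that("structural radius sources track the built-in geometries", {
  rms <- hydrodynamic_radii("rms")
  gyr <- hydrodynamic_radii("gyration")
  expect_equal(unique(rms$radius_A[rms$species == "CO2"]),
               rms_radius(co2_geometry("epm2")))
  expect_equal(unique(gyr$radius_A[gyr$species == "EtOH"]),
               gyration_radius(ethanol_geometry()))
})

test_that("experimental diffusion tables cover the grid with fixed radii", {
  visc <- synthetic_viscosity_table()
  tab <- experimental_diffusion_table(visc, species = "CO2")
  expect_equal(nrow(tab), 18) # 3 temperatures x 6 levels
  # viscosity rises with %vol at fixed T, so D falls
  for (tK in unique(tab$temperature_K)) {
    d <- tab$D_m2s[tab$temperature_K == tK]
    expect_true(all(diff(d) < 0))
  }
  # CO2 diffuses faster than EtOH at equal (T, eta): smaller radius
  etoh <- experimental_diffusion_table(visc, species = "EtOH")
  expect_true(all(tab$D_m2s > etoh$D_m2s))
})

test_that("swapping the radius table rescales diffusivities by the radius ratio", {
  visc <- synthetic_viscosity_table()
  nmr <- experimental_diffusion_table(visc, hydrodynamic_radii("nmr"), "EtOH")
  rms <- experimental_diffusion_table(visc, hydrodynamic_radii("rms"), "EtOH")
  r_rms <- rms_radius(ethanol_geometry())
  rad <- hydrodynamic_radii("nmr")
  r_nmr <- rad$radius_A[rad$species == "EtOH"][
    match(nmr$temperature_K, rad$temperature_K[rad$species == "EtOH"])]
  expect_equal(rms$D_m2s / nmr$D_m2s, r_nmr / r_rms, tolerance = 1e-12)
})

test_that("missing radius entries fail with the offending key", {
  visc <- data.frame(temperature_K = c(285, 300), pct_vol = 0,
                     viscosity_Pas = 1.2e-3)
  expect_error(experimental_diffusion_table(visc, species = "CO2"), "300")
})

test_that("viscosity tables are read with unit conversion", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("temperature_K\tpct_vol\tviscosity_mPas",
               "285\t0\t1.23", "285\t3\t1.42"), path)
  tab <- read_viscosity_table(path)
  expect_equal(tab$viscosity_Pas, c(1.23e-3, 1.42e-3))
  bundled <- synthetic_viscosity_table()
  # monotone in %vol, decreasing in T at fixed %vol
  for (tK in unique(bundled$temperature_K))
    expect_true(all(diff(bundled$viscosity_Pas[
      bundled$temperature_K == tK]) > 0))
  for (pv in unique(bundled$pct_vol))
    expect_true(all(diff(bundled$viscosity_Pas[bundled$pct_vol == pv]) < 0))
})
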