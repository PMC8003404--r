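test_that("ethanol counts reproduce the reference box compositions", {
  expected <- c(`0` = 0L, `3` = 385L, `6` = 795L, `9` = 1232L,
                `12` = 1699L, `15` = 2199L)
  got <- vapply(as.numeric(names(expected)), ethanol_count, integer(1))
  expect_identical(got, unname(expected))
})

test_that("ethanol count rounds half away from zero and is monotone", {
  # the 12 %vol entry sits at 1698.7: floor would give 1698
  raw <- 40000 * 796.06 * 18.015 / (999.49 * (100 / 12 - 1) * 46.068)
  expect_lt(raw, 1699)
  expect_identical(ethanol_count(12), 1699L)
  counts <- vapply(seq(0.5, 20, by = 0.5), ethanol_count, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("ethanol count rejects out-of-domain inputs", {
  expect_error(ethanol_count(100), "pct_vol")
  expect_error(ethanol_count(-1), "pct_vol")
  expect_error(ethanol_count(3, n_water = -5), "positive")
  expect_error(ethanol_count(3, rho_water = 0), "positive")
})

test_that("box side estimates span the expected range", {
  l0 <- box_side_estimate(mixture_spec(0), "water_density_only")
  l15 <- box_side_estimate(mixture_spec(15), "ideal_volume_mixing")
  expect_equal(l0, 10.6, tolerance = 0.01)
  expect_equal(l15, 11.2, tolerance = 0.01)
  # ethanol partial volume only ever enlarges the box
  for (pv in c(3, 9, 15)) {
    spec <- mixture_spec(pv)
    expect_gte(box_side_estimate(spec, "ideal_volume_mixing"),
               box_side_estimate(spec, "water_density_only"))
  }
})

test_that("box volume scales linearly with molecule counts", {
  s1 <- mixture_spec(6)
  s2 <- mixture_spec(6, n_water = 2 * s1$n_water, n_co2 = 2 * s1$n_co2,
                     n_ethanol = 2 * s1$n_ethanol)
  expect_equal(box_side_estimate(s2), box_side_estimate(s1) * 2^(1 / 3),
               tolerance = 1e-12)
})

test_that("mixture spec enforces its invariants", {
  expect_error(mixture_spec(3, n_ethanol = 0), "n_ethanol")
  expect_error(mixture_spec(0, n_ethanol = 10), "n_ethanol")
  expect_error(mixture_spec(3, rho_water = -1), "positive")
  expect_silent(validate_mixture_spec(mixture_spec(0)))
})

test_that("box structures respect counts, bounds and the separation cutoff", {
  spec <- mixture_spec(9, n_water = 300, n_co2 = 20,
                       n_ethanol = ethanol_count(9, n_water = 300))
  st <- build_box_structure(spec, seed = 42, min_dist = 0.25)
  expect_equal(n_molecules(st), spec$n_water + spec$n_co2 + spec$n_ethanol)
  expect_true(all(st$atoms[c("x", "y", "z")] >= 0) &&
                all(st$atoms[c("x", "y", "z")] < st$box_side))
  # minimum-image COM separations all above the cutoff
  n <- nrow(st$com)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    d <- sweep(st$com[(i + 1):n, , drop = FALSE], 2, st$com[i, ])
    d <- d - st$box_side * round(d / st$box_side)
    dmin <- min(dmin, sqrt(min(rowSums(d^2))))
  }
  expect_gte(dmin, 0.25)
})

test_that("box structure generation is deterministic and can fail to pack", {
  spec <- mixture_spec(0, n_water = 50, n_co2 = 5)
  a <- build_box_structure(spec, seed = 7)
  b <- build_box_structure(spec, seed = 7)
  expect_identical(a$atoms, b$atoms)
  expect_error(build_box_structure(spec, seed = 1, min_dist = 1.5,
                                   max_attempts = 20),
               "placement failure")
})

test_that("GRO round trip preserves a structure to format precision", {
  spec <- mixture_spec(0, n_water = 20, n_co2 = 3)
  st <- build_box_structure(spec, seed = 3)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(st, path)
  back <- read_gro(path)
  expect_equal(nrow(back$atoms), nrow(st$atoms))
  expect_equal(back$box_side, st$box_side, tolerance = 1e-4)
  expect_equal(back$atoms$x, st$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$z, st$atoms$z, tolerance = 1e-3)
  expect_identical(back$atoms$resname, st$atoms$resname)
})

test_that("composition reports have the documented layout", {
  rep <- composition_report()
  expect_identical(names(rep), c("pct_vol", "temperature_K", "n_water",
                                 "n_co2", "n_ethanol", "box_nm"))
  expect_identical(rep$n_ethanol, c(0L, 385L, 795L, 1232L, 1699L, 2199L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_composition_report(rep, path)
  expect_equal(utils::read.delim(path)$n_ethanol, rep$n_ethanol)
})
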