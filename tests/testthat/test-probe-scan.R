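# Dipolar probe, scan geometry and scan-table I/O.

test_that("dipole probe is a +1/-1 pair at the requested separation", {
  pr <- dipole_probe(c(1, 2, 3), c(0, 0, 2), separation = 1)
  expect_equal(sort(pr$q), c(-1, 1))
  expect_equal(sqrt(sum((pr[1, c("x", "y", "z")] - pr[2, c("x", "y", "z")])^2)), 1)
  expect_equal(colMeans(pr[, c("x", "y", "z")]), c(x = 1, y = 2, z = 3))
})

test_that("scan grids have the arithmetic-sequence point count", {
  w <- toy_molecule("water")
  ax <- scan_axis(c(0, 0, 1), id = "z")
  pl <- generate_scan(w, ax)
  expect_equal(nrow(pl), 31)
  expect_equal(pl$distance_angstrom[1], 2.5)
  expect_equal(pl$distance_angstrom[31], 10.0)

  expect_equal(nrow(generate_scan(w, ax, d_min = 5, d_max = 5)), 1)
  # generic floor((d_max - d_min)/step) + 1 law on exact-multiple grids
  for (case in list(c(2, 8, 0.5), c(1, 2, 0.1), c(3, 3.75, 0.25))) {
    pl2 <- generate_scan(w, ax, d_min = case[1], d_max = case[2], step = case[3])
    expect_equal(nrow(pl2), floor((case[2] - case[1]) / case[3] + 1e-9) + 1)
  }
})

test_that("four default axes give 124 pairwise-distinct placements", {
  w <- toy_molecule("water")
  pl <- generate_scan(w, fluqfit:::.default_axes())
  expect_equal(nrow(pl), 124)
  expect_equal(nrow(unique(pl[, c("mx", "my", "mz")])), 124)
})

test_that("recomputed anchor distances equal the requested grid to 1e-9", {
  w <- toy_molecule("water")
  com <- center_of_mass(w)
  pl <- generate_scan(w, list(scan_axis(c(1, 1, 0), id = "diag"),
                              scan_axis(c(0, 0, -1), id = "zm")))
  d <- sqrt((pl$mx - com[1])^2 + (pl$my - com[2])^2 + (pl$mz - com[3])^2)
  expect_equal(d, pl$distance_angstrom, tolerance = 1e-9)
})

test_that("per-axis anchor override measures distance from the override point", {
  w <- toy_molecule("water")
  anchor <- c(0, 0, 0)  # the O atom rather than the center of mass
  pl <- generate_scan(w, scan_axis(c(0, 0, 1), id = "O", origin = anchor),
                      d_min = 3, d_max = 4, step = 0.5)
  d <- sqrt(pl$mx^2 + pl$my^2 + pl$mz^2)
  expect_equal(d, pl$distance_angstrom, tolerance = 1e-12)
})

test_that("probe orientation rules are honoured", {
  w <- toy_molecule("water")
  along <- generate_scan(w, scan_axis(c(0, 0, 1), orientation = "along"),
                         d_min = 3, d_max = 3)
  anti <- generate_scan(w, scan_axis(c(0, 0, 1), orientation = "anti"),
                        d_min = 3, d_max = 3)
  perp <- generate_scan(w, scan_axis(c(0, 0, 1), orientation = "perpendicular"),
                        d_min = 3, d_max = 3)
  expect_equal(unlist(along[1, c("ex", "ey", "ez")], use.names = FALSE), c(0, 0, 1))
  expect_equal(unlist(anti[1, c("ex", "ey", "ez")], use.names = FALSE), c(0, 0, -1))
  expect_equal(sum(unlist(perp[1, c("ex", "ey", "ez")]) * c(0, 0, 1)), 0)
})

test_that("placements colliding with an atom are rejected", {
  w <- toy_molecule("water")
  # axis through the O atom with the probe's trailing charge landing on it
  expect_error(generate_scan(w, scan_axis(c(0, 0, 1), origin = c(0, 0, -0.6)),
                             d_min = 1.05, d_max = 1.15, step = 0.05),
               "collides")
})

test_that("scan energies match the single-probe path and the grid oracle", {
  w <- toy_molecule("water")
  p <- water_params()
  pl <- generate_scan(w, scan_axis(c(0, 0, 1)), d_min = 3, d_max = 5, step = 1)
  evald <- evaluate_scan(pl, w, p)
  for (i in seq_len(nrow(evald))) {
    pr <- dipole_probe(c(evald$mx[i], evald$my[i], evald$mz[i]),
                       c(evald$ex[i], evald$ey[i], evald$ez[i]))
    expect_equal(evald$e_fq_kcal[i], fq_interaction_energy(w, p, pr),
                 tolerance = 1e-10)
    expect_equal(evald$e_fq_kcal[i], oracle_grid_interaction(w, p, pr),
                 tolerance = 1e-6)
  }
})

test_that("scan energies decay monotonically in |E| beyond 8 angstrom", {
  w <- toy_molecule("water")
  p <- water_params()
  pl <- generate_scan(w, fluqfit:::.default_axes(), d_min = 8, d_max = 14,
                      step = 0.5)
  evald <- evaluate_scan(pl, w, p)
  for (a in unique(evald$axis_id)) {
    e <- abs(evald$e_fq_kcal[evald$axis_id == a])
    expect_true(all(diff(e) < 1e-12))
  }
  far <- evaluate_scan(generate_scan(w, scan_axis(c(0, 0, 1)),
                                     d_min = 1000, d_max = 1000), w, p)
  expect_lt(abs(far$e_fq_kcal), 1e-6)
})

test_that("flipping the probe negates the leading-order far-field interaction", {
  w <- toy_molecule("water")
  p <- water_params()
  mid <- c(0, 0, 20)
  e_plus <- fq_interaction_energy(w, p, dipole_probe(mid, c(0, 0, 1)))
  e_minus <- fq_interaction_energy(w, p, dipole_probe(mid, c(0, 0, -1)))
  expect_lt(abs(e_plus + e_minus), 0.01 * max(abs(e_plus), abs(e_minus)))
})

test_that("scan CSV round trip is exact to 1e-12 and validates its input", {
  w <- toy_molecule("water")
  ds <- make_reference_scan(w, water_params(), axes = list(scan_axis(c(0, 0, 1))),
                            d_min = 2.5, d_max = 4.75, step = 0.25, seed = 2)
  expect_equal(nrow(ds), 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_scan_csv(ds, f)
  back <- read_scan_csv(f)
  for (cl in c("distance_angstrom", "mx", "my", "mz", "ex", "ey", "ez",
               "e_ref_kcal", "weight")) {
    expect_equal(back[[cl]], ds[[cl]], tolerance = 1e-12)
  }
  expect_equal(back$axis_id, ds$axis_id)

  bad <- as.data.frame(ds); bad$distance_angstrom[3] <- -1
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(read_scan_csv(f2), "row 3")

  bad2 <- as.data.frame(ds); bad2$e_ref_kcal <- NULL
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad2, f3, row.names = FALSE)
  expect_error(read_scan_csv(f3), "e_ref_kcal")

  f4 <- withr::local_tempfile(fileext = ".csv")
  file.create(f4)
  expect_error(read_scan_csv(f4), "empty")
})

test_that("default weights are the inverse solvent-probe distance", {
  w <- toy_molecule("water")
  ds <- make_reference_scan(w, water_params(), axes = list(scan_axis(c(1, 0, 0))),
                            seed = 1)
  expect_equal(ds$weight, 1 / ds$distance_angstrom)
})
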