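# Snapshot cadence, sphere clipping and solvated-frame I/O.

test_that("snapshot schedules follow the one-interval-after-start rule", {
  t100 <- snapshot_times(2000, 20)
  expect_length(t100, 100)
  expect_equal(t100[1], 20)
  expect_equal(t100[100], 2000)

  expect_equal(snapshot_times(20, 20), 20)

  t25 <- snapshot_times(500, 20, window_start = 500)
  expect_length(t25, 25)
  expect_false(is.unsorted(t25, strictly = TRUE))
  expect_equal(t25[1], 520)

  expect_error(snapshot_times(10, 20), "empty schedule")
})

# hand-placed fixture: water-like solute at origin, 5 rigid 2-atom
# solvent molecules whose centers of mass sit at known distances
shell_fixture <- function(distances = c(3, 10, 19, 26, 30), box = NULL) {
  solute <- data.frame(element = c("O", "H", "H"),
                       x = c(0, 0.76, -0.76), y = 0, z = c(0, 0.59, 0.59))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(-1, 0, 0), c(0, -1, 0))
  scom <- unname(fluqfit:::.center_of_mass(solute$element,
                                           as.matrix(solute[, c("x", "y", "z")])))
  rows <- lapply(seq_along(distances), function(m) {
    com <- scom + dirs[m, ] * distances[m]
    # homonuclear pair straddling its center of mass
    data.frame(element = "N", x = com[1] + c(0.5, -0.5), y = com[2],
               z = com[3], mol = m)
  })
  solvated_frame(solute, do.call(rbind, rows), box = box)
}

test_that("sphere clipping retains exactly the molecules inside the radius", {
  fr <- shell_fixture()
  clipped <- cut_sphere(fr, 20)
  expect_equal(sort(unique(clipped$solvent$mol)), 1:3)
  expect_equal(nrow(clipped$solvent), 6)

  all_in <- cut_sphere(fr, 1000)
  expect_equal(nrow(all_in$solvent), nrow(fr$solvent))

  only_solute <- suppressWarnings(cut_sphere(fr, 0.2))
  expect_equal(nrow(only_solute$solvent), 0)
  expect_equal(only_solute$solute, fr$solute)
  expect_warning(cut_sphere(fr, 0.2), "solute extent")
})

test_that("clipping is idempotent, monotone in radius, and keeps molecules whole", {
  fr <- shell_fixture()
  counts <- vapply(c(1.5, 5, 15, 22, 28, 40), function(r) {
    cl <- suppressWarnings(cut_sphere(fr, r))
    # integrity: every retained molecule has both atoms
    expect_true(all(table(cl$solvent$mol) == 2))
    nrow(cl$solvent)
  }, numeric(1))
  expect_false(is.unsorted(counts))

  once <- cut_sphere(fr, 20)
  twice <- cut_sphere(once, 20)
  expect_equal(twice$solvent, once$solvent)
  expect_equal(twice$solute, once$solute)
})

test_that("periodic molecules are re-wrapped whole around the solute", {
  # solute near the low-x face; a molecule near the high-x face is only
  # 3 angstrom away through the periodic boundary
  box <- c(30, 30, 30)
  solute <- data.frame(element = "C", x = 2, y = 15, z = 15)
  solvent <- data.frame(element = "N", x = c(28.5, 29.5), y = 15, z = 15,
                        mol = 1L)
  fr <- solvated_frame(solute, solvent, box = box)
  cl <- cut_sphere(fr, 5)
  expect_equal(nrow(cl$solvent), 2)                       # wrapped image kept
  expect_equal(sort(cl$solvent$x), c(-1.5, -0.5))         # shifted by -box
  expect_equal(diff(sort(cl$solvent$x)), 1.0)             # still whole

  # without the periodic box the same molecule is 27 angstrom away
  cl2 <- cut_sphere(solvated_frame(solute, solvent, box = NULL), 5)
  expect_equal(nrow(cl2$solvent), 0)
})

test_that("XYZ round trip and droplet sidecar preserve the frame", {
  fr <- shell_fixture()
  xyz <- withr::local_tempfile(fileext = ".xyz")
  js <- withr::local_tempfile(fileext = ".json")
  write_droplet(fr, xyz, js)
  frames <- read_xyz(xyz)
  expect_length(frames, 1)
  at <- frames[[1]]$atoms
  expect_equal(nrow(at), nrow(fr$solute) + nrow(fr$solvent))
  expect_equal(at$x[1:3], fr$solute$x, tolerance = 1e-10)

  side <- jsonlite::read_json(js, simplifyVector = FALSE)
  expect_equal(side$n_solute, 3L)
  expect_length(side$solvent_groups, 5)
  expect_equal(sort(unlist(side$solvent_groups)), 4:13)

  rebuilt <- frame_from_atoms(at, n_solute = 3, solvent_size = 2)
  expect_equal(rebuilt$solvent$mol, fr$solvent$mol)
  expect_equal(rebuilt$solvent$z, fr$solvent$z, tolerance = 1e-10)
})

test_that("multi-frame XYZ files are split into frames", {
  xyz <- withr::local_tempfile(fileext = ".xyz")
  at <- data.frame(element = c("O", "H"), x = c(0, 1), y = 0, z = 0)
  write_xyz(at, xyz, comment = "f1")
  write_xyz(at, xyz, comment = "f2", append = TRUE)
  frames <- read_xyz(xyz)
  expect_length(frames, 2)
  expect_equal(frames[[2]]$comment, "f2")
})

test_that("GRO files are parsed fixed-width with nm-to-angstrom conversion", {
  gro <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "toy system",
    "    5",
    "    1SOL     C1    1   1.500   1.500   1.500",
    "    2WAT     OW    2   1.800   1.500   1.500",
    "    2WAT    HW1    3   1.880   1.500   1.560",
    "    3WAT     OW    4   0.300   1.500   1.500",
    "    3WAT    HW1    5   0.380   1.500   1.560",
    "   3.00000   3.00000   3.00000"), gro)
  fr <- read_gro(gro)
  expect_equal(fr$box, c(30, 30, 30))
  expect_equal(nrow(fr$solute), 1)
  expect_equal(fr$solute$x, 15)       # 1.5 nm -> 15 angstrom
  expect_equal(fr$solute$element, "C")
  expect_equal(unique(fr$solvent$mol), c(1, 2))
  expect_equal(fr$solvent$element, c("O", "H", "O", "H"))

  by_name <- read_gro(gro, solute = "SOL")
  expect_equal(by_name$solute$x, fr$solute$x)
})

test_that("PDB frames are grouped by residue", {
  skip_if_not_installed("bio3d")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            1, " C1", "LIG", 1, 0, 0, 0, "C"),
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            2, " OW", "HOH", 2, 5, 0, 0, "O"),
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            3, " HW", "HOH", 2, 5.8, 0, 0.6, "H"),
    "END"), pdb)
  fr <- read_pdb_frame(pdb)
  expect_equal(nrow(fr$solute), 1)
  expect_equal(fr$solvent$element, c("O", "H"))
  expect_equal(fr$solvent$mol, c(1, 1))
  expect_equal(fr$solvent$x, c(5, 5.8), tolerance = 1e-6)
})
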