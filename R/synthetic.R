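# Synthetic-data generators: every stage of the pipeline is testable
# without external quantum-chemistry or molecular-dynamics input.  Scan
# fixtures are produced by a *known* FQ truth parameter set (optionally
# noisy), solvated frames by random packing of rigid toy molecules, and
# excitation ensembles by Gaussian sampling that mimics the scatter of
# snapshot excitation energies.

#' Toy molecule geometries
#'
#' Fixed small geometries shipped with the package so closed-form oracles
#' (two-site charges and polarizability, brute-force charge-grid
#' minimization) have stable inputs:
#' * `diatomic` - CO-like pair, bond 1.128 angstrom along z;
#' * `water` - bent H2O (O-H 0.9572 angstrom, angle 104.52 deg) in the
#'   xz-plane;
#' * `nitrile` - linear CCN (C-C 1.458, C-N 1.157 angstrom) along z.
#'
#' @param name `"diatomic"`, `"water"` or `"nitrile"`.
#' @param kernel interaction kernel passed to [fq_system].
#' @return an [fq_system] (one neutral constraint group).
#' @export
toy_molecule <- function(name = c("water", "diatomic", "nitrile"),
                         kernel = c("ohno", "bare-coulomb")) {
  name <- match.arg(name)
  kernel <- match.arg(kernel)
  switch(name,
    diatomic = fq_system(c("C", "O"),
                         rbind(c(0, 0, 0), c(0, 0, 1.128)), kernel = kernel),
    water = {
      r <- 0.9572; half <- (104.52 / 2) * pi / 180
      fq_system(c("O", "H", "H"),
                rbind(c(0, 0, 0),
                      c(r * sin(half), 0, r * cos(half)),
                      c(-r * sin(half), 0, r * cos(half))),
                kernel = kernel)
    },
    nitrile = fq_system(c("C", "C", "N"),
                        rbind(c(0, 0, -1.458), c(0, 0, 0), c(0, 0, 1.157)),
                        kernel = kernel))
}

# default four-axis scan layout: both signed directions of the main (z)
# axis plus the two in-plane/out-of-plane transverse directions
.default_axes <- function() {
  list(scan_axis(c(0, 0, 1), id = "z+"),
       scan_axis(c(0, 0, -1), id = "z-"),
       scan_axis(c(1, 0, 0), id = "x+"),
       scan_axis(c(0, 1, 0), id = "y+"))
}

#' Generate a synthetic reference scan from a known FQ truth
#'
#' Stands in for an external quantum-chemistry reference dataset: probe
#' placements are generated on the requested grid, reference energies are
#' the FQ interaction energies under the truth parameters plus optional
#' i.i.d. Gaussian noise.  A noise-free dataset therefore satisfies
#' `fq_loss(dataset, system, truth)$xi2 == 0` exactly.
#'
#' @param system the solvent [fq_system].
#' @param truth the generating [fq_params].
#' @param axes list of [scan_axis]; default: four axes (+z, -z, +x, +y),
#'   which with the default grid gives 124 placements.
#' @param d_min,d_max,step scan grid (angstrom); defaults 2.5 / 10.0 /
#'   0.25 (31 points per axis).
#' @param noise_sd Gaussian noise standard deviation (kcal/mol), >= 0.
#' @param seed integer seed (required; noise-free columns are identical
#'   across seeds).
#' @return a [scan_dataset] with truth energies in `e_ref_kcal` and
#'   weights `1/d`.
#' @export
make_reference_scan <- function(system, truth, axes = NULL,
                                d_min = 2.5, d_max = 10.0, step = 0.25,
                                noise_sd = 0, seed) {
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  stopifnot(.is_number(noise_sd), noise_sd >= 0)
  if (is.null(axes)) axes <- .default_axes()
  placements <- generate_scan(system, axes, d_min = d_min, d_max = d_max,
                              step = step)
  evald <- evaluate_scan(placements, system, truth)
  set.seed(as.integer(seed))
  evald$e_ref_kcal <- evald$e_fq_kcal +
    stats::rnorm(nrow(evald), sd = noise_sd)
  evald$e_fq_kcal <- NULL
  scan_dataset(evald)
}

# uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed)
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Build a synthetic solvated frame
#'
#' Random rigid packing of whole solvent molecules around a solute placed
#' at the box center: positions are drawn uniformly in the box,
#' orientations uniformly on SO(3), and a candidate molecule is accepted
#' only when its center of mass stays at least `min_dist` from every
#' center of mass already placed.  Deterministic for a given seed.
#'
#' @param n_solvent number of solvent molecules (>= 0).
#' @param box orthorhombic box lengths (angstrom; scalar recycled).
#' @param template rigid solvent geometry, an [fq_system]
#'   (default [toy_molecule]`("water")`).
#' @param solute solute geometry, an [fq_system] (default: the template).
#' @param min_dist minimum center-of-mass separation (angstrom).
#' @param seed integer seed (required).
#' @param max_retries placement attempts per molecule before giving up.
#' @return a [solvated_frame].
#' @export
make_solvated_frame <- function(n_solvent, box, template = toy_molecule("water"),
                                solute = template, min_dist = 3.0, seed,
                                max_retries = 2000) {
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  stopifnot(n_solvent >= 0, min_dist > 0)
  if (length(box) == 1L) box <- rep(box, 3)
  stopifnot(length(box) == 3, all(box > 0))
  set.seed(as.integer(seed))

  center <- box / 2
  scoords <- sweep(solute$coords, 2, center_of_mass(solute)) |>
    sweep(2, center, `+`)
  solute_df <- data.frame(element = solute$elements,
                          x = scoords[, 1], y = scoords[, 2], z = scoords[, 3])
  tcoords <- sweep(template$coords, 2, center_of_mass(template))

  coms <- matrix(center, nrow = 1)
  rows <- vector("list", n_solvent)
  for (m in seq_len(n_solvent)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      pos <- stats::runif(3) * box
      # minimum-image center-of-mass distances in the periodic box
      dd <- sweep(coms, 2, pos)
      dd <- dd - sweep(round(sweep(dd, 2, box, `/`)), 2, box, `*`)
      if (min(rowSums(dd^2)) >= min_dist^2) {
        R <- .random_rotation()
        xyz <- sweep(tcoords %*% t(R), 2, pos, `+`)
        rows[[m]] <- data.frame(element = template$elements,
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                mol = m)
        coms <- rbind(coms, pos)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("packing failure: could not place molecule %d of %d at density %.3g molecules/angstrom^3",
                   m, n_solvent, (n_solvent + 1) / prod(box)))
    }
  }
  solvated_frame(solute_df, do.call(rbind, rows), box = box)
}

#' Sample a synthetic excitation ensemble
#'
#' Gaussian draws mimicking the scatter of snapshot excitation energies
#' around the band center; `n = 100` mirrors a typical snapshot count.
#'
#' @param mean band center (eV).
#' @param sd energy scatter (eV), >= 0.
#' @param n number of snapshots (>= 1), default 100.
#' @param seed integer seed (required).
#' @param label,phi,epsilon solvent metadata (see [excitation_ensemble]).
#' @return an [excitation_ensemble].
#' @export
make_excitation_ensemble <- function(mean, sd, n = 100, seed,
                                     label = NA_character_, phi = NA_real_,
                                     epsilon = NA_real_) {
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  stopifnot(.is_number(mean), .is_number(sd), sd >= 0, n >= 1)
  set.seed(as.integer(seed))
  excitation_ensemble(energies = stats::rnorm(n, mean, sd),
                      label = label, phi = phi, epsilon = epsilon)
}
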