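# Reference-dataset geometry: a dipolar probe (two opposite unit point
# charges) swept along molecular symmetry axes at a grid of distances.

#' Dipolar probe
#'
#' A pair of +1 / -1 a.u. point charges separated by 1 angstrom (default),
#' placed symmetrically about a midpoint along an orientation vector (the
#' positive charge sits on the +orientation side).
#'
#' @param midpoint length-3 position of the probe midpoint (angstrom).
#' @param orientation length-3 direction vector (normalized internally).
#' @param separation charge-charge distance (angstrom), default 1.
#' @return data.frame with columns `q`, `x`, `y`, `z` (one row per charge).
#' @export
dipole_probe <- function(midpoint = c(0, 0, 0), orientation = c(0, 0, 1),
                         separation = 1) {
  stopifnot(length(midpoint) == 3, .is_number(separation), separation > 0)
  u <- .unit_vector(orientation)
  pos <- midpoint + u * separation / 2
  neg <- midpoint - u * separation / 2
  data.frame(q = c(1, -1),
             x = c(pos[1], neg[1]), y = c(pos[2], neg[2]), z = c(pos[3], neg[3]))
}

#' Scan axis
#'
#' Defines one symmetry axis of the distance scan: the anchor point the
#' solvent-probe distance is measured from (default: molecular center of
#' mass, resolved at generation time), the scan direction, and the rule
#' fixing the probe orientation relative to the axis.
#'
#' @param direction length-3 direction vector (normalized to 1e-12).
#' @param id axis identifier used in scan tables.
#' @param origin anchor point (angstrom) or `NULL` for the molecule's
#'   center of mass (allows atom-anchored scans as a per-axis override).
#' @param orientation `"along"` (probe dipole parallel to the axis,
#'   positive charge outward), `"anti"` (antiparallel) or
#'   `"perpendicular"`.
#' @return An object of class `scan_axis`.
#' @export
scan_axis <- function(direction, id = "axis1", origin = NULL,
                      orientation = c("along", "anti", "perpendicular")) {
  orientation <- match.arg(orientation)
  u <- .unit_vector(direction)
  stopifnot(abs(sqrt(sum(u^2)) - 1) < 1e-12)
  if (!is.null(origin)) stopifnot(length(origin) == 3, all(is.finite(origin)))
  structure(list(id = as.character(id), direction = u, origin = origin,
                 orientation = orientation),
            class = "scan_axis")
}

# deterministic unit vector perpendicular to u
.perp_vector <- function(u) {
  v <- c(-u[2], u[1], 0)                 # u x z_hat, up to sign
  if (sqrt(sum(v^2)) < 1e-8) v <- c(1, 0, 0)
  .unit_vector(v)
}

.axis_probe_orientation <- function(axis) {
  switch(axis$orientation,
         along = axis$direction,
         anti = -axis$direction,
         perpendicular = .perp_vector(axis$direction))
}

#' Principal inertia axes of a molecule
#'
#' Helper proposing scan axes from the principal axes of the mass-weighted
#' inertia tensor (automatic point-group detection is deliberately out of
#' scope; axes remain user-specified).
#'
#' @param system an [fq_system].
#' @return list of three [scan_axis] objects (ids `pa1`-`pa3`).
#' @export
principal_axes <- function(system) {
  m <- .element_mass(system$elements)
  com <- center_of_mass(system)
  X <- sweep(system$coords, 2, com)
  r2 <- rowSums(X^2)
  I <- diag(c(sum(m * r2), sum(m * r2), sum(m * r2))) -
    t(X) %*% (X * m)
  ev <- eigen(I, symmetric = TRUE)
  lapply(1:3, function(k) scan_axis(ev$vectors[, k], id = paste0("pa", k)))
}

#' Generate dipolar-probe scan placements
#'
#' For each axis, places the probe midpoint at distances
#' `d_min, d_min + step, ...` up to `d_max` (endpoint included when it
#' falls on the grid within 1e-9) measured from the axis anchor (molecule
#' center of mass unless the axis overrides it).  The default grid
#' (2.5 to 10.0 angstrom in steps of 0.25) yields 31 placements per axis.
#'
#' @param system an [fq_system] (the solvent molecule).
#' @param axes a [scan_axis] or list of them.
#' @param d_min,d_max,step scan grid (angstrom); `d_min <= d_max`,
#'   `step > 0`.
#' @param separation probe charge separation (angstrom).
#' @return data.frame of placements with columns `axis_id`,
#'   `distance_angstrom`, `mx`, `my`, `mz` (midpoint), `ex`, `ey`, `ez`
#'   (orientation unit vector).
#' @export
generate_scan <- function(system, axes, d_min = 2.5, d_max = 10.0, step = 0.25,
                          separation = 1) {
  if (inherits(axes, "scan_axis")) axes <- list(axes)
  stopifnot(length(axes) >= 1, .is_number(d_min), .is_number(d_max), .is_number(step))
  if (d_min > d_max) stop("'d_min' must be <= 'd_max'")
  if (step <= 0) stop("'step' must be > 0")
  npts <- floor((d_max - d_min) / step + 1e-9) + 1L
  d <- d_min + step * (seq_len(npts) - 1L)
  com <- center_of_mass(system)
  rows <- lapply(axes, function(ax) {
    origin <- if (is.null(ax$origin)) com else ax$origin
    orient <- .axis_probe_orientation(ax)
    mid <- t(origin + outer(ax$direction, d))    # npts x 3
    data.frame(axis_id = ax$id, distance_angstrom = d,
               mx = mid[, 1], my = mid[, 2], mz = mid[, 3],
               ex = orient[1], ey = orient[2], ez = orient[3])
  })
  placements <- do.call(rbind, rows)
  # collision check: both probe charges must stay clear of every atom
  for (i in seq_len(nrow(placements))) {
    pr <- dipole_probe(c(placements$mx[i], placements$my[i], placements$mz[i]),
                       c(placements$ex[i], placements$ey[i], placements$ez[i]),
                       separation)
    dmin <- min(vapply(seq_len(nrow(pr)), function(k) {
      min(sqrt(rowSums(sweep(system$coords, 2,
                             c(pr$x[k], pr$y[k], pr$z[k]))^2)))
    }, numeric(1)))
    if (dmin < .MIN_DIST_ANG) {
      stop(sprintf("probe placement %d (axis %s, d = %.3f angstrom) collides with an atom",
                   i, placements$axis_id[i], placements$distance_angstrom[i]))
    }
  }
  attr(placements, "separation") <- separation
  placements
}

#' Scan dataset
#'
#' Validates and classes a table of probe-scan records: placements,
#' reference interaction energies `e_ref_kcal` and fitting weights
#' (default `w_i = 1/d_i` with d in angstrom, the inverse solvent-probe
#' distance).
#'
#' @param df data.frame with at least `axis_id`, `distance_angstrom`,
#'   `ex`, `ey`, `ez`, `e_ref_kcal`; midpoint columns `mx`, `my`, `mz`
#'   are required for re-evaluating FQ energies; a `weight` column is
#'   added as `1/distance` when absent.
#' @return data.frame of class `scan_dataset`.
#' @export
scan_dataset <- function(df) {
  required <- c("axis_id", "distance_angstrom", "ex", "ey", "ez", "e_ref_kcal")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("scan table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) < 1L) stop("empty scan dataset")
  if (nrow(df) > 1e4) stop("scan dataset exceeds the supported size (10^4 records)")
  num_cols <- intersect(c("distance_angstrom", "mx", "my", "mz",
                          "ex", "ey", "ez", "e_ref_kcal", "weight"), names(df))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) | is.na(df[[cl]]))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing value in column '%s', row %d", cl, bad[1]))
    }
    df[[cl]] <- v
  }
  neg <- which(df$distance_angstrom <= 0)
  if (length(neg)) {
    stop(sprintf("non-positive distance in row %d", neg[1]))
  }
  if (is.null(df$weight)) df$weight <- 1 / df$distance_angstrom
  if (any(df$weight <= 0)) stop("weights must be > 0")
  class(df) <- c("scan_dataset", "data.frame")
  df
}

# fast multi-placement evaluator; see fq-core.R for the single-probe path.
# Precomputes everything geometry-dependent once so repeated parameter
# evaluations (GA inner loop) only pay for a small factor-solve.
.make_scan_evaluator <- function(system, placements, separation = NULL) {
  if (is.null(separation)) {
    separation <- attr(placements, "separation")
    if (is.null(separation)) separation <- 1
  }
  n <- n_atoms(system)
  rmat <- .distance_matrix_bohr(system$coords)
  C <- .constraint_matrix(system)
  g <- nrow(C)
  N <- nrow(placements)
  Vmat <- matrix(0, n, N)
  for (i in seq_len(N)) {
    pr <- dipole_probe(c(placements$mx[i], placements$my[i], placements$mz[i]),
                       c(placements$ex[i], placements$ey[i], placements$ez[i]),
                       separation)
    Vmat[, i] <- .point_charge_potential(pr, system$coords)
  }
  spec_idx <- match(system$species, unique(system$species))
  species <- unique(system$species)
  kernel <- system$kernel
  Q <- system$group_charges

  # theta = c(chi_by_species, eta_by_species); returns E_int (kcal/mol) per placement
  function(theta) {
    k <- length(species)
    chi <- theta[spec_idx]
    eta <- theta[k + spec_idx]
    J <- .kernel_from_dist(rmat, eta, kernel)
    rhs <- rbind(cbind(-chi, -chi - Vmat), matrix(Q, g, N + 1))
    sol <- .solve_augmented(J, C, rhs)
    q <- sol$q
    JQ <- J %*% q
    E <- colSums(chi * q) + 0.5 * colSums(q * JQ) + colSums(cbind(0, Vmat) * q)
    (E[-1] - E[1]) * .HARTREE2KCAL
  }
}

#' Evaluate a probe scan at the FQ level
#'
#' Computes the FQ-probe interaction energy for every placement and
#' returns the table with an `e_fq_kcal` column appended.
#'
#' @param placements placement table from [generate_scan] or a
#'   [scan_dataset] carrying midpoint columns.
#' @param system an [fq_system].
#' @param params an [fq_params].
#' @param separation probe charge separation (angstrom); taken from the
#'   placement table attribute when available.
#' @return input table with `e_fq_kcal` added.
#' @export
evaluate_scan <- function(placements, system, params, separation = NULL) {
  need <- c("mx", "my", "mz", "ex", "ey", "ez")
  if (!all(need %in% names(placements))) {
    stop("placements must carry midpoint and orientation columns (",
         paste(need, collapse = ", "), ")")
  }
  ev <- .make_scan_evaluator(system, placements, separation)
  species <- unique(system$species)
  theta <- .params_to_theta(params, species)
  placements$e_fq_kcal <- ev(theta)
  placements
}
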