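# Electronegativity-equalization core: energy functional
#   E(q) = sum_i chi_i q_i + 1/2 q' J q + sum_i V_i q_i
# minimized under per-group charge constraints via Lagrange multipliers.
# All internal linear algebra is in atomic units (hartree, bohr, e).

# per-atom chi / eta looked up by species label
.atom_params <- function(system, params) {
  idx <- match(system$species, names(params$chi))
  if (anyNA(idx)) {
    stop("no FQ parameters for species: ",
         paste(unique(system$species[is.na(idx)]), collapse = ", "))
  }
  list(chi = unname(params$chi[idx]), eta = unname(params$eta[idx]))
}

# pairwise distance matrix in bohr
.distance_matrix_bohr <- function(coords_ang) {
  unname(as.matrix(stats::dist(coords_ang))) * .ANG2BOHR
}

# kernel from a precomputed distance matrix (bohr) and per-atom eta
.kernel_from_dist <- function(rmat, eta, kernel) {
  n <- length(eta)
  if (n == 1L) return(matrix(eta, 1, 1))
  if (kernel == "ohno") {
    ebar <- outer(eta, eta, `+`) / 2
    J <- ebar / sqrt(1 + ebar^2 * rmat^2)
  } else {  # bare-coulomb
    J <- 1 / rmat
    diag(J) <- 0
  }
  diag(J) <- eta
  J
}

#' Charge-charge coupling matrix of an FQ system
#'
#' Builds the symmetric interaction kernel J (a.u.): diagonal entries are
#' the atomic hardnesses eta_i; off-diagonal entries follow the Ohno form
#' `J_ij = eta_bar / sqrt(1 + eta_bar^2 r_ij^2)` with
#' `eta_bar = (eta_i + eta_j)/2` (default), which reproduces eta on the
#' diagonal and decays to the bare Coulomb `1/r` at long range.  A
#' `bare-coulomb` kernel (off-diagonal exactly `1/r`) is available for
#' cross-checks.
#'
#' @param system an [fq_system].
#' @param params an [fq_params] covering every species in the system.
#' @return symmetric n x n numeric matrix (a.u.).
#' @export
fq_kernel <- function(system, params) {
  ap <- .atom_params(system, params)
  rmat <- .distance_matrix_bohr(system$coords)
  .kernel_from_dist(rmat, ap$eta, system$kernel)
}

# potential (a.u.) at each FQ atom from a point-charge set
# charges: data.frame(q, x, y, z) with coordinates in angstrom
.point_charge_potential <- function(charges, coords_ang) {
  n <- nrow(coords_ang)
  V <- numeric(n)
  for (k in seq_len(nrow(charges))) {
    d <- sqrt((coords_ang[, 1] - charges$x[k])^2 +
              (coords_ang[, 2] - charges$y[k])^2 +
              (coords_ang[, 3] - charges$z[k])^2)
    if (any(d < .MIN_DIST_ANG)) {
      stop(sprintf("singular potential: point charge %d within %.2f angstrom of an FQ atom",
                   k, .MIN_DIST_ANG))
    }
    V <- V + charges$q[k] / (d * .ANG2BOHR)
  }
  V
}

#' Electrostatic potential of a point-charge set at the FQ atoms
#'
#' Brute-force Coulomb sum, in atomic units.
#'
#' @param charges data.frame with columns `q` (a.u.), `x`, `y`, `z`
#'   (angstrom), e.g. a [dipole_probe] placement.
#' @param system an [fq_system].
#' @return numeric vector, one potential value (a.u.) per atom.
#' @export
probe_potential <- function(charges, system) {
  .point_charge_potential(charges, system$coords)
}

# assemble and factor-solve the augmented system for one or more RHS.
# Returns list(q = n x m, lambda = g x m, residual)
.solve_augmented <- function(J, C, rhs) {
  n <- ncol(J); g <- nrow(C)
  A <- rbind(cbind(J, t(C)), cbind(C, matrix(0, g, g)))
  X <- tryCatch(solve(A, rhs),
                error = function(e) stop("degenerate geometry: augmented FQ system is singular (",
                                         conditionMessage(e), ")", call. = FALSE))
  X <- as.matrix(X)
  list(q = X[seq_len(n), , drop = FALSE],
       lambda = X[n + seq_len(g), , drop = FALSE],
       residual = max(abs(A %*% X - rhs)))
}

#' Solve for the equilibrated fluctuating charges
#'
#' Minimizes `E(q) = sum chi_i q_i + 1/2 q' J q + sum V_i q_i` subject to
#' the per-group total-charge constraints, by direct factorization of the
#' Lagrange-augmented symmetric linear system.
#'
#' @param system an [fq_system].
#' @param params an [fq_params].
#' @param potential external per-atom electrostatic potential (a.u.):
#'   either a numeric vector with one value per atom, a point-charge
#'   data.frame (columns `q`, `x`, `y`, `z`; see [probe_potential]), or
#'   `NULL` for an isolated system.
#' @return An object of class `fq_charges`: fields `charges` (a.u.),
#'   `lambda` (Lagrange multipliers per group), `energy` (total FQ energy,
#'   a.u.) and `residual` (max residual of the stationarity system).
#' @examples
#' co <- toy_molecule("diatomic")
#' p <- fq_params(chi = c(C = 0.2, O = 0.5), eta = c(C = 0.5, O = 0.6))
#' fq_solve(co, p)
#' @export
fq_solve <- function(system, params, potential = NULL) {
  ap <- .atom_params(system, params)
  n <- n_atoms(system)
  if (is.null(potential)) {
    V <- numeric(n)
  } else if (is.data.frame(potential)) {
    V <- .point_charge_potential(potential, system$coords)
  } else {
    if (length(potential) != n) {
      stop("external potential must supply one value per FQ atom (got ",
           length(potential), ", need ", n, ")")
    }
    V <- as.numeric(potential)
  }
  J <- fq_kernel(system, params)
  C <- .constraint_matrix(system)
  rhs <- c(-(ap$chi + V), system$group_charges)
  sol <- .solve_augmented(J, C, matrix(rhs, ncol = 1))
  q <- unname(drop(sol$q))
  energy <- sum(ap$chi * q) + 0.5 * sum(q * (J %*% q)) + sum(V * q)
  structure(list(charges = q, lambda = unname(drop(sol$lambda)), energy = energy,
                 residual = sol$residual, potential = V),
            class = "fq_charges")
}

#' @export
print.fq_charges <- function(x, ...) {
  cat(sprintf("FQ charge solution: %d atoms, energy %.10g a.u., residual %.2e\n",
              length(x$charges), x$energy, x$residual))
  print(round(x$charges, 8))
  invisible(x)
}

#' Probe-molecule interaction energy at the FQ level
#'
#' Equilibrates the FQ charges in the electrostatic potential of a
#' point-charge probe and returns the interaction energy
#' `E(relaxed in probe field, incl. FQ-probe Coulomb term) - E(isolated)`,
#' in kcal/mol.  By the variational character of the charge solution this
#' relaxed interaction energy is always below (or equal to) the energy
#' obtained with charges frozen at their isolated values.
#'
#' @param system an [fq_system].
#' @param params an [fq_params].
#' @param probe point-charge data.frame (columns `q`, `x`, `y`, `z`), e.g.
#'   a [dipole_probe] placement.
#' @return interaction energy in kcal/mol.
#' @export
fq_interaction_energy <- function(system, params, probe) {
  if (!all(is.finite(as.matrix(probe[, c("q", "x", "y", "z")])))) {
    stop("probe charges and positions must be finite")
  }
  iso <- fq_solve(system, params, potential = NULL)
  per <- fq_solve(system, params, potential = probe)
  (per$energy - iso$energy) * .HARTREE2KCAL
}

#' Static polarizability tensor of an FQ system
#'
#' Computes the 3x3 static dipole polarizability from the analytic linear
#' response of the constrained charges to a uniform electric field:
#' `alpha_ab = sum_i r_(i,a) dq_i/dF_b`, obtained by solving the augmented
#' system once per field direction.  For a strictly planar molecule the
#' out-of-plane response vanishes identically: a uniform field normal to
#' the plane shifts the site potentials by a group-wise constant, which is
#' absorbed by the charge-conservation constraint.
#'
#' @param system a neutral [fq_system] (all group charges 0).
#' @param params an [fq_params].
#' @param alpha_mol optional reference molecular isotropic polarizability
#'   (a.u.) used to report a relative error.
#' @param alpha_bulk optional reference bulk isotropic polarizability
#'   (a.u.); compare against the tensor of a multi-molecule cluster built
#'   with [merge_systems].
#' @return An object of class `fq_polarizability`: `tensor` (a.u.),
#'   `alpha_iso` (trace/3), `eigenvalues`, and relative errors versus any
#'   supplied targets.
#' @export
fq_polarizability <- function(system, params, alpha_mol = NULL, alpha_bulk = NULL) {
  if (any(abs(system$group_charges) > 1e-12)) {
    stop("polarizability is defined here for neutral systems only")
  }
  ap <- .atom_params(system, params)
  rmat <- .distance_matrix_bohr(system$coords)
  J <- .kernel_from_dist(rmat, ap$eta, system$kernel)
  C <- .constraint_matrix(system)
  R <- system$coords * .ANG2BOHR               # n x 3, bohr
  g <- nrow(C)
  rhs <- rbind(R, matrix(0, g, 3))             # dV_i/dF_b = -r_(i,b)
  sol <- .solve_augmented(J, C, rhs)
  alpha <- t(R) %*% sol$q                      # 3 x 3, a.u.
  alpha <- (alpha + t(alpha)) / 2
  ev <- eigen(alpha, symmetric = TRUE, only.values = TRUE)$values
  iso <- sum(diag(alpha)) / 3
  out <- list(tensor = alpha, alpha_iso = iso, eigenvalues = ev,
              alpha_mol = alpha_mol, alpha_bulk = alpha_bulk,
              rel_err_mol = if (is.null(alpha_mol)) NULL else abs(iso - alpha_mol) / abs(alpha_mol),
              rel_err_bulk = if (is.null(alpha_bulk)) NULL else abs(iso - alpha_bulk) / abs(alpha_bulk))
  class(out) <- "fq_polarizability"
  out
}

#' @export
print.fq_polarizability <- function(x, ...) {
  cat("FQ static polarizability (a.u.)\n")
  print(round(x$tensor, 6))
  cat(sprintf("alpha_iso = %.6f; eigenvalues: %s\n", x$alpha_iso,
              paste(sprintf("%.6f", x$eigenvalues), collapse = ", ")))
  if (!is.null(x$rel_err_mol)) {
    cat(sprintf("alpha_mol target %.4f -> relative error %.3f%%\n",
                x$alpha_mol, 100 * x$rel_err_mol))
  }
  if (!is.null(x$rel_err_bulk)) {
    cat(sprintf("alpha_bulk target %.4f -> relative error %.3f%%\n",
                x$alpha_bulk, 100 * x$rel_err_bulk))
  }
  invisible(x)
}
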