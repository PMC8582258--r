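# Independent oracles and shared fixtures.  Everything here re-derives
# the physics element by element (scalar Ohno formula, brute-force
# Coulomb sums, grid minimization, finite differences) without touching
# the package's assembled linear-algebra path.

ANG2BOHR <- 1.8897261254578281
HARTREE2KCAL <- 627.5094740631

water_params <- function() {
  fq_params(chi = c(O = 0.50, H = 0.15), eta = c(O = 0.60, H = 0.50))
}

nitrile_params <- function() {
  fq_params(chi = c(C = 0.25, N = 0.55), eta = c(C = 0.48, N = 0.62))
}

# scalar Ohno coupling between two atoms (distances in angstrom)
oracle_ohno <- function(eta_i, eta_j, r_ang) {
  eb <- (eta_i + eta_j) / 2
  r <- r_ang * ANG2BOHR
  eb / sqrt(1 + eb^2 * r^2)
}

# element-by-element kernel assembly
oracle_kernel <- function(system, params) {
  n <- nrow(system$coords)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        J[i, j] <- params$eta[[system$species[i]]]
      } else {
        r <- sqrt(sum((system$coords[i, ] - system$coords[j, ])^2))
        J[i, j] <- oracle_ohno(params$eta[[system$species[i]]],
                               params$eta[[system$species[j]]], r)
      }
    }
  }
  J
}

# brute-force potential of a point-charge table at the system's atoms
oracle_potential <- function(probe, system) {
  vapply(seq_len(nrow(system$coords)), function(i) {
    v <- 0
    for (k in seq_len(nrow(probe))) {
      r <- sqrt(sum((system$coords[i, ] - c(probe$x[k], probe$y[k], probe$z[k]))^2))
      v <- v + probe$q[k] / (r * ANG2BOHR)
    }
    v
  }, numeric(1))
}

# total FQ energy of an explicit charge vector (a.u.)
oracle_energy <- function(system, params, q, V = NULL) {
  J <- oracle_kernel(system, params)
  chi <- vapply(system$species, function(s) params$chi[[s]], numeric(1))
  if (is.null(V)) V <- rep(0, length(q))
  sum(chi * q) + 0.5 * sum(q * (J %*% q)) + sum(V * q)
}

# brute-force interaction energy of a neutral 3-atom molecule with a
# probe: successive grid refinement of E(q) over the two free charges
# (the third is fixed by neutrality), for both the isolated molecule and
# the molecule in the probe potential.
oracle_grid_interaction <- function(system, params, probe) {
  stopifnot(nrow(system$coords) == 3)
  J <- oracle_kernel(system, params)
  chi <- vapply(system$species, function(s) params$chi[[s]], numeric(1))
  Vp <- oracle_potential(probe, system)

  grid_min <- function(V) {
    c1 <- 0; c2 <- 0; half <- 2.5; step <- 0.05
    for (stage in 1:4) {
      g <- expand.grid(q1 = seq(c1 - half, c1 + half, by = step),
                       q2 = seq(c2 - half, c2 + half, by = step))
      Q <- rbind(g$q1, g$q2, -g$q1 - g$q2)
      E <- colSums(chi * Q) + 0.5 * colSums(Q * (J %*% Q)) + colSums(V * Q)
      i <- which.min(E)
      c1 <- g$q1[i]; c2 <- g$q2[i]
      half <- 2 * step; step <- step / 25
    }
    list(e = E[i], q = c(c1, c2, -c1 - c2))
  }
  (grid_min(Vp)$e - grid_min(rep(0, 3))$e) * HARTREE2KCAL
}

# finite-field polarizability via central differences on the solved
# charges (field in a.u.; site potential V_i = -F . r_i, r in bohr)
oracle_finite_field_alpha <- function(system, params, field = 1e-4) {
  R <- system$coords * ANG2BOHR
  alpha <- matrix(0, 3, 3)
  for (b in 1:3) {
    Fv <- c(0, 0, 0); Fv[b] <- field
    qp <- fq_solve(system, params, potential = -(R %*% Fv))$charges
    qm <- fq_solve(system, params, potential = (R %*% Fv))$charges
    dq <- (qp - qm) / (2 * field)
    alpha[, b] <- colSums(R * dq)
  }
  alpha
}

# random neutral cluster with a minimum-distance guarantee
random_cluster <- function(n, species_pool = c("O", "H", "C"), seed,
                           spread = 3, min_dist = 0.8) {
  set.seed(seed)
  repeat {
    co <- matrix(runif(n * 3, -spread, spread), n, 3)
    if (n == 1 || min(dist(co)) >= min_dist) break
  }
  fq_system(sample(species_pool, n, replace = TRUE), co)
}

random_cluster_params <- function() {
  fq_params(chi = c(O = 0.55, H = 0.12, C = 0.30),
            eta = c(O = 0.58, H = 0.45, C = 0.50))
}
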