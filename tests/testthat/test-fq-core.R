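# Electronegativity-equalization core: kernel, constrained charge
# solver, interaction energies, polarizability.

test_that("kernel reproduces hardness on the diagonal and Coulomb asymptotics", {
  one <- fq_system("O", matrix(c(0, 0, 0), 1))
  p <- random_cluster_params()
  expect_equal(fq_kernel(one, p), matrix(p$eta[["O"]], 1, 1))

  r_bohr <- 50
  two <- fq_system(c("O", "H"), rbind(c(0, 0, 0), c(0, 0, r_bohr / ANG2BOHR)))
  J <- fq_kernel(two, p)
  expect_true(isSymmetric(J))
  expect_lt(abs(J[1, 2] - 1 / r_bohr) / (1 / r_bohr), 1e-3)

  bare <- fq_system(c("O", "H"), rbind(c(0, 0, 0), c(0, 0, r_bohr / ANG2BOHR)),
                    kernel = "bare-coulomb")
  expect_equal(fq_kernel(bare, p)[1, 2], 1 / r_bohr)
})

test_that("kernel matches element-by-element evaluation on a 3-atom system", {
  w <- toy_molecule("water")
  p <- water_params()
  expect_equal(fq_kernel(w, p), oracle_kernel(w, p), tolerance = 1e-14)
})

test_that("kernel construction rejects bad inputs", {
  w <- toy_molecule("water")
  expect_error(fq_kernel(w, fq_params(chi = c(O = 0.5), eta = c(O = 0.6))),
               "no FQ parameters for species: H")
  expect_error(fq_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.01))),
               "degenerate geometry")
})

test_that("symmetric homonuclear diatomic carries no charge", {
  s <- fq_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  p <- fq_params(chi = c(H = 0.3), eta = c(H = 0.5))
  sol <- fq_solve(s, p)
  expect_equal(sol$charges, c(0, 0), tolerance = 1e-14)
  expect_equal(sol$energy, 0, tolerance = 1e-14)
})

test_that("heteronuclear diatomic matches the closed-form two-site solution", {
  for (case in list(c(0.1, 0.6, 0.4, 0.7, 1.2), c(0.3, 0.35, 0.55, 0.5, 2.0),
                    c(0.0, 1.0, 0.2, 0.9, 3.5))) {
    chi1 <- case[1]; chi2 <- case[2]; eta1 <- case[3]; eta2 <- case[4]; d <- case[5]
    s <- fq_system(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, d)))
    p <- fq_params(chi = c(C = chi1, O = chi2), eta = c(C = eta1, O = eta2))
    J12 <- oracle_ohno(eta1, eta2, d)
    q1 <- (chi2 - chi1) / (eta1 + eta2 - 2 * J12)
    sol <- fq_solve(s, p)
    expect_equal(sol$charges, c(q1, -q1), tolerance = 1e-12)
    expect_equal(sol$energy, -0.5 * (chi2 - chi1)^2 / (eta1 + eta2 - 2 * J12),
                 tolerance = 1e-12)
  }
})

test_that("group charge sums hit their constraints to 1e-10 for any input", {
  p <- random_cluster_params()
  for (seed in 1:5) {
    set.seed(seed)
    s <- random_cluster(6, seed = seed)
    # split into two molecules with net charges 0 and +1
    s2 <- fq_system(s$elements, s$coords, groups = rep(1:2, each = 3),
                    group_charges = c(0, 1))
    V <- rnorm(6)
    sol <- fq_solve(s2, p, potential = V)
    sums <- tapply(sol$charges, s2$groups, sum)
    expect_equal(as.numeric(sums), c(0, 1), tolerance = 1e-10)
    expect_lt(sol$residual, 1e-8)
  }
})

test_that("the solver energy is a variational minimum over feasible charges", {
  p <- random_cluster_params()
  s <- random_cluster(5, seed = 42)
  set.seed(99)
  V <- rnorm(5, sd = 0.05)
  sol <- fq_solve(s, p, potential = V)
  for (i in 1:20) {
    q <- rnorm(5)
    q <- q - mean(q)  # feasible: neutral
    expect_gte(oracle_energy(s, p, q, V), sol$energy - 1e-12)
  }
  # and perturbations around the solution only raise the energy
  for (i in 1:5) {
    dq <- rnorm(5, sd = 1e-3); dq <- dq - mean(dq)
    expect_gte(oracle_energy(s, p, sol$charges + dq, V), sol$energy - 1e-14)
  }
})

test_that("solver validates the external potential", {
  w <- toy_molecule("water")
  expect_error(fq_solve(w, water_params(), potential = c(0.1, 0.2)),
               "one value per FQ atom")
})

test_that("interaction energy decays to zero at large distance", {
  w <- toy_molecule("water")
  p <- water_params()
  e <- fq_interaction_energy(w, p, dipole_probe(c(0, 0, 1e3)))
  expect_lt(abs(e), 1e-6)
})

test_that("relaxed interaction energy is bounded by the frozen-charge energy", {
  p <- water_params()
  w <- toy_molecule("water")
  q_iso <- fq_solve(w, p)$charges
  set.seed(7)
  for (i in 1:10) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    pr <- dipole_probe(u * runif(1, 3, 8), rnorm(3))
    relaxed <- fq_interaction_energy(w, p, pr)
    frozen <- sum(probe_potential(pr, w) * q_iso) * HARTREE2KCAL
    expect_lte(relaxed, frozen + 1e-10)
  }
})

test_that("interaction energy matches brute-force grid minimization", {
  p <- water_params()
  w <- toy_molecule("water")
  pr <- dipole_probe(c(0, 0, 4), c(0, 0, 1))
  expect_equal(fq_interaction_energy(w, p, pr),
               oracle_grid_interaction(w, p, pr), tolerance = 1e-6)
})

test_that("a probe sitting on an FQ atom is rejected", {
  w <- toy_molecule("water")
  expect_error(fq_interaction_energy(w, water_params(),
                                     dipole_probe(c(0, 0, 0.5), c(0, 0, 1))),
               "singular potential")
})

test_that("interaction energy is invariant under rigid translation", {
  p <- water_params()
  w <- toy_molecule("water")
  pr <- dipole_probe(c(0, 0, 4), c(0, 1, 1))
  e0 <- fq_interaction_energy(w, p, pr)
  t <- c(13.2, -4.5, 7.8)
  wt <- fq_system(w$elements, sweep(w$coords, 2, t, `+`))
  prt <- pr; prt[, c("x", "y", "z")] <- prt[, c("x", "y", "z")] + rep(t, each = 2)
  expect_equal(fq_interaction_energy(wt, p, prt), e0, tolerance = 1e-10)
})

test_that("diatomic polarizability matches the closed form", {
  d_ang <- 1.4; d <- d_ang * ANG2BOHR
  s <- fq_system(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, d_ang)))
  p <- fq_params(chi = c(C = 0.2, O = 0.5), eta = c(C = 0.45, O = 0.62))
  J12 <- oracle_ohno(0.45, 0.62, d_ang)
  a <- fq_polarizability(s, p)
  expect_equal(a$tensor[3, 3], d^2 / (0.45 + 0.62 - 2 * J12), tolerance = 1e-12)
  expect_equal(max(abs(a$tensor[1:2, ])), 0, tolerance = 1e-14)
})

test_that("planar molecules have exactly zero out-of-plane polarizability", {
  a <- fq_polarizability(toy_molecule("water"), water_params())
  expect_lt(min(abs(a$eigenvalues)), 1e-8)
  expect_true(isSymmetric(a$tensor, tol = 1e-8))
})

test_that("analytic polarizability matches finite-field differentiation", {
  p <- random_cluster_params()
  for (seed in c(3, 17, 31)) {
    s <- random_cluster(5, seed = seed)
    a <- fq_polarizability(s, p)
    expect_equal(a$tensor, oracle_finite_field_alpha(s, p), tolerance = 1e-6)
  }
})

test_that("rotating the system applies a similarity transform to alpha", {
  p <- random_cluster_params()
  s <- random_cluster(4, seed = 5)
  a0 <- fq_polarizability(s, p)$tensor
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sr <- fq_system(s$elements, s$coords %*% t(R), species = s$species)
  ar <- fq_polarizability(sr, p)$tensor
  expect_equal(ar, R %*% a0 %*% t(R), tolerance = 1e-10)
})

test_that("polarizability requires neutral groups", {
  s <- fq_system(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.2)),
                 group_charges = 1)
  expect_error(fq_polarizability(s, random_cluster_params()), "neutral")
})
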