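---
title: "Parametrizing fluctuating-charge solvent models and analysing solvatochromic shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametrizing fluctuating-charge solvent models and analysing solvatochromic shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluqfit)
```

## The model

In a fluctuating-charge (FQ) force field every classical atom carries a
charge $q_i$ that is not fixed but equilibrates according to the
electronegativity-equalization principle.  The energy of a charge
configuration is

$$E(\mathbf q) \;=\; \sum_i \chi_i q_i \;+\; \tfrac12 \mathbf q^\top
\mathbf J\, \mathbf q \;+\; \sum_i V_i q_i,$$

where $\chi_i$ is the electronegativity of atom $i$ (charge flows from
low to high $\chi$), the diagonal of $\mathbf J$ holds the chemical
hardnesses $\eta_i$ (resistance to charge flow), and $V_i$ is any
external electrostatic potential -- here the potential of a point-charge
probe, later the potential of a quantum-mechanical solute in an
embedding calculation.  Minimizing $E$ subject to one charge-conservation
constraint per molecule ($\sum_{i \in m} q_i = Q_m$, so charge never
flows between molecules) is a linear problem; `fq_solve()` factorizes the
Lagrange-augmented symmetric system directly, which at solvent-molecule
sizes is both exact and cheap.  The returned energy is stationary, and
the solution is variational: any other feasible charge vector has higher
energy, which also bounds relaxed interaction energies from above by
their frozen-charge counterparts.

For the off-diagonal couplings we use the Ohno form
$$J_{ij} = \frac{\bar\eta_{ij}}{\sqrt{1 + \bar\eta_{ij}^2 r_{ij}^2}},
\qquad \bar\eta_{ij} = \tfrac12 (\eta_i + \eta_j),$$
(atomic units) which interpolates smoothly between the hardness on the
diagonal and the bare Coulomb $1/r$ at long range.  This choice of
kernel is conventional in the charge-equilibration literature; a
`bare-coulomb` option is kept for cross-checks.  Internally everything
is in atomic units (hartree, bohr); the user interface accepts angstrom
and reports scan energies in kcal/mol and excitation energies in eV.

Because the charges respond linearly to a uniform field, the static
dipole polarizability follows analytically:
$\alpha_{ab} = \sum_i r_{i,a}\, \partial q_i / \partial F_b$, one extra
solve per field direction (`fq_polarizability()`).  Two structural
consequences are worth knowing.  First, within a neutral molecule only
*differences* of $\chi$ matter -- a global shift of all
electronegativities is a gauge that leaves charges, energies and
polarizabilities unchanged.  Second, a strictly planar molecule has
exactly zero out-of-plane polarizability: a field normal to the plane
shifts all site potentials by a constant, which the charge-conservation
constraint absorbs.  This is a genuine limitation of charge-only
polarizable models (atomic-dipole extensions lift it) and the package
treats it as a property to verify, not to hide.

## The reference scan

The fitting data are interaction-energy curves between the solvent
molecule and a dipolar probe: two point charges of $\pm 1$ a.u.
separated by 1 angstrom (`dipole_probe()`).  The probe midpoint is swept
along user-chosen symmetry axes at distances 2.5--10.0 angstrom in steps
of 0.25 (31 placements per axis; `generate_scan()`).  Distances are
measured from the molecular center of mass by default, with a per-axis
anchor override for atom-anchored scans, and the convention is stored in
the table so the weights below are reproducible.  Axes are deliberately
user-specified -- automatic point-group detection is out of scope --
but `principal_axes()` proposes candidates from the inertia tensor.
With four axes the default grid gives 124 placements; real
parametrizations use a few axes and orientations per solvent, on the
order of 150--250 points.

## Loss and optimization

The loss is a distance-weighted mean squared error over the scan,

$$\xi^2 = \frac1N \sum_{i=1}^{N} w_i \left(E^{\mathrm{REF}}_{\mathrm{int},i}
 - E^{\mathrm{FQ}}_{\mathrm{int},i}\right)^2, \qquad w_i = 1/d_i,$$

with $d_i$ the solvent--probe distance in angstrom (`fq_loss()`).  We
normalize by $N$ (not by $\sum_i w_i$), so refits on different grids
remain comparable; this is documented because the two conventions differ
by a constant factor.

The map from parameters to energies runs through a constrained linear
solve, so $\xi^2$ is non-convex in $(\boldsymbol\chi, \boldsymbol\eta)$
and has several local minima; gradient descent from one starting point
is unreliable.  `fq_fit()` therefore uses a real-coded genetic algorithm
with every parameter restrained to $[0,1]$ a.u.: blend (BLX-$\alpha$)
crossover, bounded Gaussian mutation, binary tournament selection and a
single elite, 100 individuals per population and 100 generations, with
20 independent restarts by default -- 2000 random starting points in
parameter space.  All rates, bounds and counts live in
`fq_ga_control()`; every stochastic entry point takes an explicit seed
and is bit-for-bit reproducible.  One refinement is ours: after each
restart the best candidate is polished by bounded L-BFGS-B on the same
loss (`polish = TRUE`).  The loss is smooth inside the box, so this
memetic step reliably drives noise-free synthetic recoveries from the
$10^{-2}$ plateau a pure GA reaches down to $10^{-6}$ and below, at
negligible cost; it can be switched off to study the bare GA.

Because of the $\chi$ gauge, "recovering the truth" on synthetic data
means reproducing its energies and polarizabilities, not its raw
parameter values; the recovery checks in the test suite are phrased that
way.

## Validation and selection

The GA returns one best candidate per restart, typically several with
near-identical losses.  Two physical screens pick the optimal set
(`select_optimal()`):

1. **Electronegativity ordering** (`check_ordering()`): fitted $\chi$
   must increase strictly along each declared row of the periodic table
   (e.g. C < N < O).  Hydrogen is exempt by default since it is not in
   the same period; the chains are configurable.  Violators are
   rejected outright.
2. **Polarizability agreement** (`check_polarizability()`): the
   isotropic $\alpha$ of the molecule -- and of a user-supplied
   multi-molecule cluster when a bulk target is given -- must match the
   reference values within a tolerance (default 10%).

Among survivors the lowest loss wins; ties break by smaller molecular-
$\alpha$ error, then lexicographic parameter order, so the election is
deterministic and invariant under permutation of the candidates.  The
composite rule is a package choice: the protocol asks for
simultaneously lowest loss and lowest $\alpha$ errors without defining
a combination, and "filter on $\alpha$, then rank by loss" keeps the
two criteria separable and auditable.  The bulk reference is defined
operationally as the isotropic $\alpha$ of a cluster geometry under the
same FQ model (`merge_systems()`), with the target value supplied
externally.

## Snapshots and droplets

For condensed-phase spectra the solvent configurations come from
dynamics.  `snapshot_times()` samples a trajectory window uniformly with
the first frame one interval after the window start, so a 2 ns window at
20 ps spacing yields exactly 100 frames.  `cut_sphere()` clips each
frame to a solute-centered droplet (radii of 20--25 angstrom are
typical): solvent molecules are re-wrapped whole by the minimum-image
convention around the solute center of mass (orthorhombic boxes only),
then retained when their center of mass lies within the radius.  The
center-of-mass criterion avoids dangling boundary molecules; an
`any-atom` criterion is selectable.  Clipping is idempotent, monotone in
the radius, and never splits a molecule.  Readers exist for multi-frame
XYZ, GRO (nm converted to angstrom) and PDB; `write_droplet()` emits the
droplet XYZ plus a JSON sidecar with the molecule grouping the FQ layer
needs.

## Ensembles, shifts and band shapes

Per-snapshot excitation energies computed in the linear-response (LR)
and corrected-linear-response (cLR) regimes are combined with the
frozen-density energy $\omega_0$ by summing both shifts:
$\omega_0 + (\mathrm{LR}-\omega_0) + (\mathrm{cLR}-\omega_0) =
\mathrm{LR} + \mathrm{cLR} - \omega_0$ (`clr2_energy()`).

Solvatochromic shifts are $\Delta E = E^{\mathrm{solv}} -
E^{\mathrm{ref}}$ with the ensemble mean as the default
$E^{\mathrm{solv}}$ estimator (robust at around 100 snapshots; the
fitted band center is selectable).  Negative shifts are red, positive
blue; the reference is the vacuum energy, or a reference solvent such as
dioxane when no gas-phase value exists.

`band_shape()` turns an ensemble into an absorption band: each energy
contributes a unit-area Gaussian of width $\sigma_0$ (default 0.05 eV on
a 0.001 eV grid; both configurable) and a single Gaussian is
least-squares fitted to the sum, reporting the full width at half
maximum $\mathrm{fwhm} = 2\sqrt{2\ln 2}\,\sigma$ -- the direct measure
of solvent-induced band broadening.  The fit uses
Levenberg--Marquardt (`minpack.lm`), which unlike Gauss--Newton also
converges on exactly-Gaussian (zero-residual) inputs; when all sticks
coincide the band is the broadening Gaussian itself and the fwhm is
$2\sqrt{2\ln 2}\,\sigma_0$ analytically.  `polarity_trend()` regresses
per-solvent quantities against the relative polarity $\phi$ and flags
outliers by studentized residuals (threshold 3), since strongly
hydrogen-bonding solvents often fall off the linear polarity trend; on a
numerically exact line the leave-one-out statistics are pure rounding
noise and nothing is flagged.

## The synthetic-data generators, and what passing tests mean

Real parametrizations consume quantum-chemistry reference energies and
dynamics trajectories; the package ships generators so every stage is
testable without either.  `make_reference_scan()` produces scan tables
whose reference energies come from a *known* FQ truth plus optional
i.i.d. Gaussian noise -- so the loss at the truth is exactly zero for
noise-free data and has expectation $\bar w \sigma^2$ under noise.
`make_solvated_frame()` packs rigid toy molecules (fixed geometries:
a CO-like diatomic, a bent water-like triatomic, a linear nitrile-like
triatomic) at random positions and orientations with a minimum
center-of-mass separation of 3 angstrom.  `make_excitation_ensemble()`
draws Gaussian energies mimicking snapshot scatter.  All generators are
pure functions of their arguments and a mandatory seed.

These fixtures emulate the *structure* of real data, not its physics:
synthetic scans are exactly representable by the FQ model, whereas
quantum-chemical references contain out-of-plane polarization, charge
penetration and exchange effects the model cannot express, so real fits
plateau at a finite loss where synthetic recoveries go to zero.
Likewise the Gaussian ensembles carry no vibronic or non-Gaussian
structure.  Passing tests therefore demonstrate the correctness of the
machinery -- solver, loss, optimizer, selection, band analysis -- not
the accuracy of FQ for any particular solvent.

## Numerical choices

* Units: atomic units internally; angstrom at the interface
  (1 angstrom = 1.8897261255 bohr), kcal/mol for scan energies
  (1 hartree = 627.5094741 kcal/mol), eV for excitation energies.
* Linear solves: dense direct factorization of the augmented system;
  iterative methods are pointless at these sizes.  A singular augmented
  system (degenerate geometry) is a hard error.
* Geometry guards: interatomic or probe--atom distances below 0.1
  angstrom are rejected.
* Charge conservation holds to $10^{-10}$ a.u. and the stationarity
  residual to $10^{-8}$ by construction of the direct solve; both are
  checked in the test suite, along with agreement between analytic and
  finite-field polarizabilities to $10^{-6}$ a.u.
* Hardness positivity: the GA box is $[0,1]$ with a lower bound of
  $10^{-4}$ on $\eta$ so every candidate defines a valid model.
* Problem sizes in the shipped tests: 3-atom toy molecules, 124-point
  scans, GA configurations of 2--4 restarts with populations of 30--50
  over 25--50 generations, and $10^4$-sample ensembles -- small enough
  to run everywhere, large enough that the recovery and fwhm criteria
  are meaningful.

## Limitations

* No out-of-plane polarization for planar molecules (inherent to
  charge-only models).
* No Pauli repulsion, dispersion or charge transfer between molecules;
  interaction energies are purely electrostatic + polarization.
* Orthorhombic boxes only in the periodic re-wrapping; triclinic cells
  are out of scope.
* The package performs no quantum-chemistry or dynamics itself: it
  builds the reference geometry, fits and validates parameters, and
  analyses exported excitation-energy tables.

## A worked miniature

```{r example, eval = FALSE}
water <- toy_molecule("water")
truth <- fq_params(chi = c(O = 0.50, H = 0.15), eta = c(O = 0.60, H = 0.50))
scan <- make_reference_scan(water, truth, seed = 1)        # 124 points
fit <- fq_fit(scan, water,
              control = fq_ga_control(pop_size = 50, restarts = 4,
                                      generations = 50),
              seed = 2)
summary(fit)
ref <- validation_reference(order = list("O"), exempt = "H",
                            alpha_mol = fq_polarizability(water, truth)$alpha_iso)
select_optimal(fit, water, ref)
```
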