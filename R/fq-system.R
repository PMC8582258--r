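#' Fluctuating-charge system
#'
#' An FQ system is the set of classical atoms that carry fluctuating
#' charges: element symbols, Cartesian coordinates, a partition of the
#' atoms into charge-constraint groups (normally one group per solvent
#' molecule, each with fixed total charge, so no intermolecular charge
#' transfer occurs), and the choice of charge-charge interaction kernel.
#'
#' @param elements character vector of element symbols (used for masses).
#' @param coords numeric n x 3 matrix of coordinates in angstrom.
#' @param groups integer vector of length n assigning each atom to a
#'   constraint group, or a list of atom-index vectors partitioning the
#'   atoms. Default: all atoms in one group.
#' @param group_charges total charge (a.u.) of each group; default 0
#'   (neutral molecules).
#' @param species species labels used for parameter lookup; default the
#'   element symbols (`per-element` parametrization).
#' @param kernel charge-charge interaction kernel: `"ohno"` (default) or
#'   `"bare-coulomb"`.
#' @return An object of class `fq_system`.
#' @examples
#' water_like <- toy_molecule("water")
#' water_like$elements
#' @export
fq_system <- function(elements, coords, groups = NULL, group_charges = NULL,
                      species = elements, kernel = c("ohno", "bare-coulomb")) {
  kernel <- match.arg(kernel)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (nrow(coords) != n || ncol(coords) != 3L) {
    stop("'coords' must be an n x 3 matrix matching 'elements'")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (length(species) != n) stop("'species' must have one label per atom")
  .element_mass(elements)  # validates symbols

  if (is.null(groups)) groups <- rep(1L, n)
  if (is.list(groups)) {
    gid <- integer(n)
    for (g in seq_along(groups)) gid[groups[[g]]] <- g
    groups <- gid
  }
  groups <- as.integer(groups)
  if (length(groups) != n || any(groups < 1L) || anyNA(groups)) {
    stop("'groups' must assign every atom to a group (partition of the atom set)")
  }
  groups <- match(groups, sort(unique(groups)))  # densify ids
  ngroup <- max(groups)
  if (is.null(group_charges)) group_charges <- rep(0, ngroup)
  if (length(group_charges) != ngroup) {
    stop("'group_charges' must have one value per constraint group")
  }

  if (n > 1L) {
    dmin <- min(stats::dist(coords))
    if (dmin < .MIN_DIST_ANG) {
      stop(sprintf("degenerate geometry: atoms closer than %.2f angstrom (min %.4f)",
                   .MIN_DIST_ANG, dmin))
    }
  }

  structure(list(elements = elements, coords = coords, species = species,
                 groups = groups, group_charges = as.numeric(group_charges),
                 kernel = kernel),
            class = "fq_system")
}

#' @export
print.fq_system <- function(x, ...) {
  cat(sprintf("FQ system: %d atoms, %d constraint group(s), kernel '%s'\n",
              nrow(x$coords), max(x$groups), x$kernel))
  cat("species:", paste(unique(x$species), collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in an FQ system
#' @param system an [fq_system].
#' @return integer atom count.
#' @export
n_atoms <- function(system) nrow(system$coords)

#' Center of mass of an FQ system
#' @param system an [fq_system].
#' @return length-3 numeric vector (angstrom).
#' @export
center_of_mass <- function(system) .center_of_mass(system$elements, system$coords)

# group-constraint incidence matrix (ngroup x n)
.constraint_matrix <- function(system) {
  n <- n_atoms(system)
  g <- max(system$groups)
  C <- matrix(0, g, n)
  C[cbind(system$groups, seq_len(n))] <- 1
  C
}

#' Read / write FQ systems as JSON
#'
#' Layout: `{"elements": [...], "coords": [[x,y,z],...], "groups": [...],
#' "group_charges": [...], "species": [...], "kernel": "..."}` with
#' coordinates in angstrom.
#'
#' @param path file path.
#' @param system an [fq_system].
#' @return `read_system_json` returns an [fq_system]; the writer returns
#'   `path` invisibly.
#' @export
read_system_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- obj$coords
  if (!is.matrix(co)) co <- matrix(unlist(co), ncol = 3, byrow = TRUE)
  fq_system(elements = obj$elements,
            coords = co,
            groups = if (is.null(obj$groups)) NULL else obj$groups,
            group_charges = obj$group_charges,
            species = if (is.null(obj$species)) obj$elements else obj$species,
            kernel = if (is.null(obj$kernel)) "ohno" else obj$kernel)
}

#' @rdname read_system_json
#' @export
write_system_json <- function(system, path) {
  stopifnot(inherits(system, "fq_system"))
  jsonlite::write_json(
    list(elements = system$elements,
         coords = unname(system$coords),
         groups = system$groups, group_charges = system$group_charges,
         species = system$species, kernel = system$kernel),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Merge several FQ systems into one multi-molecule system
#'
#' Each input keeps its own constraint groups (shifted to stay distinct),
#' so charge cannot flow between the merged molecules.  Used e.g. to build
#' the multi-molecule cluster whose isotropic polarizability plays the
#' role of the bulk polarizability target during validation.
#'
#' @param systems list of [fq_system] objects (same kernel).
#' @param offsets optional list of length-3 translations (angstrom), one
#'   per system.
#' @return an [fq_system].
#' @export
merge_systems <- function(systems, offsets = NULL) {
  stopifnot(length(systems) >= 1L)
  if (is.null(offsets)) offsets <- rep(list(c(0, 0, 0)), length(systems))
  elements <- character(0); species <- character(0)
  coords <- NULL; groups <- integer(0); gq <- numeric(0); gmax <- 0L
  for (i in seq_along(systems)) {
    s <- systems[[i]]
    elements <- c(elements, s$elements)
    species <- c(species, s$species)
    coords <- rbind(coords, sweep(s$coords, 2, offsets[[i]], `+`))
    groups <- c(groups, s$groups + gmax)
    gq <- c(gq, s$group_charges)
    gmax <- gmax + max(s$groups)
  }
  fq_system(elements, coords, groups = groups, group_charges = gq,
            species = species, kernel = systems[[1]]$kernel)
}
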