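# Readers/writers for solvated configurations: multi-frame XYZ, GROMACS
# GRO (nm -> angstrom), PDB (via bio3d), and the droplet writer (XYZ plus
# a JSON sidecar with the molecule grouping for the FQ layer).

#' Read a (multi-frame) XYZ file
#'
#' @param path XYZ file; repeated `natoms / comment / atom lines` blocks
#'   are read as successive frames.
#' @return list of frames, each a list with `atoms`
#'   (data.frame `element`, `x`, `y`, `z`, angstrom) and `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame starting at line ", i)
    comment <- lines[i + 1L]
    rec <- strsplit(trimws(lines[i + 1L + seq_len(n)]), "[[:space:]]+")
    atoms <- data.frame(
      element = vapply(rec, `[`, character(1), 1L),
      x = as.numeric(vapply(rec, `[`, character(1), 2L)),
      y = as.numeric(vapply(rec, `[`, character(1), 3L)),
      z = as.numeric(vapply(rec, `[`, character(1), 4L)))
    if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
      stop("non-numeric coordinate in XYZ frame starting at line ", i)
    }
    frames[[length(frames) + 1L]] <- list(atoms = atoms, comment = comment)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames in XYZ file: ", path)
  frames
}

#' Write atoms to an XYZ file
#'
#' @param atoms data.frame with `element`, `x`, `y`, `z` (angstrom), or a
#'   [solvated_frame] (solute atoms first, then solvent).
#' @param path output path.
#' @param comment comment line.
#' @param append append as an additional frame.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(atoms, path, comment = "", append = FALSE) {
  if (inherits(atoms, "solvated_frame")) {
    atoms <- rbind(atoms$solute[, c("element", "x", "y", "z")],
                   atoms$solvent[, c("element", "x", "y", "z")])
  }
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(atoms)), comment,
               sprintf("%-3s %18.12f %18.12f %18.12f",
                       atoms$element, atoms$x, atoms$y, atoms$z)), con)
  invisible(path)
}

#' Write an embedding droplet: XYZ plus molecule-grouping sidecar
#'
#' Writes the clipped frame as XYZ (solute first) and a JSON sidecar
#' recording the solute atom count, the atom-index groups of each solvent
#' molecule (1-based into the XYZ order) and the box, so the FQ layer can
#' rebuild its per-molecule charge constraints.
#'
#' @param frame a [solvated_frame].
#' @param path_xyz,path_json output paths; the sidecar defaults to
#'   `<path_xyz>.json`.
#' @return invisible list of the two paths.
#' @export
write_droplet <- function(frame, path_xyz, path_json = paste0(path_xyz, ".json")) {
  stopifnot(inherits(frame, "solvated_frame"))
  write_xyz(frame, path_xyz,
            comment = sprintf("droplet t=%s ps", format(frame$time)))
  ns <- nrow(frame$solute)
  groups <- if (nrow(frame$solvent)) {
    unname(lapply(split(seq_len(nrow(frame$solvent)), frame$solvent$mol), `+`, ns))
  } else list()
  jsonlite::write_json(list(n_solute = ns, solvent_groups = groups,
                            box = frame$box, time = frame$time),
                       path_json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(xyz = path_xyz, json = path_json))
}

#' Assemble a solvated frame from a flat atom table
#'
#' Convenience for XYZ input: the first `n_solute` atoms are the solute,
#' the remainder are solvent molecules of `solvent_size` atoms each, in
#' file order.
#'
#' @param atoms data.frame with `element`, `x`, `y`, `z`.
#' @param n_solute number of solute atoms.
#' @param solvent_size atoms per solvent molecule.
#' @param box optional box lengths (angstrom).
#' @param time frame time (ps).
#' @return a [solvated_frame].
#' @export
frame_from_atoms <- function(atoms, n_solute, solvent_size, box = NULL,
                             time = NA_real_) {
  stopifnot(n_solute >= 1, solvent_size >= 1)
  nsv <- nrow(atoms) - n_solute
  if (nsv %% solvent_size != 0) {
    stop("solvent atom count (", nsv, ") is not a multiple of 'solvent_size'")
  }
  solute <- atoms[seq_len(n_solute), c("element", "x", "y", "z")]
  solvent <- atoms[n_solute + seq_len(nsv), c("element", "x", "y", "z")]
  solvent$mol <- if (nsv) rep(seq_len(nsv / solvent_size), each = solvent_size) else integer(0)
  solvated_frame(solute, solvent, box = box, time = time)
}

#' Read a GROMACS GRO configuration
#'
#' Fixed-width parse of a single-configuration `.gro` file; positions and
#' box vectors are converted from nm to angstrom.  Molecules are grouped
#' by residue number; the solute is selected by residue name or number.
#'
#' @param path `.gro` file.
#' @param solute residue name (character) or residue number(s) (numeric)
#'   identifying the solute; default: the first residue.
#' @return a [solvated_frame].
#' @export
read_gro <- function(path, solute = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || length(lines) < 3L + natoms) {
    stop("malformed GRO file: bad atom count")
  }
  rec <- lines[2L + seq_len(natoms)]
  resno <- as.integer(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  atomname <- trimws(substr(rec, 11, 15))
  x <- as.numeric(substr(rec, 21, 28)) * 10
  y <- as.numeric(substr(rec, 29, 36)) * 10
  z <- as.numeric(substr(rec, 37, 44)) * 10
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("non-numeric coordinates in GRO file")
  boxv <- as.numeric(strsplit(trimws(lines[3L + natoms]), "[[:space:]]+")[[1]])
  box <- if (length(boxv) >= 3) boxv[1:3] * 10 else NULL
  element <- gsub("[0-9]+$", "", gsub("^[0-9]+", "", atomname))
  element <- paste0(toupper(substr(element, 1, 1)), tolower(substr(element, 2, 99)))
  # two-letter symbols only when valid; otherwise fall back to the first letter
  element <- ifelse(element %in% names(.ATOMIC_MASSES), element, substr(element, 1, 1))
  if (is.null(solute)) solute <- resno[1]
  is_solute <- if (is.character(solute)) resname %in% solute else resno %in% solute
  if (!any(is_solute)) stop("no atoms match the solute selection")
  atoms <- data.frame(element = element, x = x, y = y, z = z)
  solvent <- atoms[!is_solute, , drop = FALSE]
  solvent$mol <- if (nrow(solvent)) match(resno[!is_solute], unique(resno[!is_solute])) else integer(0)
  solvated_frame(atoms[is_solute, , drop = FALSE], solvent, box = box)
}

#' Read a PDB file as a solvated frame
#'
#' Thin wrapper over [bio3d::read.pdb]; molecules are grouped by residue
#' number and the solute selected by residue name or number.
#'
#' @param path PDB file.
#' @param solute residue name(s) (character) or residue number(s)
#'   (numeric); default: the first residue.
#' @return a [solvated_frame].
#' @export
read_pdb_frame <- function(path, solute = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("package 'bio3d' is required to read PDB files")
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  element <- trimws(at$elesy)
  blank <- !nzchar(element)
  element[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  atoms <- data.frame(element = element, x = at$x, y = at$y, z = at$z)
  resno <- at$resno
  if (is.null(solute)) solute <- resno[1]
  is_solute <- if (is.character(solute)) at$resid %in% solute else resno %in% solute
  if (!any(is_solute)) stop("no atoms match the solute selection")
  solvent <- atoms[!is_solute, , drop = FALSE]
  solvent$mol <- if (nrow(solvent)) match(resno[!is_solute], unique(resno[!is_solute])) else integer(0)
  solvated_frame(atoms[is_solute, , drop = FALSE], solvent, box = NULL)
}
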