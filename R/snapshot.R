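# Preparation of embedding inputs from solvated configurations: snapshot
# cadence along a trajectory and solute-centered sphere clipping.

#' Snapshot extraction times
#'
#' Uniform sampling of a trajectory window: the first snapshot falls one
#' interval after the window start, so a 2 ns window sampled every 20 ps
#' yields exactly 100 frames.
#'
#' @param window_length length of the sampling window (ps).
#' @param interval sampling interval (ps), > 0.
#' @param window_start start of the window (ps), default 0.
#' @return sorted numeric vector of frame times (ps).
#' @examples
#' length(snapshot_times(2000, 20))  # 100
#' @export
snapshot_times <- function(window_length, interval, window_start = 0) {
  stopifnot(.is_number(window_length), .is_number(interval), .is_number(window_start))
  if (interval <= 0) stop("'interval' must be > 0")
  if (window_length <= 0) stop("'window_length' must be > 0")
  n <- floor(window_length / interval + 1e-9)
  if (n < 1L) stop("empty schedule: interval exceeds the sampling window")
  window_start + interval * seq_len(n)
}

#' Solvated frame
#'
#' One configuration of a solute surrounded by whole solvent molecules,
#' optionally periodic in an orthorhombic box.
#'
#' @param solute data.frame with columns `element`, `x`, `y`, `z`
#'   (angstrom); must be nonempty.
#' @param solvent data.frame with columns `element`, `x`, `y`, `z`, `mol`
#'   (integer molecule id); may have zero rows.
#' @param box orthorhombic box lengths (angstrom, length 3) or `NULL` for
#'   a non-periodic cluster.
#' @param time frame time (ps), optional.
#' @return object of class `solvated_frame`.
#' @export
solvated_frame <- function(solute, solvent = NULL, box = NULL, time = NA_real_) {
  need <- c("element", "x", "y", "z")
  stopifnot(is.data.frame(solute), all(need %in% names(solute)), nrow(solute) >= 1)
  if (is.null(solvent)) {
    solvent <- data.frame(element = character(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), mol = integer(0))
  }
  stopifnot(is.data.frame(solvent), all(c(need, "mol") %in% names(solvent)))
  if (nrow(solvent) && anyNA(solvent$mol)) {
    stop("every solvent atom must belong to exactly one molecule group")
  }
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(is.finite(box)), all(box > 0))
  }
  structure(list(solute = solute, solvent = solvent, box = box, time = time),
            class = "solvated_frame")
}

#' @export
print.solvated_frame <- function(x, ...) {
  nmol <- if (nrow(x$solvent)) length(unique(x$solvent$mol)) else 0L
  cat(sprintf("solvated frame: %d solute atoms, %d solvent molecules (%d atoms)%s\n",
              nrow(x$solute), nmol, nrow(x$solvent),
              if (is.null(x$box)) "" else sprintf(", box %.2f x %.2f x %.2f angstrom",
                                                  x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

# minimum-image shift (angstrom) bringing `delta` closest to 0
.mic_shift <- function(delta, box) -box * round(delta / box)

#' Clip a solvated frame to a solute-centered sphere
#'
#' Retains the solute and every solvent molecule whose inclusion point
#' lies within `radius` of the solute center of mass.  Before the
#' distance test each solvent molecule is re-wrapped as a whole by the
#' minimum-image convention around the solute center (orthorhombic boxes
#' only), so no molecule is ever split.  The default inclusion criterion
#' is the molecular center of mass; `"any-atom"` keeps a molecule when
#' any of its atoms falls inside the sphere.
#'
#' @param frame a [solvated_frame].
#' @param radius sphere radius (angstrom), > 0; typical droplet radii for
#'   embedding calculations are 20-25 angstrom depending on solute size.
#' @param criterion `"com"` (default) or `"any-atom"`.
#' @return the clipped [solvated_frame] (box retained).
#' @export
cut_sphere <- function(frame, radius, criterion = c("com", "any-atom")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(frame, "solvated_frame"), .is_number(radius), radius > 0)
  solute_xyz <- as.matrix(frame$solute[, c("x", "y", "z")])
  scom <- .center_of_mass(frame$solute$element, solute_xyz)
  ext <- max(sqrt(rowSums(sweep(solute_xyz, 2, scom)^2)))
  if (radius < ext) {
    warning(sprintf("radius (%.2f angstrom) is smaller than the solute extent (%.2f); solute retained anyway",
                    radius, ext))
  }
  sv <- frame$solvent
  if (!nrow(sv)) return(frame)
  keep <- logical(nrow(sv))
  for (m in unique(sv$mol)) {
    sel <- sv$mol == m
    xyz <- as.matrix(sv[sel, c("x", "y", "z")])
    com <- .center_of_mass(sv$element[sel], xyz)
    if (!is.null(frame$box)) {
      shift <- .mic_shift(com - scom, frame$box)
      xyz <- sweep(xyz, 2, shift, `+`)
      com <- com + shift
      sv[sel, c("x", "y", "z")] <- xyz
    }
    d <- if (criterion == "com") {
      sqrt(sum((com - scom)^2))
    } else {
      min(sqrt(rowSums(sweep(xyz, 2, scom)^2)))
    }
    keep[sel] <- d <= radius
  }
  solvated_frame(frame$solute, sv[keep, , drop = FALSE], box = frame$box,
                 time = frame$time)
}
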