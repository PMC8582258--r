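# Post-fit physical screening: candidate parameter sets must respect the
# periodic-table electronegativity ordering and reproduce reference
# molecular (and optionally bulk) isotropic polarizabilities; survivors
# are ranked by loss.

#' Validation reference for FQ parameter screening
#'
#' @param order list of species chains that must have strictly increasing
#'   electronegativity, e.g. `list(c("C", "N", "O"))` for second-row
#'   elements read left to right.
#' @param exempt species excluded from the ordering check (hydrogen by
#'   default: it does not sit in the same period as the heavy atoms).
#' @param alpha_mol target molecular isotropic polarizability (a.u.),
#'   optional.
#' @param alpha_bulk target bulk isotropic polarizability (a.u.),
#'   optional; checked on a user-supplied multi-molecule cluster.
#' @param tol maximum allowed relative error on the polarizabilities
#'   (default 0.10).
#' @return list of class `validation_reference`.
#' @export
validation_reference <- function(order = list(), exempt = "H",
                                 alpha_mol = NULL, alpha_bulk = NULL,
                                 tol = 0.10) {
  if (!is.list(order)) order <- list(order)
  if (!is.null(alpha_mol)) stopifnot(.is_number(alpha_mol), alpha_mol > 0)
  if (!is.null(alpha_bulk)) stopifnot(.is_number(alpha_bulk), alpha_bulk > 0)
  stopifnot(.is_number(tol), tol > 0)
  structure(list(order = order, exempt = exempt,
                 alpha_mol = alpha_mol, alpha_bulk = alpha_bulk, tol = tol),
            class = "validation_reference")
}

#' Electronegativity-ordering check
#'
#' A candidate parameter set passes when its chi values increase strictly
#' along every declared chain (atomic electronegativity grows moving right
#' along a period).  Violating pairs are enumerated.  Every fitted species
#' must appear in a chain or be explicitly exempted.
#'
#' @param params an [fq_params].
#' @param ref a [validation_reference].
#' @return list with `pass` (logical) and `violations` (data.frame of
#'   offending `(lo, hi)` species pairs).
#' @export
check_ordering <- function(params, ref) {
  species <- names(params$chi)
  covered <- unique(c(unlist(ref$order), ref$exempt))
  orphan <- setdiff(species, covered)
  if (length(orphan)) {
    stop("species missing from both the ordering chains and the exemptions: ",
         paste(orphan, collapse = ", "))
  }
  lo <- character(0); hi <- character(0)
  for (chain in ref$order) {
    chain <- chain[chain %in% species]  # only fitted species constrain
    if (length(chain) < 2L) next
    for (i in seq_len(length(chain) - 1L)) {
      if (!(params$chi[[chain[i]]] < params$chi[[chain[i + 1L]]])) {
        lo <- c(lo, chain[i]); hi <- c(hi, chain[i + 1L])
      }
    }
  }
  list(pass = length(lo) == 0L,
       violations = data.frame(lo = lo, hi = hi, stringsAsFactors = FALSE))
}

#' Polarizability-agreement check
#'
#' Computes the FQ isotropic polarizability of the molecule (and of a
#' bulk cluster, when given) and reports relative errors against the
#' reference targets.
#'
#' @param params an [fq_params].
#' @param system the neutral solvent [fq_system].
#' @param ref a [validation_reference] carrying the targets and tolerance.
#' @param bulk_system optional multi-molecule [fq_system] (see
#'   [merge_systems]) for the bulk check; required when `ref$alpha_bulk`
#'   is set.
#' @return list with `alpha_iso`, `rel_err_mol`, `rel_err_bulk` (NULL when
#'   no bulk target) and `pass`.
#' @export
check_polarizability <- function(params, system, ref, bulk_system = NULL) {
  rep_mol <- fq_polarizability(system, params, alpha_mol = ref$alpha_mol)
  rel_mol <- rep_mol$rel_err_mol
  rel_bulk <- NULL
  if (!is.null(ref$alpha_bulk)) {
    if (is.null(bulk_system)) {
      stop("an alpha_bulk target is set but no bulk cluster geometry was supplied")
    }
    rel_bulk <- fq_polarizability(bulk_system, params,
                                  alpha_bulk = ref$alpha_bulk)$rel_err_bulk
  }
  pass <- TRUE
  if (!is.null(rel_mol)) pass <- pass && rel_mol <= ref$tol
  if (!is.null(rel_bulk)) pass <- pass && rel_bulk <= ref$tol
  list(alpha_iso = rep_mol$alpha_iso, rel_err_mol = rel_mol,
       rel_err_bulk = rel_bulk, pass = pass)
}

#' Validate one candidate parameter set
#'
#' Combines the ordering and polarizability screens into a single verdict.
#'
#' @inheritParams check_polarizability
#' @return list of class `validation_verdict` with fields
#'   `ordering_pass`, `violations`, `alpha_iso`, `rel_err_mol`,
#'   `rel_err_bulk`, `accepted`.
#' @export
validate_params <- function(params, system, ref, bulk_system = NULL) {
  ord <- check_ordering(params, ref)
  pol <- check_polarizability(params, system, ref, bulk_system)
  structure(list(ordering_pass = ord$pass, violations = ord$violations,
                 alpha_iso = pol$alpha_iso, rel_err_mol = pol$rel_err_mol,
                 rel_err_bulk = pol$rel_err_bulk,
                 accepted = ord$pass && pol$pass),
            class = "validation_verdict")
}

#' @export
print.validation_verdict <- function(x, ...) {
  cat("FQ candidate validation\n")
  cat("  electronegativity ordering:", if (x$ordering_pass) "pass" else "FAIL", "\n")
  if (nrow(x$violations)) {
    cat("    violating pairs:",
        paste(sprintf("(%s, %s)", x$violations$lo, x$violations$hi), collapse = " "), "\n")
  }
  cat(sprintf("  alpha_iso = %.4f a.u.", x$alpha_iso))
  if (!is.null(x$rel_err_mol)) cat(sprintf("; alpha_mol rel. error %.2f%%", 100 * x$rel_err_mol))
  if (!is.null(x$rel_err_bulk)) cat(sprintf("; alpha_bulk rel. error %.2f%%", 100 * x$rel_err_bulk))
  cat("\n  accepted:", x$accepted, "\n")
  invisible(x)
}

#' Select the optimal parameter set among GA restarts
#'
#' Applies the physical screens to every per-restart best candidate of an
#' [fq_fit]: candidates violating the electronegativity ordering are
#' rejected outright; survivors must meet the polarizability tolerance;
#' among those, the set with the lowest loss wins.  Ties are broken by
#' the smaller molecular-polarizability error, then by lexicographic
#' parameter order, so the choice is deterministic and invariant under
#' permutation of the candidate list.
#'
#' @param fit an [fq_fit] (or a list with `restarts` and `species` of the
#'   same layout).
#' @param system the solvent [fq_system].
#' @param ref a [validation_reference].
#' @param bulk_system optional cluster geometry for the bulk check.
#' @return list of class `fq_selection`: `par` (the elected [fq_params]),
#'   `restart` (its index), and `table` (per-candidate loss, errors and
#'   verdicts).
#' @export
select_optimal <- function(fit, system, ref, bulk_system = NULL) {
  species <- fit$species
  k <- length(species)
  tab <- fit$restarts
  ncand <- nrow(tab)
  theta_cols <- c(paste0("chi.", species), paste0("eta.", species))
  cand <- lapply(seq_len(ncand), function(i) {
    .theta_to_params(as.numeric(tab[i, theta_cols]), species)
  })
  ord_pass <- vapply(cand, function(p) check_ordering(p, ref)$pass, logical(1))
  pol <- lapply(cand, function(p) check_polarizability(p, system, ref, bulk_system))
  rel_mol <- vapply(pol, function(x) if (is.null(x$rel_err_mol)) NA_real_ else x$rel_err_mol,
                    numeric(1))
  rel_bulk <- vapply(pol, function(x) if (is.null(x$rel_err_bulk)) NA_real_ else x$rel_err_bulk,
                     numeric(1))
  pol_pass <- vapply(pol, `[[`, logical(1), "pass")
  surv <- ord_pass & pol_pass
  table <- data.frame(restart = tab$restart, loss = tab$loss,
                      ordering_pass = ord_pass,
                      rel_err_mol = rel_mol, rel_err_bulk = rel_bulk,
                      accepted = surv)
  if (!any(surv)) {
    stop("no candidate parameter set survives validation; ",
         "relax the polarizability tolerance or run more GA restarts")
  }
  idx <- which(surv)
  # rank: loss, then alpha_mol error, then lexicographic parameter order
  key_mol <- ifelse(is.na(rel_mol[idx]), Inf, rel_mol[idx])
  o <- idx[do.call(order, c(list(tab$loss[idx], key_mol),
                            as.list(as.data.frame(tab[idx, theta_cols, drop = FALSE]))))]
  best <- o[1]
  structure(list(par = cand[[best]], restart = tab$restart[best], table = table),
            class = "fq_selection")
}

#' @export
print.fq_selection <- function(x, ...) {
  cat(sprintf("optimal FQ parameter set: restart %d\n", x$restart))
  print(x$par)
  cat("candidate table:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
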