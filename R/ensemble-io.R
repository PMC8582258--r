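# Ensemble CSV I/O: either component tables (snapshot_id, omega0_ev,
# lr_ev, clr_ev) or plain energy tables (snapshot_id, energy_ev), with an
# optional solvent-metadata JSON sidecar {label, phi, epsilon}.

#' Read / write excitation ensembles as CSV
#'
#' @param path CSV with columns `snapshot_id, omega0_ev, lr_ev, clr_ev`
#'   (component form; energies combined via [clr2_energy]) or
#'   `snapshot_id, energy_ev`.
#' @param meta optional path to a JSON file with fields `label`, `phi`,
#'   `epsilon`.
#' @param ensemble an [excitation_ensemble].
#' @return `read_ensemble_csv` returns an [excitation_ensemble];
#'   `write_ensemble_csv` returns `path` invisibly (writing the metadata
#'   sidecar too when `meta` is given).
#' @export
read_ensemble_csv <- function(path, meta = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty ensemble file: ", path)
  lab <- NA_character_; phi <- NA_real_; eps <- NA_real_
  if (!is.null(meta)) {
    m <- jsonlite::read_json(meta, simplifyVector = TRUE)
    if (!is.null(m$label)) lab <- m$label
    if (!is.null(m$phi)) phi <- as.numeric(m$phi)
    if (!is.null(m$epsilon)) eps <- as.numeric(m$epsilon)
  }
  comp_cols <- c("omega0_ev", "lr_ev", "clr_ev")
  if (all(comp_cols %in% names(df))) {
    excitation_ensemble(components = df, ids = df$snapshot_id,
                        label = lab, phi = phi, epsilon = eps)
  } else if ("energy_ev" %in% names(df)) {
    excitation_ensemble(energies = df$energy_ev, ids = df$snapshot_id,
                        label = lab, phi = phi, epsilon = eps)
  } else {
    stop("ensemble CSV must have columns (snapshot_id, omega0_ev, lr_ev, clr_ev) ",
         "or (snapshot_id, energy_ev)")
  }
}

#' @rdname read_ensemble_csv
#' @export
write_ensemble_csv <- function(ensemble, path, meta = NULL) {
  stopifnot(inherits(ensemble, "excitation_ensemble"))
  df <- if (!is.null(ensemble$components)) {
    cbind(data.frame(snapshot_id = ensemble$ids), ensemble$components)
  } else {
    data.frame(snapshot_id = ensemble$ids, energy_ev = ensemble$energies)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(list(label = ensemble$label, phi = ensemble$phi,
                              epsilon = ensemble$epsilon),
                         meta, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
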