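#' Fluctuating-charge parameter set
#'
#' Container for the per-species electronegativities (chi) and chemical
#' hardnesses (eta) that define a fluctuating-charge (FQ) force field.
#' These two vectors are the decision variables of the parametrization:
#' chi is the linear coefficient of the charge in the FQ energy (charge
#' flows from low to high chi), eta the quadratic self-interaction
#' coefficient (resistance to charge flow, which fixes the model
#' polarizability).
#'
#' @param chi named numeric vector of electronegativities (a.u.), one per
#'   species label.
#' @param eta named numeric vector of chemical hardnesses (a.u.), strictly
#'   positive, with the same names as `chi`.
#' @param granularity `"per-element"` when species labels are element
#'   symbols, `"per-atom-type"` when they are force-field atom types.
#' @return An object of class `fq_params`.
#' @examples
#' fq_params(chi = c(O = 0.45, H = 0.10), eta = c(O = 0.60, H = 0.48))
#' @export
fq_params <- function(chi, eta, granularity = c("per-element", "per-atom-type")) {
  granularity <- match.arg(granularity)
  if (is.null(names(chi)) || is.null(names(eta))) {
    stop("'chi' and 'eta' must be named by species")
  }
  if (!setequal(names(chi), names(eta))) {
    stop("'chi' and 'eta' must cover the same species")
  }
  eta <- eta[names(chi)]
  if (!all(is.finite(chi)) || !all(is.finite(eta))) {
    stop("all chi and eta values must be finite")
  }
  if (any(eta <= 0)) {
    stop("chemical hardness eta must be > 0 for every species (offending: ",
         paste(names(eta)[eta <= 0], collapse = ", "), ")")
  }
  structure(list(chi = chi, eta = eta, granularity = granularity),
            class = "fq_params")
}

#' @export
print.fq_params <- function(x, ...) {
  cat("FQ parameter set (", x$granularity, ")\n", sep = "")
  tab <- data.frame(species = names(x$chi), chi = unname(x$chi),
                    eta = unname(x$eta))
  print(tab, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
as.data.frame.fq_params <- function(x, ...) {
  data.frame(species = names(x$chi), chi = unname(x$chi), eta = unname(x$eta),
             stringsAsFactors = FALSE)
}

# flatten to the GA decision vector c(chi_1..chi_k, eta_1..eta_k)
.params_to_theta <- function(params, species) {
  c(params$chi[species], params$eta[species])
}

.theta_to_params <- function(theta, species,
                             granularity = "per-element") {
  k <- length(species)
  fq_params(chi = stats::setNames(theta[seq_len(k)], species),
            eta = stats::setNames(theta[k + seq_len(k)], species),
            granularity = granularity)
}

#' Read / write FQ parameter sets as JSON
#'
#' The JSON layout is `{"granularity": ..., "species": {"O": {"chi": ...,
#' "eta": ...}, ...}}`.
#'
#' @param path file path.
#' @param params an [fq_params] object.
#' @return `read_params_json` returns an [fq_params] object;
#'   `write_params_json` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$species)) stop("parameter JSON lacks a 'species' field")
  sp <- obj$species
  chi <- vapply(sp, function(s) as.numeric(s[["chi"]]), numeric(1))
  eta <- vapply(sp, function(s) as.numeric(s[["eta"]]), numeric(1))
  fq_params(chi = chi, eta = eta,
            granularity = if (is.null(obj$granularity)) "per-element" else obj$granularity)
}

#' @rdname read_params_json
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "fq_params"))
  species <- lapply(names(params$chi), function(s) {
    list(chi = unname(params$chi[[s]]), eta = unname(params$eta[[s]]))
  })
  names(species) <- names(params$chi)
  jsonlite::write_json(list(granularity = params$granularity, species = species),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
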