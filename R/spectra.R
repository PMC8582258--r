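# Solvatochromic analysis over snapshot ensembles: corrected-linear-
# response energy combination, shifts, Gaussian band shapes and fwhm,
# and polarity-trend regression.

#' Combine frozen-density, LR and cLR excitation energies
#'
#' Sums the linear-response and corrected-linear-response shifts relative
#' to the frozen-density excitation energy omega0:
#' `omega0 + (LR - omega0) + (cLR - omega0) = LR + cLR - omega0`.
#'
#' @param omega0,lr,clr numeric vectors (eV), recycled to a common length.
#' @return combined excitation energies (eV).
#' @examples
#' clr2_energy(4.00, 3.80, 3.90)  # 3.70
#' @export
clr2_energy <- function(omega0, lr, clr) {
  if (missing(omega0) || missing(lr) || missing(clr)) {
    stop("all three components (omega0, lr, clr) are required")
  }
  if (anyNA(omega0) || anyNA(lr) || anyNA(clr)) {
    stop("excitation-energy components must not contain missing values")
  }
  lr + clr - omega0
}

#' Excitation-energy ensemble
#'
#' Per-snapshot vertical excitation energies of a chromophore in a given
#' solvent, optionally with their frozen-density/LR/cLR components (in
#' which case the combined energies are formed via [clr2_energy]), plus
#' solvent metadata: label, relative polarity phi (normalized empirical
#' polarity, in `[0, 1]`) and dielectric constant epsilon.
#'
#' @param energies numeric vector of excitation energies (eV); omit when
#'   `components` is given.
#' @param components optional data.frame with columns `omega0_ev`,
#'   `lr_ev`, `clr_ev`.
#' @param ids snapshot identifiers (default `1:n`).
#' @param label solvent label, e.g. `"WTR"`.
#' @param phi relative solvent polarity in `[0, 1]` (optional).
#' @param epsilon dielectric constant (optional).
#' @return object of class `excitation_ensemble`.
#' @export
excitation_ensemble <- function(energies = NULL, components = NULL, ids = NULL,
                                label = NA_character_, phi = NA_real_,
                                epsilon = NA_real_) {
  if (is.null(energies)) {
    if (is.null(components)) stop("either 'energies' or 'components' is required")
    need <- c("omega0_ev", "lr_ev", "clr_ev")
    if (!all(need %in% names(components))) {
      stop("'components' must have columns ", paste(need, collapse = ", "))
    }
    energies <- clr2_energy(components$omega0_ev, components$lr_ev,
                            components$clr_ev)
  }
  if (!length(energies)) stop("empty excitation ensemble")
  if (!all(is.finite(energies))) stop("excitation energies must be finite")
  if (!is.na(phi) && (phi < 0 || phi > 1)) stop("'phi' must lie in [0, 1]")
  if (is.null(ids)) ids <- seq_along(energies)
  structure(list(ids = ids, energies = as.numeric(energies),
                 components = components, label = label,
                 phi = phi, epsilon = epsilon),
            class = "excitation_ensemble")
}

#' @export
print.excitation_ensemble <- function(x, ...) {
  cat(sprintf("excitation ensemble%s: %d snapshots, mean %.4f eV (sd %.4f)\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$energies), mean(x$energies), stats::sd(x$energies)))
  if (!is.na(x$phi)) cat(sprintf("  solvent polarity phi = %.3f, epsilon = %.3g\n",
                                 x$phi, x$epsilon))
  invisible(x)
}

#' @export
mean.excitation_ensemble <- function(x, ...) mean(x$energies)

.as_energies <- function(x) {
  if (inherits(x, "excitation_ensemble")) x$energies else as.numeric(x)
}

#' Solvatochromic shift of an ensemble
#'
#' `Delta E = E_solv - E_ref`, where `E_solv` is the ensemble estimate
#' (arithmetic mean of the snapshot energies by default, or the fitted
#' band center) and `E_ref` the reference excitation energy: the vacuum
#' energy for vacuo-to-solvent shifts, or the energy in a reference
#' solvent (e.g. dioxane) when no gas-phase value is available.  Negative
#' shifts are red shifts, positive are blue shifts.
#'
#' @param ensemble an [excitation_ensemble] or numeric vector (eV).
#' @param e_ref reference excitation energy (eV).
#' @param convention `"vacuum"` or `"dioxane"` (recorded in the result).
#' @param estimator `"mean"` (default) or `"band"` (center of the fitted
#'   Gaussian, see [band_shape]).
#' @param sigma0 broadening used when `estimator = "band"`.
#' @return object of class `shift_record`: `e_ref`, `e_solv`, `delta_e`
#'   (eV), `convention`, `estimator`.
#' @export
solvatochromic_shift <- function(ensemble, e_ref,
                                 convention = c("vacuum", "dioxane"),
                                 estimator = c("mean", "band"),
                                 sigma0 = 0.05) {
  convention <- match.arg(convention)
  estimator <- match.arg(estimator)
  e <- .as_energies(ensemble)
  if (!length(e)) stop("empty ensemble")
  stopifnot(.is_number(e_ref))
  e_solv <- if (estimator == "mean") mean(e) else band_shape(e, sigma0)$center
  structure(list(e_ref = e_ref, e_solv = e_solv, delta_e = e_solv - e_ref,
                 convention = convention, estimator = estimator),
            class = "shift_record")
}

#' @export
print.shift_record <- function(x, ...) {
  kind <- if (x$delta_e < 0) "red" else if (x$delta_e > 0) "blue" else "no"
  cat(sprintf("solvatochromic shift (%s reference, %s estimator): E_solv %.4f - E_ref %.4f = %+.4f eV (%s shift)\n",
              x$convention, x$estimator, x$e_solv, x$e_ref, x$delta_e, kind))
  invisible(x)
}

#' Band shape from a stick spectrum
#'
#' Builds the absorption band of a snapshot ensemble: each excitation
#' energy contributes a unit-area Gaussian of width `sigma0` on a regular
#' energy grid (the `sigma0 -> 0` limit is the stick histogram), and a
#' single Gaussian `A exp(-(x - mu)^2 / (2 s^2))` is least-squares fitted
#' to the summed spectrum.  The full width at half maximum is reported as
#' `fwhm = 2 sqrt(2 ln 2) * s`, a direct measure of the solvent-induced
#' band broadening.
#'
#' @param energies an [excitation_ensemble] or numeric vector (eV); at
#'   least 3 sticks are required for a fit unless all coincide.
#' @param sigma0 per-stick Gaussian broadening (eV), default 0.05.
#' @param grid_step energy-grid spacing (eV), default 0.001.
#' @param grid optional explicit grid (eV); default spans the sticks
#'   plus 5 broadening widths.
#' @return object of class `band_shape`: `grid`, `intensity`, `sticks`,
#'   `sigma0`, `center`, `sigma`, `fwhm`.
#' @export
band_shape <- function(energies, sigma0 = 0.05, grid_step = 0.001, grid = NULL) {
  e <- .as_energies(energies)
  stopifnot(length(e) >= 1, .is_number(sigma0), sigma0 >= 0)
  spread <- stats::sd(e)
  if (length(e) == 1L) spread <- 0
  if ((is.na(spread) || spread == 0) && sigma0 == 0) {
    stop("degenerate band: all sticks coincide and no broadening was requested")
  }
  if (spread > 0 && length(e) < 3L) {
    stop("at least 3 snapshots are required to fit a band")
  }
  # all sticks identical: the band is the broadening Gaussian itself
  if (is.na(spread) || spread == 0) {
    center <- e[1]; sigma <- sigma0
    if (is.null(grid)) grid <- seq(center - 5 * sigma0, center + 5 * sigma0, by = grid_step)
    intensity <- length(e) * stats::dnorm(grid, center, sigma0)
    fit <- NULL
  } else {
    s0 <- max(sigma0, grid_step)
    if (is.null(grid)) {
      pad <- 5 * max(s0, spread)
      grid <- seq(min(e) - pad, max(e) + pad, by = grid_step)
    }
    # accumulate stick Gaussians in chunks to bound memory on large ensembles
    intensity <- numeric(length(grid))
    for (block in split(e, ceiling(seq_along(e) / 500))) {
      intensity <- intensity +
        rowSums(vapply(block, function(ei) stats::dnorm(grid, ei, s0),
                       numeric(length(grid))))
    }
    start <- list(A = max(intensity), mu = mean(e), s = sqrt(spread^2 + s0^2))
    df <- data.frame(x = grid, y = intensity)
    fit <- minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                             data = df, start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    center <- unname(cf["mu"]); sigma <- abs(unname(cf["s"]))
  }
  structure(list(grid = grid, intensity = intensity, sticks = e,
                 sigma0 = sigma0, center = center, sigma = sigma,
                 fwhm = .FWHM_SIGMA * sigma, fit = fit),
            class = "band_shape")
}

#' @export
print.band_shape <- function(x, ...) {
  cat(sprintf("band shape: %d sticks, broadening sigma0 = %.3g eV\n",
              length(x$sticks), x$sigma0))
  cat(sprintf("fitted Gaussian: center %.4f eV, sigma %.4f eV, fwhm %.4f eV\n",
              x$center, x$sigma, x$fwhm))
  invisible(x)
}

#' @export
plot.band_shape <- function(x, ...) {
  graphics::plot(x$grid, x$intensity, type = "l",
                 xlab = "excitation energy (eV)", ylab = "intensity", ...)
  graphics::rug(x$sticks)
  graphics::curve(max(x$intensity) * exp(-(t - x$center)^2 / (2 * x$sigma^2)),
                  xname = "t", add = TRUE, col = 2, lty = 2)
  invisible(x)
}

#' Linear trend of a property against solvent polarity
#'
#' Ordinary least squares of a per-solvent quantity (dipole moment,
#' excitation energy, ...) against the relative polarity phi, with
#' studentized-residual outlier flagging: strongly hydrogen-bonding
#' solvents often deviate from the linear polarity trend because the
#' polarity index does not encode directional solute-solvent
#' interactions.
#'
#' @param phi numeric vector of polarity indices (at least two distinct
#'   values).
#' @param value numeric response, same length.
#' @param threshold |studentized residual| above which a point is flagged
#'   (default 3); points whose studentized residual is non-finite but
#'   whose raw residual is non-negligible (exact fit of the remaining
#'   points) are flagged too.
#' @return object of class `polarity_trend`: `slope`, `intercept`,
#'   `residuals`, `rstudent`, `flagged` (indices), `fit` (the `lm`).
#' @export
polarity_trend <- function(phi, value, threshold = 3) {
  stopifnot(length(phi) == length(value), length(phi) >= 2)
  if (length(unique(phi)) < 2L) {
    stop("degenerate regression: all polarity values identical")
  }
  fit <- stats::lm(value ~ phi)
  res <- stats::residuals(fit)
  rs <- if (length(phi) > 3L) suppressWarnings(stats::rstudent(fit)) else rep(NA_real_, length(phi))
  scale <- max(stats::sd(value), .Machine$double.eps)
  sigma_fit <- sqrt(sum(res^2) / fit$df.residual)
  if (sigma_fit < 1e-8 * scale) {
    # numerically exact line: leave-one-out statistics are pure rounding
    # noise, so nothing is an outlier
    flagged <- integer(0)
  } else {
    flagged <- unname(which((is.finite(rs) & abs(rs) > threshold) |
                              (!is.finite(rs) & abs(res) > 1e-8 * scale)))
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = unname(res), rstudent = unname(rs),
                 flagged = flagged, fit = fit),
            class = "polarity_trend")
}

#' @export
print.polarity_trend <- function(x, ...) {
  cat(sprintf("polarity trend: value = %.4f + %.4f * phi\n", x$intercept, x$slope))
  cat(sprintf("residual range [%.4g, %.4g]; flagged points: %s\n",
              min(x$residuals), max(x$residuals),
              if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "none"))
  invisible(x)
}
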