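# Fitting engine: distance-weighted mean-squared-error loss over the
# probe-scan reference energies, minimized by a bounded real-coded
# genetic algorithm with multiple restarts (blend crossover, bounded
# Gaussian mutation, tournament selection, one elite), optionally
# followed by a local L-BFGS-B polish from each restart's best point.

#' Weighted mean-squared-error loss of an FQ parameter set
#'
#' Computes `xi^2 = (1/N) sum_i w_i (E_ref_i - E_fq_i)^2` over a scan
#' dataset, with the default weighting `w_i = 1/d_i` (inverse
#' solvent-probe distance, d in angstrom).  Energies are in kcal/mol.
#'
#' @param dataset a [scan_dataset] with reference energies and placements.
#' @param system an [fq_system] (the solvent molecule).
#' @param params an [fq_params].
#' @return An object of class `fq_loss`: `xi2`, `n`, per-point
#'   `residuals` (`E_ref - E_fq`, kcal/mol), `weights`, and the FQ
#'   energies `e_fq`.
#' @export
fq_loss <- function(dataset, system, params) {
  dataset <- scan_dataset(as.data.frame(dataset))
  evald <- evaluate_scan(dataset, system, params)
  res <- evald$e_ref_kcal - evald$e_fq_kcal
  w <- evald$weight
  structure(list(xi2 = mean(w * res^2), n = nrow(evald),
                 residuals = res, weights = w, e_fq = evald$e_fq_kcal),
            class = "fq_loss")
}

#' @export
print.fq_loss <- function(x, ...) {
  cat(sprintf("FQ loss: xi^2 = %.6g over N = %d points (max |residual| %.4g kcal/mol)\n",
              x$xi2, x$n, max(abs(x$residuals))))
  invisible(x)
}

#' Genetic-algorithm control settings
#'
#' Defaults follow the parametrization protocol: a population of 100
#' random parameter sets per restart, at least 20 restarts (so 2000
#' initial points in parameter space), and all chi, eta restrained to the
#' `[0, 1]` a.u. box.  Operator choices (blend crossover, bounded
#' Gaussian mutation, binary tournament, single elite, 100 generations)
#' are standard real-coded GA practice; an optional bounded local polish
#' of each restart's best candidate is enabled by default.
#'
#' @param pop_size individuals per restart (>= 2).
#' @param restarts independent GA runs; the global best is the minimum
#'   over restarts.
#' @param generations generations per restart.
#' @param bounds length-2 box `(lower, upper)` applied to every chi and
#'   eta (a.u.).
#' @param eta_min strictly positive lower bound applied to hardnesses so
#'   every candidate defines a valid FQ model.
#' @param p_crossover,blx_alpha blend-crossover (BLX-alpha) probability
#'   and spread.
#' @param p_mutation,mutation_sd per-gene Gaussian mutation probability
#'   and standard deviation (fraction of the box width).
#' @param tournament_k tournament size for parent selection.
#' @param n_elite elites copied unchanged into the next generation.
#' @param polish run bounded L-BFGS-B from each restart's best candidate.
#' @return list of class `fq_ga_control`.
#' @export
fq_ga_control <- function(pop_size = 100, restarts = 20, generations = 100,
                          bounds = c(0, 1), eta_min = 1e-4,
                          p_crossover = 0.9, blx_alpha = 0.5,
                          p_mutation = 0.1, mutation_sd = 0.1,
                          tournament_k = 2, n_elite = 1, polish = TRUE) {
  stopifnot(pop_size >= 2, restarts >= 1, generations >= 1,
            length(bounds) == 2, bounds[1] < bounds[2],
            eta_min > 0, tournament_k >= 1, n_elite >= 0)
  structure(list(pop_size = as.integer(pop_size), restarts = as.integer(restarts),
                 generations = as.integer(generations), bounds = as.numeric(bounds),
                 eta_min = eta_min, p_crossover = p_crossover, blx_alpha = blx_alpha,
                 p_mutation = p_mutation, mutation_sd = mutation_sd,
                 tournament_k = as.integer(tournament_k), n_elite = as.integer(n_elite),
                 polish = isTRUE(polish)),
            class = "fq_ga_control")
}

# one GA restart over a loss closure f(theta); returns best theta/value
# plus the per-generation best-so-far trace (non-increasing by elitism)
.ga_restart <- function(f, lower, upper, ctrl) {
  d <- length(lower)
  np <- ctrl$pop_size
  span <- upper - lower
  pop <- matrix(stats::runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                nrow = np)
  fit <- apply(pop, 1, f)
  n_eval <- np
  best_i <- which.min(fit)
  best <- list(theta = pop[best_i, ], value = fit[best_i])
  trace <- numeric(ctrl$generations + 1L)
  trace[1] <- best$value

  for (gen in seq_len(ctrl$generations)) {
    # binary tournament parent selection
    pick <- function() {
      cand <- sample.int(np, ctrl$tournament_k, replace = TRUE)
      cand[which.min(fit[cand])]
    }
    children <- matrix(0, np, d)
    for (i in seq(1, np, by = 2)) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (stats::runif(1) < ctrl$p_crossover) {
        lo <- pmin(p1, p2); hi <- pmax(p1, p2)
        ext <- ctrl$blx_alpha * (hi - lo)
        c1 <- stats::runif(d, lo - ext, hi + ext)
        c2 <- stats::runif(d, lo - ext, hi + ext)
      } else {
        c1 <- p1; c2 <- p2
      }
      children[i, ] <- c1
      if (i + 1 <= np) children[i + 1, ] <- c2
    }
    # bounded Gaussian mutation
    mut <- matrix(stats::runif(np * d) < ctrl$p_mutation, np, d)
    noise <- matrix(stats::rnorm(np * d, sd = ctrl$mutation_sd), np, d) *
      matrix(span, np, d, byrow = TRUE)
    children[mut] <- children[mut] + noise[mut]
    # clip to the box
    children <- pmin(pmax(children, matrix(lower, np, d, byrow = TRUE)),
                     matrix(upper, np, d, byrow = TRUE))
    # elitism: carry the current best unchanged
    if (ctrl$n_elite > 0) {
      elite <- order(fit)[seq_len(ctrl$n_elite)]
      children[seq_len(ctrl$n_elite), ] <- pop[elite, , drop = FALSE]
    }
    pop <- children
    fit <- apply(pop, 1, f)
    n_eval <- n_eval + np
    gi <- which.min(fit)
    if (fit[gi] < best$value) best <- list(theta = pop[gi, ], value = fit[gi])
    trace[gen + 1L] <- best$value
  }

  if (ctrl$polish) {
    op <- tryCatch(
      stats::optim(best$theta, f, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(op) && is.finite(op$value) && op$value < best$value) {
      best <- list(theta = op$par, value = op$value)
      n_eval <- n_eval + op$counts[["function"]]
    }
  }
  list(best = best, trace = trace, n_eval = n_eval)
}

#' Fit FQ parameters to a reference probe scan
#'
#' Minimizes the distance-weighted mean-squared-error loss [fq_loss] over
#' the per-species electronegativities and hardnesses, using a bounded
#' real-coded genetic algorithm with multiple independent restarts.  The
#' loss surface is non-convex (the parameters enter the interaction
#' energies through a constrained linear solve), hence the population
#' search; within a neutral molecule only electronegativity differences
#' are identifiable (a global chi shift is a gauge), so recovered
#' parameters are judged by the energies and polarizabilities they
#' produce, and by the physical validation stage ([check_ordering],
#' [check_polarizability], [select_optimal]).
#'
#' @param dataset a [scan_dataset] holding placements, reference energies
#'   and weights.
#' @param system the solvent [fq_system]; its species define the decision
#'   variables.
#' @param control an [fq_ga_control].
#' @param seed integer seed; every stochastic entry point requires one and
#'   the fit is bit-for-bit reproducible given it.
#' @return An object of class `fq_fit` with components `par` (best
#'   [fq_params]), `value` (its loss), `restarts` (per-restart best
#'   losses and parameters), `traces` (best-so-far loss per generation),
#'   `n_initial_candidates` (`restarts x pop_size`), `n_evaluations`,
#'   `control`, `seed`, `species`, plus the data needed by the methods
#'   (`dataset`, `system`).
#' @seealso [predict.fq_fit], [plot.fq_fit], [simulate.fq_fit],
#'   [select_optimal]
#' @export
fq_fit <- function(dataset, system, control = fq_ga_control(), seed) {
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  stopifnot(inherits(control, "fq_ga_control"))
  dataset <- scan_dataset(as.data.frame(dataset))
  species <- unique(system$species)
  k <- length(species)
  lower <- c(rep(control$bounds[1], k),
             rep(max(control$bounds[1], control$eta_min), k))
  upper <- rep(control$bounds[2], 2 * k)

  ev <- .make_scan_evaluator(system, dataset)
  e_ref <- dataset$e_ref_kcal
  w <- dataset$weight
  n <- nrow(dataset)
  f <- function(theta) {
    r <- e_ref - ev(theta)
    mean(w * r^2)
  }

  set.seed(as.integer(seed))
  runs <- vector("list", control$restarts)
  for (r in seq_len(control$restarts)) runs[[r]] <- .ga_restart(f, lower, upper, control)

  losses <- vapply(runs, function(x) x$best$value, numeric(1))
  thetas <- t(vapply(runs, function(x) x$best$theta, numeric(2 * k)))
  colnames(thetas) <- c(paste0("chi.", species), paste0("eta.", species))
  ibest <- which.min(losses)
  par <- .theta_to_params(runs[[ibest]]$best$theta, species)

  structure(list(par = par, value = losses[ibest],
                 restarts = data.frame(restart = seq_len(control$restarts),
                                       loss = losses, thetas),
                 traces = lapply(runs, `[[`, "trace"),
                 n_initial_candidates = control$restarts * control$pop_size,
                 n_evaluations = sum(vapply(runs, `[[`, numeric(1), "n_eval")),
                 control = control, seed = as.integer(seed), species = species,
                 dataset = dataset, system = system),
            class = "fq_fit")
}

#' @export
print.fq_fit <- function(x, ...) {
  cat(sprintf("FQ parameter fit: %d restart(s) x %d individuals (seed %d)\n",
              x$control$restarts, x$control$pop_size, x$seed))
  cat(sprintf("best loss xi^2 = %.6g kcal^2/mol^2/angstrom over N = %d points\n",
              x$value, nrow(x$dataset)))
  print(x$par)
  invisible(x)
}

#' @export
summary.fq_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object,
              restart_losses = object$restarts$loss,
              rmse = sqrt(mean(res^2)), max_abs_residual = max(abs(res)),
              alpha_iso = fq_polarizability(object$system, object$par)$alpha_iso)
  class(out) <- "summary.fq_fit"
  out
}

#' @export
print.summary.fq_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("residuals: rmse %.4g, max |res| %.4g kcal/mol\n",
              x$rmse, x$max_abs_residual))
  cat(sprintf("fitted alpha_iso = %.4f a.u.\n", x$alpha_iso))
  cat("per-restart losses:\n")
  print(summary(x$restart_losses))
  invisible(x)
}

#' @export
coef.fq_fit <- function(object, ...) {
  p <- object$par
  stats::setNames(c(p$chi, p$eta),
                  c(paste0("chi.", names(p$chi)), paste0("eta.", names(p$eta))))
}

#' Predict FQ-probe interaction energies from a fit
#'
#' @param object an [fq_fit].
#' @param newdata placement table (see [generate_scan]); default the
#'   training dataset.
#' @param ... unused.
#' @return numeric vector of interaction energies (kcal/mol).
#' @export
predict.fq_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$dataset
  evaluate_scan(newdata, object$system, object$par)$e_fq_kcal
}

#' @export
fitted.fq_fit <- function(object, ...) predict(object)

#' @export
residuals.fq_fit <- function(object, ...) {
  object$dataset$e_ref_kcal - fitted(object)
}

#' Plot reference versus fitted scan energies
#'
#' One panel per scan axis: reference interaction energies as points,
#' fitted FQ energies as lines, versus the solvent-probe distance.
#'
#' @param x an [fq_fit].
#' @param ... passed to [graphics::plot].
#' @export
plot.fq_fit <- function(x, ...) {
  ds <- x$dataset
  ds$e_fq_kcal <- fitted(x)
  axes <- unique(ds$axis_id)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(axes)))
  on.exit(graphics::par(old))
  for (a in axes) {
    d <- ds[ds$axis_id == a, ]
    ylim <- range(c(d$e_ref_kcal, d$e_fq_kcal))
    graphics::plot(d$distance_angstrom, d$e_ref_kcal, ylim = ylim,
                   xlab = "solvent-probe distance (angstrom)",
                   ylab = "E_int (kcal/mol)", main = paste("axis", a), ...)
    graphics::lines(d$distance_angstrom, d$e_fq_kcal, col = 2)
  }
  invisible(x)
}

#' Simulate reference scans from a fitted parameter set
#'
#' Draws `nsim` synthetic scan datasets whose reference energies are the
#' fitted model's energies on the training placements plus Gaussian noise.
#'
#' @param object an [fq_fit].
#' @param nsim number of datasets.
#' @param seed integer seed (required).
#' @param noise_sd Gaussian noise standard deviation (kcal/mol).
#' @param ... unused.
#' @return list of [scan_dataset] objects.
#' @export
simulate.fq_fit <- function(object, nsim = 1, seed, noise_sd = 0, ...) {
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  set.seed(as.integer(seed))
  e_fq <- fitted(object)
  lapply(seq_len(nsim), function(i) {
    ds <- object$dataset
    ds$e_ref_kcal <- e_fq + stats::rnorm(length(e_fq), sd = noise_sd)
    scan_dataset(as.data.frame(ds))
  })
}
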