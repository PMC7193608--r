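#' Conductivity calibration problem
#'
#' Bundles everything needed to fit scalp and skull conductivities
#' against measured subdural strip fields: a shell tissue-model template,
#' the electrode montages, one measured pair-field vector (mV/mm) per
#' montage, and the search bounds. The bounds default to the ranges
#' reported across the conductivity literature: skull 0.0028-0.08 S/m,
#' scalp 0.0002-1.0 S/m.
#'
#' @param model a shell `tissue_model` template; every tissue except
#'   scalp and skull stays fixed at its value in the template's
#'   conductivity set.
#' @param montages list of `montage` objects.
#' @param measured list of numeric vectors (one per montage) of
#'   adjacent-pair field magnitudes (mV/mm).
#' @param models optional list of `tissue_model`s, one per montage, for
#'   montages recorded on a geometry variant (e.g. a scalp-removed model
#'   for the skull-exposed condition). Defaults to the template for every
#'   montage. A scalp-removed montage is what makes the two free
#'   conductivities separately identifiable: it pins the skull value
#'   independently of the scalp.
#' @param strip the [strip_spec()] the measurements were taken on.
#' @param bounds list with `sigma_scalp` and `sigma_skull`, each
#'   `c(lower, upper)` in S/m.
#' @param weights objective weights `c(correlation, rms)`; see
#'   [conductivity_objective()].
#' @return A `calibration_problem`.
#' @export
calibration_problem <- function(model, montages, measured, strip,
                                models = NULL,
                                bounds = list(sigma_scalp = c(2e-4, 1),
                                              sigma_skull = c(2.8e-3, 0.08)),
                                weights = c(correlation = 0.5, rms = 0.5)) {
  stopifnot(inherits(model, "tissue_model"), model$kind == "shells",
            length(montages) == length(measured), length(montages) >= 1,
            inherits(strip, "strip_spec"))
  if (is.null(models)) models <- rep(list(model), length(montages))
  stopifnot(length(models) == length(montages),
            all(vapply(models, function(m) m$kind == "shells", TRUE)))
  for (b in bounds)
    if (!(b[1] > 0 && b[1] < b[2]))
      stop("bounds must be positive and ordered", call. = FALSE)
  if (sum(lengths(measured)) < 2)
    stop("need at least 2 informative measured contacts", call. = FALSE)
  structure(list(model = model, models = models, montages = montages,
                 measured = measured, strip = strip, bounds = bounds,
                 weights = weights),
            class = "calibration_problem")
}

set_free_conductivities <- function(model, sigma_scalp, sigma_skull) {
  sig <- unclass(model$conductivities)
  prov <- attr(sig, "provenance")
  sig[["scalp"]] <- sigma_scalp
  sig[["skull"]] <- sigma_skull
  model$conductivities <- conductivity_set(sig, provenance = "calibrated")
  model
}

predict_pair_fields <- function(models, montages, strip, n_max = 200) {
  if (inherits(models, "tissue_model"))
    models <- rep(list(models), length(montages))
  Map(function(model, m) {
    sol <- solve_potential(model, m, n_max = n_max)
    strip_pair_fields(field_along_strip(sol, strip), strip$spacing_mm)
  }, models, montages)
}

#' Calibration objective
#'
#' Weighted combination of correlation mismatch and normalized RMS
#' difference between measured and simulated pooled pair fields:
#' `w1 * (1 - PearsonR) + w2 * RMS / sd(measured)`. Lower is better;
#' zero iff simulated equals measured exactly. If the measured values
#' have zero variance the correlation term is dropped (RMS-only, with
#' `degenerate = TRUE` attribute).
#'
#' @param params numeric `c(sigma_scalp, sigma_skull)` in S/m.
#' @param problem a [calibration_problem()].
#' @param n_max forward-series truncation.
#' @return Scalar objective, with attributes `pearson_r`, `rms` and
#'   `degenerate`.
#' @export
conductivity_objective <- function(params, problem, n_max = 200) {
  models <- lapply(problem$models, set_free_conductivities,
                   params[1], params[2])
  sim <- unlist(predict_pair_fields(models, problem$montages, problem$strip,
                                    n_max = n_max))
  meas <- unlist(problem$measured)
  rms <- sqrt(mean((sim - meas)^2))
  sdm <- stats::sd(meas)
  w <- problem$weights
  degenerate <- !is.finite(sdm) || sdm == 0 || stats::sd(sim) == 0
  if (degenerate) {
    obj <- rms / max(sdm, mean(abs(meas)), .Machine$double.eps)
    r <- NA_real_
  } else {
    r <- stats::cor(sim, meas)
    obj <- w[["correlation"]] * (1 - r) + w[["rms"]] * rms / sdm
  }
  structure(obj, pearson_r = r, rms = rms, degenerate = degenerate)
}

#' Fit scalp and skull conductivities to strip-field measurements
#'
#' Two-stage bounded search: a coarse log-spaced grid over the bounds
#' box (every evaluation retained for audit), followed by Nelder-Mead
#' refinement in log10-space starting from the best grid point, with a
#' quadratic penalty holding iterates inside the box. The optimizer is
#' fully deterministic; randomness only ever enters through synthetic
#' measurement noise upstream.
#'
#' @param problem a [calibration_problem()].
#' @param grid_n grid points per parameter (default 9).
#' @param refine run the Nelder-Mead refinement stage.
#' @param n_max forward-series truncation per solve.
#' @return A `conductivity_fit` with components `coefficients`
#'   (sigma_scalp, sigma_skull), `objective`, `pearson_r`, `rms_mV_mm`,
#'   `n_solves`, `convergence` (`"converged"` or `"boundary"`), `grid`
#'   (audit data frame) and the problem.
#' @seealso [coef.conductivity_fit()], [predict.conductivity_fit()],
#'   [validate_fit()]
#' @export
calibrate <- function(problem, grid_n = 9, refine = TRUE, n_max = 200) {
  stopifnot(inherits(problem, "calibration_problem"))
  b <- problem$bounds
  gs <- 10^seq(log10(b$sigma_scalp[1]), log10(b$sigma_scalp[2]),
               length.out = grid_n)
  gk <- 10^seq(log10(b$sigma_skull[1]), log10(b$sigma_skull[2]),
               length.out = grid_n)
  n_solves <- 0L
  grid <- NULL
  for (s in gs) for (k in gk) {
    obj <- tryCatch(conductivity_objective(c(s, k), problem, n_max = n_max),
                    error = function(e) NA_real_)
    n_solves <- n_solves + length(problem$montages)
    grid <- rbind(grid, data.frame(
      sigma_scalp = s, sigma_skull = k, objective = as.numeric(obj),
      pearson_r = if (is.na(obj[1])) NA_real_ else attr(obj, "pearson_r"),
      rms = if (is.na(obj[1])) NA_real_ else attr(obj, "rms")))
  }
  if (all(is.na(grid$objective)))
    stop("forward solver failed at every grid point", call. = FALSE)
  best <- grid[which.min(grid$objective), ]
  par <- c(best$sigma_scalp, best$sigma_skull)

  if (refine) {
    lo <- log10(c(b$sigma_scalp[1], b$sigma_skull[1]))
    hi <- log10(c(b$sigma_scalp[2], b$sigma_skull[2]))
    pen_obj <- function(lp) {
      lpc <- pmin(pmax(lp, lo), hi)
      pen <- sum((lp - lpc)^2) * 100
      val <- tryCatch(
        as.numeric(conductivity_objective(10^lpc, problem, n_max = n_max)),
        error = function(e) Inf)
      n_solves <<- n_solves + length(problem$montages)
      val + pen
    }
    opt <- stats::optim(log10(par), pen_obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 200))
    par <- 10^pmin(pmax(opt$par, lo), hi)
  }
  at_bound <- par[1] <= b$sigma_scalp[1] * (1 + 1e-6) ||
    par[1] >= b$sigma_scalp[2] * (1 - 1e-6) ||
    par[2] <= b$sigma_skull[1] * (1 + 1e-6) ||
    par[2] >= b$sigma_skull[2] * (1 - 1e-6)
  final <- conductivity_objective(par, problem, n_max = n_max)
  structure(list(coefficients = c(sigma_scalp = par[1], sigma_skull = par[2]),
                 objective = as.numeric(final),
                 pearson_r = attr(final, "pearson_r"),
                 rms_mV_mm = attr(final, "rms"),
                 degenerate = attr(final, "degenerate"),
                 n_solves = n_solves,
                 convergence = if (at_bound) "boundary" else "converged",
                 grid = grid, problem = problem),
            class = "conductivity_fit")
}

#' @export
print.conductivity_fit <- function(x, ...) {
  cat("Calibrated tissue conductivities (S/m):\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("objective %.4g | R = %.3f | RMS = %.4g mV/mm | %s (%d solves)\n",
              x$objective, x$pearson_r, x$rms_mV_mm, x$convergence,
              x$n_solves))
  invisible(x)
}

#' @export
summary.conductivity_fit <- function(object, ...) {
  print(object)
  cat("\nBounds:\n")
  for (nm in names(object$problem$bounds))
    cat(sprintf("  %-12s [%g, %g] S/m\n", nm,
                object$problem$bounds[[nm]][1], object$problem$bounds[[nm]][2]))
  cat(sprintf("Grid audit: %d evaluations; best grid objective %.4g\n",
              nrow(object$grid), min(object$grid$objective, na.rm = TRUE)))
  invisible(object)
}

#' @export
coef.conductivity_fit <- function(object, ...) object$coefficients

#' Predict strip pair fields from a calibrated model
#'
#' @param object a `conductivity_fit`.
#' @param montages list of `montage` objects; defaults to the montages
#'   the fit was calibrated on.
#' @param strip strip specification; defaults to the problem's.
#' @param n_max forward-series truncation.
#' @param ... unused.
#' @return List of numeric pair-field vectors (mV/mm), one per montage.
#' @export
#' @param models optional model list matching `montages` (defaults to the
#'   problem's own per-montage models, or the template for new montages).
predict.conductivity_fit <- function(object, montages = NULL, strip = NULL,
                                     models = NULL, n_max = 200, ...) {
  problem <- object$problem
  if (is.null(models))
    models <- if (is.null(montages)) problem$models else problem$model
  if (is.null(montages)) montages <- problem$montages
  if (inherits(models, "tissue_model"))
    models <- rep(list(models), length(montages))
  models <- lapply(models, set_free_conductivities,
                   object$coefficients[["sigma_scalp"]],
                   object$coefficients[["sigma_skull"]])
  predict_pair_fields(models, montages,
                      if (is.null(strip)) problem$strip else strip,
                      n_max = n_max)
}

#' Residuals of a conductivity fit
#'
#' @param object a `conductivity_fit`.
#' @param ... unused.
#' @return Numeric vector, pooled simulated minus measured pair fields.
#' @export
residuals.conductivity_fit <- function(object, ...) {
  unlist(predict(object)) - unlist(object$problem$measured)
}

#' Plot a conductivity fit
#'
#' Scatter of measured against predicted pair fields with the identity
#' line (perfect-prediction reference).
#' @param x a `conductivity_fit`.
#' @param ... passed to `plot`.
#' @export
plot.conductivity_fit <- function(x, ...) {
  sim <- unlist(predict(x)); meas <- unlist(x$problem$measured)
  graphics::plot(meas, sim, xlab = "measured field (mV/mm)",
                 ylab = "predicted field (mV/mm)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Validate a calibrated model on held-out montages
#'
#' @param fit a `conductivity_fit`.
#' @param montages held-out `montage` list (disjoint from the calibration
#'   montages).
#' @param measured list of measured pair-field vectors for the held-out
#'   montages.
#' @param strip strip specification (defaults to the fit's).
#' @param models optional per-montage model variants for the held-out
#'   conditions.
#' @param n_max forward-series truncation.
#' @return List with `pearson_r`, `p_value`, `rms_mV_mm`, `n`, and a
#'   `scatter` data frame (measured, predicted).
#' @export
validate_fit <- function(fit, montages, measured, strip = NULL,
                         models = NULL, n_max = 200) {
  stopifnot(inherits(fit, "conductivity_fit"))
  pred <- unlist(predict(fit, montages = montages, strip = strip,
                         models = models, n_max = n_max))
  meas <- unlist(measured)
  if (length(meas) < 2)
    stop("need >= 2 held-out values for a correlation", call. = FALSE)
  ct <- stats::cor.test(meas, pred)
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       rms_mV_mm = sqrt(mean((pred - meas)^2)), n = length(meas),
       scatter = data.frame(measured = meas, predicted = pred))
}
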