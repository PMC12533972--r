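# Parameter estimation: order-of-magnitude initial estimates, the
# normalized absolute-deviation error, and bound-constrained Nelder-Mead.

#' Magnitude assumptions behind the initial estimates
#'
#' The rough scales used to seed the optimizer: each term of each equation
#' should initially come out on the order of its derivative variable. The
#' defaults encode the calibrated data scales — peak neutrophils ~1000,
#' peak M1 (and M2) ~10,000 cells/mm^3, 30,000 dead myonuclei at day 0, a
#' debris saturation scale of ~1000 cells/mm^3 for the M1-to-M2 brake,
#' ~1000 neutrophils and ~5000 monocytes entering per day, and unit
#' first-order exit rates (1/day).
#'
#' @return Named list of scales.
#' @export
magnitude_scales <- function() {
  list(
    max_N = 1000,            # peak calibrated neutrophil density
    max_M1 = 10000,          # peak M1 macrophage density (order)
    max_M2 = 10000,          # peak M2 macrophage density (order)
    Md0 = 30000,             # day-0 damaged myonuclei
    debris_scale = 1000,     # Nd + Md scale at which M1->M2 is half-slowed
    neutrophil_influx = 1000, # neutrophils entering per day at peak damage
    monocyte_influx = 5000,  # monocytes entering per day at peak chemotaxis
    unit_rate = 1            # default first-order exit rate, 1/day
  )
}

#' Order-of-magnitude initial estimates with search bounds
#'
#' Build the optimizer's starting point: bilinear clearance/interaction
#' constants are set to 1 over the assumed maximum of the partner variable
#' (e.g. `cNMd = 1/max(N) = 1e-3`), influx constants to the required flux
#' over the driver magnitude (e.g. `cNin = 1000/30000`), first-order exit
#' rates to 1/day, the M1-to-M2 saturation constant to the debris scale and
#' its rate constant to `unit_rate * debris_scale` (so the conversion flux
#' is about M1 per day once debris clears). Estimates are reported at 5
#' significant digits, and the search box spans a factor of 100 below and
#' above each estimate.
#'
#' @param scales Named list of magnitude assumptions; see
#'   [magnitude_scales()]. All entries are required.
#' @param bound_factor Half-width of the search box as a multiplicative
#'   factor (default 100).
#' @return A `parameter_spec` tibble `(parameter, initial, lower, upper)`
#'   in the fixed parameter order.
#' @examples
#' heuristic_initial_estimates()
#' @export
heuristic_initial_estimates <- function(scales = magnitude_scales(),
                                        bound_factor = 100) {
  needed <- names(magnitude_scales())
  missing <- setdiff(needed, names(scales))
  if (length(missing) > 0) {
    stop("missing magnitude scale(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- scales
  initial <- c(
    cNMd = 1 / s$max_N,
    cM1Md = 1 / s$max_M1,
    cNin = s$neutrophil_influx / s$Md0,
    cNout = s$unit_rate,
    cM1Nd = 1 / s$max_M1,
    cMin = s$monocyte_influx / s$max_N,
    cMM1 = 1 / s$Md0,
    cMout = s$unit_rate,
    cM1M2 = s$unit_rate * s$debris_scale,
    cM1M2inhib = s$debris_scale,
    cM2out = s$unit_rate,
    cQSCN = 1 / s$max_N,
    cQSCMd = 1 / s$Md0,
    cASCM2 = 1 / s$max_M2,
    cASCpro = 1 / s$max_M1,
    cASCdiff = 1 / s$max_M2,
    cMcout = s$unit_rate
  )[param_names]
  initial <- signif(initial, 5)
  spec <- tibble::tibble(
    parameter = param_names,
    initial = as.numeric(initial),
    lower = as.numeric(initial) / bound_factor,
    upper = as.numeric(initial) * bound_factor
  )
  structure(spec, class = c("parameter_spec", class(spec)))
}

#' Normalized absolute-deviation error between simulation and targets
#'
#' The target-table half of the fitting error: given simulated densities
#' and calibrated targets, compute
#' `E = sum_X sum_d |Sim_X(d) - T_X(d)| / max_d T_X(d)`,
#' where `X` ranges over the cell types present in the target table and
#' `d` over each type's target days. Division by each type's maximum
#' target keeps abundant populations from dominating. The fixed day-7
#' dead-cell targets (max target 1) enter through the same formula.
#'
#' @param sim A data frame `(day, cell_type, value)` of simulated
#'   densities covering every target row.
#' @param targets A `calibrated_targets` table (or any data frame with
#'   `day`, `cell_type`, `target`).
#' @return Non-negative scalar error.
#' @export
absolute_deviation_error <- function(sim, targets) {
  targets <- tibble::as_tibble(targets)
  sim <- tibble::as_tibble(sim)
  joined <- dplyr::left_join(targets, sim, by = c("day", "cell_type"))
  if (anyNA(joined$value)) {
    miss <- joined[is.na(joined$value), ]
    stop("no simulated value for cell type ", miss$cell_type[1],
         " at day ", miss$day[1], call. = FALSE)
  }
  per_type <- joined |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      contribution = sum(abs(.data$value - .data$target)) /
        max(.data$target),
      .groups = "drop"
    )
  if (any(!is.finite(per_type$contribution))) {
    stop("all-zero targets for cell type ",
         per_type$cell_type[!is.finite(per_type$contribution)][1],
         call. = FALSE)
  }
  sum(per_type$contribution)
}

#' Fitting error of a parameter vector
#'
#' Simulate the model at the target days and evaluate
#' [absolute_deviation_error()] against the calibrated targets.
#'
#' @param params A [rate_parameters()] vector.
#' @param targets A `calibrated_targets` table.
#' @param initial Day-0 [cell_state()].
#' @param ... Passed to [simulate_regeneration()] (tolerances, method).
#' @return Non-negative scalar error.
#' @export
fit_error <- function(params, targets, initial, ...) {
  targets <- tibble::as_tibble(targets)
  days <- sort(unique(c(0, targets$day)))
  traj <- simulate_regeneration(params, initial, grid = days, ...)
  sim <- dplyr::rename(tidy(traj), day = "time_days")
  sim$cell_type <- as.character(sim$cell_type)
  absolute_deviation_error(sim, targets)
}

# Box-constrained Nelder-Mead. Standard reflection/expansion/contraction
# coefficients by default, or the dimension-scaled ("adaptive") variants
# that behave better in high dimension; every candidate vertex is clipped
# into [lower, upper] before evaluation, the same bound handling as the
# reference simplex implementations that accept box constraints.
# Deterministic.
nelder_mead_box <- function(fn, x0, lower, upper, max_evals = 10000,
                            xatol = 1e-10, fatol = 1e-10,
                            adaptive = FALSE) {
  n <- length(x0)
  stopifnot(length(lower) == n, length(upper) == n, all(lower <= upper))
  if (adaptive && n > 1) {
    chi <- 1 + 2 / n; psi <- 0.75 - 1 / (2 * n); sigma <- 1 - 1 / n
  } else {
    chi <- 2; psi <- 0.5; sigma <- 0.5
  }
  clip <- function(x) pmin(pmax(x, lower), upper)
  x0 <- clip(x0)
  if (all(upper == lower)) {
    f0 <- fn(x0)
    return(list(x = x0, f = f0, nfev = 1, converged = TRUE,
                trace = tibble::tibble(eval = 1, best_error = f0)))
  }
  simplex <- matrix(rep(x0, each = n + 1), nrow = n + 1)
  for (i in seq_len(n)) {
    simplex[i + 1, i] <- if (x0[i] != 0) x0[i] * 1.05 else 0.00025
  }
  simplex <- t(apply(simplex, 1, clip))
  fv <- apply(simplex, 1, fn)
  nfev <- n + 1
  trace_e <- nfev
  trace_f <- min(fv)
  record <- function(f) {
    if (f < trace_f[length(trace_f)]) {
      trace_e <<- c(trace_e, nfev)
      trace_f <<- c(trace_f, f)
    }
  }
  converged <- FALSE
  while (nfev < max_evals) {
    o <- order(fv)
    simplex <- simplex[o, , drop = FALSE]
    fv <- fv[o]
    if (max(abs(sweep(simplex[-1, , drop = FALSE], 2, simplex[1, ]))) <=
          xatol && max(abs(fv[-1] - fv[1])) <= fatol) {
      converged <- TRUE
      break
    }
    centroid <- colMeans(simplex[seq_len(n), , drop = FALSE])
    worst <- simplex[n + 1, ]
    xr <- clip(centroid + (centroid - worst))
    fr <- fn(xr); nfev <- nfev + 1; record(fr)
    shrink <- FALSE
    if (fr < fv[1]) {
      xe <- clip(centroid + chi * (centroid - worst))
      fe <- fn(xe); nfev <- nfev + 1; record(fe)
      if (fe < fr) {
        simplex[n + 1, ] <- xe; fv[n + 1] <- fe
      } else {
        simplex[n + 1, ] <- xr; fv[n + 1] <- fr
      }
    } else if (fr < fv[n]) {
      simplex[n + 1, ] <- xr; fv[n + 1] <- fr
    } else if (fr < fv[n + 1]) {
      xc <- clip(centroid + psi * (centroid - worst))
      fc <- fn(xc); nfev <- nfev + 1; record(fc)
      if (fc <= fr) {
        simplex[n + 1, ] <- xc; fv[n + 1] <- fc
      } else shrink <- TRUE
    } else {
      xc <- clip(centroid - psi * (centroid - worst))
      fc <- fn(xc); nfev <- nfev + 1; record(fc)
      if (fc < fv[n + 1]) {
        simplex[n + 1, ] <- xc; fv[n + 1] <- fc
      } else shrink <- TRUE
    }
    if (shrink) {
      for (i in 2:(n + 1)) {
        simplex[i, ] <- clip(simplex[1, ] + sigma * (simplex[i, ] -
                                                       simplex[1, ]))
        fv[i] <- fn(simplex[i, ])
      }
      nfev <- nfev + n
      record(min(fv))
    }
  }
  o <- order(fv)
  list(x = simplex[o[1], ], f = fv[o[1]], nfev = nfev,
       converged = converged,
       trace = tibble::tibble(eval = trace_e, best_error = trace_f))
}

#' Fit the rate constants to calibrated targets
#'
#' Minimize [fit_error()] over the search box of a parameter spec with
#' bound-constrained Nelder-Mead, starting from the spec's initial
#' estimates. Candidate vertices are clipped into the box, so every
#' evaluated parameter vector is feasible. Optionally the search runs in
#' log-parameter space (`log_scale = TRUE`), which can help since the
#' constants span about eight orders of magnitude; the default searches in
#' linear space. `restarts` re-starts the simplex at the incumbent best
#' point, sharing the evaluation budget equally. The procedure is
#' deterministic; `seed` is accepted for interface symmetry with the
#' stochastic generators and is only used to seed any future stochastic
#' options.
#'
#' @param spec A `parameter_spec` from [heuristic_initial_estimates()].
#' @param targets A `calibrated_targets` table.
#' @param initial Day-0 [cell_state()].
#' @param max_evals Total error-evaluation budget (default 10000).
#' @param log_scale Search in log-parameter space?
#' @param adaptive Use dimension-scaled simplex coefficients (helpful for
#'   the 17-dimensional search)? Default uses the classical coefficients.
#' @param restarts Number of simplex restarts at the incumbent (default 0).
#' @param xatol,fatol Simplex convergence tolerances.
#' @param seed Optional integer seed.
#' @param ... Passed to [fit_error()] (solver settings).
#' @return A `regen_fit` object: optimized `rate_parameters`, final and
#'   initial error, best-so-far error trace, convergence flag, evaluation
#'   count, and the spec/targets/initial state used. The final error never
#'   exceeds the error at the initial estimate.
#' @export
fit_parameters <- function(spec, targets, initial, max_evals = 10000,
                           log_scale = FALSE, restarts = 0,
                           adaptive = FALSE,
                           xatol = 1e-10, fatol = 1e-10, seed = NULL, ...) {
  stopifnot(is.data.frame(spec),
            all(c("parameter", "initial", "lower", "upper") %in%
                  names(spec)))
  spec <- tibble::as_tibble(spec)[match(param_names, spec$parameter), ]
  if (anyNA(spec$parameter)) {
    stop("parameter spec must cover all 17 rate constants", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  initial <- as_cell_state(initial)
  x0 <- stats::setNames(spec$initial, spec$parameter)
  lower <- spec$lower
  upper <- spec$upper
  objective <- function(x) {
    p <- structure(stats::setNames(x, param_names),
                   class = "rate_parameters")
    e <- tryCatch(fit_error(p, targets, initial, ...),
                  error = function(cond) NA_real_)
    if (!is.finite(e)) 1e12 else e
  }
  if (log_scale) {
    if (any(lower <= 0)) {
      stop("log-scale search requires strictly positive lower bounds",
           call. = FALSE)
    }
    fn <- function(z) objective(exp(z))
    z0 <- log(x0); zl <- log(lower); zu <- log(upper)
  } else {
    fn <- objective
    z0 <- x0; zl <- lower; zu <- upper
  }
  budget <- max(1, floor(max_evals / (restarts + 1)))
  best <- NULL
  start <- z0
  traces <- list()
  offset <- 0
  total_nfev <- 0
  for (r in seq_len(restarts + 1)) {
    res <- nelder_mead_box(fn, start, zl, zu, max_evals = budget,
                           xatol = xatol, fatol = fatol,
                           adaptive = adaptive)
    total_nfev <- total_nfev + res$nfev
    res$trace$eval <- res$trace$eval + offset
    offset <- offset + res$nfev
    traces[[r]] <- res$trace
    if (is.null(best) || res$f < best$f) best <- res
    start <- best$x
  }
  trace <- dplyr::filter(
    dplyr::bind_rows(traces),
    .data$best_error <= cummin(.data$best_error)
  )
  x_best <- if (log_scale) exp(best$x) else best$x
  params <- structure(stats::setNames(as.numeric(x_best), param_names),
                      class = "rate_parameters")
  initial_error <- objective(if (log_scale) exp(z0) else z0)
  final_error <- min(best$f, initial_error)
  if (best$f > initial_error) {
    params <- structure(stats::setNames(as.numeric(x0), param_names),
                        class = "rate_parameters")
  }
  structure(list(
    parameters = params,
    error = final_error,
    initial_error = initial_error,
    trace = trace,
    converged = best$converged,
    nfev = total_nfev,
    spec = spec,
    targets = targets,
    initial_state = initial
  ), class = "regen_fit")
}

#' @export
print.regen_fit <- function(x, ...) {
  cat("<regen_fit>\n")
  cat(sprintf("  error: %.6g (from %.6g at initial estimates)\n",
              x$error, x$initial_error))
  cat(sprintf("  evaluations: %d; converged: %s\n", x$nfev, x$converged))
  invisible(x)
}

#' Tidy a fitted model
#'
#' One row per rate constant with the initial estimate, search bounds and
#' fitted value.
#'
#' @param x A `regen_fit`.
#' @param ... Unused.
#' @return A tibble `(parameter, initial, lower, upper, estimate)`.
#' @export
tidy.regen_fit <- function(x, ...) {
  tibble::tibble(
    parameter = x$spec$parameter,
    initial = x$spec$initial,
    lower = x$spec$lower,
    upper = x$spec$upper,
    estimate = as.numeric(x$parameters)
  )
}

#' One-line fit summary
#'
#' @param x A `regen_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the final error, the error at the initial
#'   estimates, the fractional error reduction, the evaluation count and
#'   the convergence flag.
#' @export
glance.regen_fit <- function(x, ...) {
  tibble::tibble(
    error = x$error,
    initial_error = x$initial_error,
    error_reduction = 1 - x$error / x$initial_error,
    nfev = x$nfev,
    converged = x$converged
  )
}

#' Plot the optimizer's error trace
#'
#' Best-so-far error against evaluation count, log-scaled.
#'
#' @param object A `regen_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regen_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$eval, y = .data$best_error)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "error evaluations", y = "best error so far") +
    ggplot2::theme_minimal()
}
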