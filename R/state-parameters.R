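# State and rate-constant vectors for the nine-population regeneration model.

# Fixed orderings used for vectorization everywhere in the package.
state_names <- c("Md", "N", "Nd", "M", "M1", "M2", "QSC", "ASC", "Mc")
param_names <- c(
  "cNMd", "cM1Md", "cNin", "cNout", "cM1Nd", "cMin", "cMM1", "cMout",
  "cM1M2", "cM1M2inhib", "cM2out", "cQSCN", "cQSCMd", "cASCM2",
  "cASCpro", "cASCdiff", "cMcout"
)
observable_names <- c("N", "M", "M1", "M2", "QSC", "ASC", "Mc")
unobservable_names <- c("Md", "Nd")

#' Cell-type population state
#'
#' Construct a validated vector of the nine population densities of the
#' regeneration model, in cells per cubic millimeter: damaged (dead)
#' myonuclei `Md`, neutrophils `N`, dead neutrophils `Nd`, monocytes `M`,
#' M1 and M2 macrophages, quiescent (`QSC`) and activated (`ASC`) satellite
#' cells, and myocytes (`Mc`). `Md` and `Nd` are not observable in annotated
#' single-cell data; the other seven types are.
#'
#' @param ... Named densities (any subset of the nine; omitted types are 0),
#'   or a single named numeric vector covering a subset of the nine names.
#' @return A named numeric vector of length 9 in the fixed ordering
#'   `Md, N, Nd, M, M1, M2, QSC, ASC, Mc`, with class `"cell_state"`.
#' @examples
#' cell_state(Md = 30000, N = 20, M = 44, M2 = 56, QSC = 111)
#' @export
cell_state <- function(...) {
  x <- collect_named(..., allowed = state_names, what = "cell state")
  full <- stats::setNames(numeric(length(state_names)), state_names)
  full[names(x)] <- x
  validate_nonnegative(full, "cell state")
  structure(full, class = "cell_state")
}

#' Rate constants of the regeneration model
#'
#' Construct a validated vector of the 17 rate constants. All are
#' non-negative; `cM1M2inhib` is a saturation constant in cells/mm^3, the
#' rest carry per-day or per-(day * cells/mm^3) units as implied by the
#' linear or bilinear term they govern.
#'
#' @param ... Named values for all 17 constants, or a single named numeric
#'   vector containing all 17.
#' @return A named numeric vector of length 17 in the fixed (published
#'   table) ordering, with class `"rate_parameters"`.
#' @examples
#' fitted_rate_parameters()
#' @export
rate_parameters <- function(...) {
  x <- collect_named(..., allowed = param_names, what = "rate parameter")
  missing <- setdiff(param_names, names(x))
  if (length(missing) > 0) {
    stop("missing rate parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[param_names]
  validate_nonnegative(x, "rate parameter")
  structure(x, class = "rate_parameters")
}

# Gather ... into a named numeric vector restricted to `allowed` names.
collect_named <- function(..., allowed, what) {
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) && !is.null(names(dots[[1]]))) {
    dots <- as.list(dots[[1]])
  }
  if (length(dots) == 0) return(stats::setNames(numeric(0), character(0)))
  nm <- names(dots)
  if (is.null(nm) || any(nm == "")) {
    stop("all ", what, " values must be named", call. = FALSE)
  }
  bad <- setdiff(nm, allowed)
  if (length(bad) > 0) {
    stop("unknown ", what, " field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicated ", what, " field(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  vapply(dots, function(v) {
    stopifnot(is.numeric(v), length(v) == 1)
    as.numeric(v)
  }, numeric(1))
}

validate_nonnegative <- function(x, what) {
  if (any(!is.finite(x))) {
    stop("non-finite ", what, " value(s): ",
         paste(names(x)[!is.finite(x)], collapse = ", "), call. = FALSE)
  }
  if (any(x < 0)) {
    stop("negative ", what, " value(s): ",
         paste(names(x)[x < 0], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

as_cell_state <- function(x) {
  if (inherits(x, "cell_state")) return(x)
  cell_state(x)
}

as_rate_parameters <- function(x) {
  if (inherits(x, "rate_parameters")) return(x)
  rate_parameters(x)
}

#' Published optimized rate constants
#'
#' The fitted values of the 17 rate constants obtained by bound-constrained
#' Nelder-Mead calibration against the injury time-course targets, as
#' printed in the model's parameter table. These reproduce the reported
#' trajectory features (neutrophil peak near 1000 cells/mm^3 around day 1,
#' M1 peak near 7000 cells/mm^3 around day 2).
#'
#' @return A `rate_parameters` vector.
#' @export
fitted_rate_parameters <- function() {
  rate_parameters(
    cNMd = 1.0000e-05, cM1Md = 3.8885e-04, cNin = 8.9560e-02,
    cNout = 1.2987e+00, cM1Nd = 2.2054e-04, cMin = 2.1884e+01,
    cMM1 = 9.2002e-05, cMout = 3.2537e+00, cM1M2 = 3.7605e+02,
    cM1M2inhib = 1.0522e+03, cM2out = 1.6957e-02, cQSCN = 6.1567e-04,
    cQSCMd = 1.1516e-06, cASCM2 = 2.7655e-04, cASCpro = 2.2439e-04,
    cASCdiff = 6.9390e-05, cMcout = 5.1369e-01
  )
}

#' Day-0 initial state for the strong-injury scenario
#'
#' The initial condition used for all fitted-model simulations: 30,000
#' damaged myonuclei per mm^3 (a typical strong injury), no dead
#' neutrophils, and the calibrated day-0 densities of the seven observable
#' types (20 neutrophils, 44 monocytes, 0 M1, 56 M2, 111 quiescent
#' satellite cells, 0 activated satellite cells, 0 myocytes).
#'
#' @return A `cell_state` vector.
#' @export
default_initial_state <- function() {
  cell_state(Md = 30000, N = 20, Nd = 0, M = 44, M1 = 0, M2 = 56,
             QSC = 111, ASC = 0, Mc = 0)
}

#' Reference monocyte/macrophage-lineage densities
#'
#' Flow-cytometry reference counts of the total monocyte/macrophage lineage
#' (M + M1 + M2) in injured muscle, used to anchor proportion-to-density
#' calibration: 100, 5000, 20000 and 5000 cells/mm^3 at days 0, 1, 3 and 7
#' post-injury. Day 3.5 data are calibrated against the day-3 value;
#' intermediate days are linearly interpolated (see
#' [interpolate_reference()]).
#'
#' @return A tibble with columns `day` and `lineage_count`.
#' @export
reference_lineage_counts <- function() {
  tibble::tibble(day = c(0, 1, 3, 7),
                 lineage_count = c(100, 5000, 20000, 5000))
}

#' Observable cell types
#'
#' The seven model populations visible in annotated single-cell data.
#' Dead myonuclei (`Md`) and dead neutrophils (`Nd`) are modeled but never
#' observed.
#'
#' @return Character vector of the seven observable type names.
#' @export
observable_cell_types <- function() observable_names

#' @export
print.cell_state <- function(x, ...) {
  cat("<cell_state> densities (cells/mm^3)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("<rate_parameters> 17 rate constants\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname tidy.regen_trajectory
#' @export
tidy.cell_state <- function(x, ...) {
  tibble::tibble(cell_type = names(x), density = as.numeric(x),
                 observable = names(x) %in% observable_names)
}

#' @rdname tidy.regen_trajectory
#' @export
tidy.rate_parameters <- function(x, ...) {
  tibble::tibble(parameter = names(x), value = as.numeric(x))
}
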