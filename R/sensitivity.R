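# Local one-at-a-time parameter sensitivity of the model trajectory.

#' Perturbation sensitivity of the trajectory to each rate constant
#'
#' Simulate an unperturbed trajectory, then one trajectory per rate
#' constant with that constant increased by a small relative amount
#' (default 0.1%), and record the difference (perturbed minus unperturbed)
#' for every population at every grid time. For each population the 17 x T
#' difference matrix is scaled by the absolute value of its largest-
#' magnitude entry, giving values in \[-1, 1\]; an all-zero matrix (e.g.
#' any immune population against the satellite-cell constants, which
#' cannot influence it) is left all-zero. Differences smaller than
#' 1e-9 times the population's trajectory maximum are treated as exact
#' zeros, a dead band that keeps solver round-off from polluting signs.
#'
#' By default the stored values are raw trajectory differences; with
#' `derivative = TRUE` each parameter's row is divided by the absolute
#' perturbation `rel_delta * p`, approximating the partial derivative of
#' the trajectory. The two conventions differ only by per-row positive
#' factors, so within-matrix normalization and all sign structure agree up
#' to cross-parameter weighting.
#'
#' @param params A [rate_parameters()] vector (typically
#'   [fitted_rate_parameters()]).
#' @param initial Day-0 [cell_state()].
#' @param rel_delta Relative perturbation size (> 0; default 0.001).
#' @param grid Time grid; default hourly.
#' @param derivative Divide differences by the absolute perturbation?
#' @param ... Passed to [simulate_regeneration()].
#' @return A `sensitivity_tensor`: per population a normalized and a raw
#'   17 x T matrix (rows in the fixed parameter order, columns the grid
#'   times), plus the grid, parameters and settings used.
#' @examples
#' \donttest{
#' sens <- perturbation_sensitivity(fitted_rate_parameters(),
#'                                  default_initial_state())
#' }
#' @export
perturbation_sensitivity <- function(params, initial, rel_delta = 0.001,
                                     grid = "hourly", derivative = FALSE,
                                     ...) {
  if (!is.numeric(rel_delta) || rel_delta <= 0) {
    stop("rel_delta must be positive", call. = FALSE)
  }
  params <- as_rate_parameters(params)
  initial <- as_cell_state(initial)
  times <- simulation_grid(grid)
  base <- simulate_regeneration(params, initial, grid = times, ...)
  base_mat <- as.matrix(tibble::as_tibble(base)[state_names])
  raw <- lapply(state_names, function(v) {
    matrix(0, nrow = length(param_names), ncol = length(times),
           dimnames = list(param_names, NULL))
  })
  names(raw) <- state_names
  for (pn in param_names) {
    pert <- unclass(params)
    pert[pn] <- pert[pn] * (1 + rel_delta)
    traj <- tryCatch(
      simulate_regeneration(rate_parameters(pert), initial, grid = times,
                            ...),
      error = function(cond) {
        stop("simulation failed under perturbation of ", pn, ": ",
             conditionMessage(cond), call. = FALSE)
      }
    )
    diff_mat <- as.matrix(tibble::as_tibble(traj)[state_names]) - base_mat
    if (derivative) diff_mat <- diff_mat / (unclass(params)[pn] * rel_delta)
    for (v in state_names) raw[[v]][pn, ] <- diff_mat[, v]
  }
  for (v in state_names) {
    dead_band <- 1e-9 * max(base_mat[, v])
    raw[[v]][abs(raw[[v]]) < dead_band] <- 0
  }
  normalized <- lapply(raw, normalize_sensitivity)
  structure(list(
    normalized = normalized, raw = raw, time = times,
    params = params, initial = initial, rel_delta = rel_delta,
    derivative = derivative
  ), class = "sensitivity_tensor")
}

# Scale a matrix into [-1, 1] by its largest absolute entry; all-zero
# matrices stay all-zero. Idempotent.
normalize_sensitivity <- function(m) {
  top <- max(abs(m))
  if (top == 0) m else m / top
}

#' @export
print.sensitivity_tensor <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_tensor> %d parameters x %d time points x %d populations (rel_delta = %g%s)\n",
    nrow(x$raw[[1]]), ncol(x$raw[[1]]), length(x$raw),
    x$rel_delta, if (x$derivative) ", derivative scaling" else ""
  ))
  invisible(x)
}

#' @rdname tidy.regen_trajectory
#' @export
tidy.sensitivity_tensor <- function(x, ...) {
  purrr::map_dfr(names(x$raw), function(v) {
    tibble::tibble(
      cell_type = v,
      parameter = rep(param_names, times = length(x$time)),
      time_days = rep(x$time, each = length(param_names)),
      raw = as.numeric(x$raw[[v]]),
      normalized = as.numeric(x$normalized[[v]])
    )
  })
}

#' Sensitivity heatmaps
#'
#' One heatmap per population: rows are the 17 rate constants in the fixed
#' order, columns are grid times, fill is the normalized difference on a
#' blue-white-red diverging scale anchored at -1, 0 and +1.
#'
#' @param object A `sensitivity_tensor`.
#' @param cell_types Populations to include (default all nine).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_tensor <- function(object, cell_types = state_names,
                                        ...) {
  dat <- dplyr::filter(tidy(object), .data$cell_type %in% cell_types)
  dat <- dplyr::mutate(
    dat,
    cell_type = factor(.data$cell_type, levels = state_names),
    parameter = factor(.data$parameter, levels = rev(param_names))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_days,
                                    y = .data$parameter,
                                    fill = .data$normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::labs(x = "days post-injury", y = NULL,
                  fill = "scaled\ndifference") +
    ggplot2::theme_minimal()
}

#' Export sensitivity matrices as heatmap images and CSV files
#'
#' Writes, per population, `sensitivity_<type>.csv` (normalized matrix,
#' one `parameter` column then one column per grid time, full double
#' precision) and `sensitivity_<type>.png` (the heatmap of
#' [autoplot.sensitivity_tensor()]).
#'
#' @param tensor A `sensitivity_tensor`.
#' @param path Output directory (created if needed).
#' @param image Also write heatmap images? (CSV is always written.)
#' @param width,height Image size in inches.
#' @return Tibble of written file paths, invisibly.
#' @export
export_sensitivity <- function(tensor, path, image = TRUE,
                               width = 7, height = 4) {
  stopifnot(inherits(tensor, "sensitivity_tensor"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::map_dfr(names(tensor$normalized), function(v) {
    m <- tensor$normalized[[v]]
    csv <- file.path(path, paste0("sensitivity_", v, ".csv"))
    # 17 significant digits: the shortest representation guaranteed to
    # parse back to the identical double
    tbl <- tibble::as_tibble(as.data.frame(apply(m, 2, sprintf,
                                                 fmt = "%.17g")))
    names(tbl) <- format(tensor$time, trim = TRUE)
    tbl <- tibble::add_column(tbl, parameter = param_names, .before = 1)
    readr::write_csv(tbl, csv)
    out <- tibble::tibble(cell_type = v, file = csv)
    if (image) {
      png_file <- file.path(path, paste0("sensitivity_", v, ".png"))
      plt <- autoplot.sensitivity_tensor(tensor, cell_types = v)
      ggplot2::ggsave(png_file, plt, width = width, height = height,
                      dpi = 150)
      out <- dplyr::bind_rows(out,
                              tibble::tibble(cell_type = v, file = png_file))
    }
    out
  })
  invisible(files)
}

#' Read a sensitivity matrix CSV written by [export_sensitivity()]
#'
#' @param file CSV path.
#' @return A 17 x T numeric matrix with parameter row names.
#' @export
read_sensitivity_csv <- function(file) {
  # base reader: strtod parsing is correctly rounded, so the 17-digit
  # representation restores each double bit for bit
  tbl <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(tbl[-1])
  storage.mode(m) <- "double"
  dimnames(m) <- list(tbl$parameter, NULL)
  m
}
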