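# Calibration of cell-type proportions to absolute densities (cells/mm^3).
#
# Annotated single-cell data give only counts out of an indefinite sampled
# amount of tissue. The monocyte/macrophage lineage (M + M1 + M2) has
# externally measured absolute densities at several days post-injury, so
# each day's proportions are rescaled by the factor that maps the lineage's
# mean proportion onto its reference density.

observable_or_stop <- function(cell_type) {
  bad <- setdiff(unique(cell_type), observable_names)
  if (length(bad) > 0) {
    stop("unmodeled cell type(s) in table: ", paste(bad, collapse = ", "),
         "; discard unmodeled types before loading", call. = FALSE)
  }
}

#' Per-replicate cell-type proportions from counts
#'
#' Divide each cell type's count by the replicate's total across the seven
#' observable types. Types absent from a replicate get proportion 0, so
#' every (day, replicate) carries all seven types and proportions sum to 1.
#'
#' @param counts A data frame with columns `day`, `replicate`, `cell_type`
#'   (one of the seven observable types) and `count` (non-negative).
#' @return A tibble `(day, replicate, cell_type, proportion)`.
#' @export
proportions_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  req <- c("day", "replicate", "cell_type", "count")
  if (!all(req %in% names(counts))) {
    stop("count table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  observable_or_stop(counts$cell_type)
  if (any(counts$count < 0)) stop("negative counts", call. = FALSE)
  full <- tidyr::complete(
    counts,
    tidyr::nesting(day, replicate),
    cell_type = observable_names,
    fill = list(count = 0)
  )
  out <- full |>
    dplyr::group_by(.data$day, .data$replicate) |>
    dplyr::mutate(total = sum(.data$count)) |>
    dplyr::ungroup()
  zero <- dplyr::distinct(dplyr::filter(out, .data$total == 0),
                          .data$day, .data$replicate)
  if (nrow(zero) > 0) {
    stop("zero total count for day ", zero$day[1], ", replicate ",
         zero$replicate[1], call. = FALSE)
  }
  out |>
    dplyr::mutate(proportion = .data$count / .data$total) |>
    dplyr::select("day", "replicate", "cell_type", "proportion") |>
    dplyr::arrange(.data$day, .data$replicate,
                   match(.data$cell_type, observable_names))
}

#' Interpolate reference lineage densities to arbitrary days
#'
#' Returns the reference monocyte/macrophage-lineage density at each
#' requested day: the exact reference value at reference days, linear
#' interpolation between bracketing days otherwise. Day 3.5 is special: the
#' day-3 reference value is used directly (the reference series has no
#' day-3.5 measurement and the day-3 count is taken to apply), not an
#' interpolation. Requested days outside the reference range are an error;
#' no extrapolation is performed.
#'
#' @param ref A data frame `(day, lineage_count)` with strictly increasing
#'   days and positive counts; default [reference_lineage_counts()].
#' @param days Numeric vector of requested days.
#' @return A tibble `(day, lineage_count)` for the requested days.
#' @examples
#' interpolate_reference(days = c(0, 1, 2, 3.5, 5, 7))
#' @export
interpolate_reference <- function(ref = reference_lineage_counts(), days) {
  ref <- tibble::as_tibble(ref)
  stopifnot(all(c("day", "lineage_count") %in% names(ref)))
  if (any(diff(ref$day) <= 0)) {
    stop("reference days must be strictly increasing", call. = FALSE)
  }
  if (any(ref$lineage_count <= 0)) {
    stop("reference lineage counts must be positive", call. = FALSE)
  }
  out_of_range <- days < min(ref$day) | days > max(ref$day)
  if (any(out_of_range)) {
    stop("requested day(s) outside reference range: ",
         paste(days[out_of_range], collapse = ", "), call. = FALSE)
  }
  value <- vapply(days, function(d) {
    if (d == 3.5 && !(3.5 %in% ref$day) && 3 %in% ref$day) {
      return(ref$lineage_count[ref$day == 3])
    }
    stats::approx(ref$day, ref$lineage_count, xout = d)$y
  }, numeric(1))
  tibble::tibble(day = days, lineage_count = value)
}

#' Calibrate proportions to absolute densities
#'
#' For each day `d`, the scale factor is `S(d) = T(d) / P_lineage(d)`,
#' where `T(d)` is the (interpolated) reference monocyte/macrophage-lineage
#' density and `P_lineage(d)` the cross-replicate mean of the summed M, M1
#' and M2 proportions. The calibrated target for cell type `X` is
#' `S(d) * mean P_X(d)` and its spread is `S(d)` times the cross-replicate
#' sample standard deviation of `P_X(d)` (0 when a day has one replicate).
#' By construction the calibrated M + M1 + M2 total equals the reference
#' density exactly.
#'
#' The dead populations are never observed; when `dead_cell_targets = TRUE`
#' (default), fixed day-7 targets of a single cell each are appended for
#' `Md` and `Nd`, encoding that debris is essentially gone by day 7.
#'
#' @param props A proportion table from [proportions_from_counts()].
#' @param ref Reference lineage table; default
#'   [reference_lineage_counts()].
#' @param dead_cell_targets Append the fixed `Md`/`Nd` day-7 targets?
#' @return A `calibrated_targets` tibble
#'   `(day, cell_type, target, sd, scale_factor)` in cells/mm^3.
#' @export
calibrate_targets <- function(props, ref = reference_lineage_counts(),
                              dead_cell_targets = TRUE) {
  props <- tibble::as_tibble(props)
  stopifnot(all(c("day", "replicate", "cell_type", "proportion") %in%
                  names(props)))
  observable_or_stop(props$cell_type)
  stats_tbl <- props |>
    dplyr::group_by(.data$day, .data$cell_type) |>
    dplyr::summarise(
      mean_p = mean(.data$proportion),
      sd_p = ifelse(dplyr::n() > 1, stats::sd(.data$proportion), 0),
      .groups = "drop"
    )
  lineage <- stats_tbl |>
    dplyr::filter(.data$cell_type %in% c("M", "M1", "M2")) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(p_lineage = sum(.data$mean_p), .groups = "drop")
  if (any(lineage$p_lineage == 0)) {
    stop("zero monocyte/macrophage-lineage proportion at day ",
         lineage$day[lineage$p_lineage == 0][1],
         "; scale factor undefined", call. = FALSE)
  }
  ref_at <- interpolate_reference(ref, lineage$day)
  scale_tbl <- dplyr::mutate(
    dplyr::left_join(lineage, ref_at, by = "day"),
    scale_factor = .data$lineage_count / .data$p_lineage
  )
  out <- stats_tbl |>
    dplyr::left_join(dplyr::select(scale_tbl, "day", "scale_factor"),
                     by = "day") |>
    dplyr::transmute(
      day = .data$day, cell_type = .data$cell_type,
      target = .data$scale_factor * .data$mean_p,
      sd = .data$scale_factor * .data$sd_p,
      scale_factor = .data$scale_factor
    )
  if (dead_cell_targets) {
    out <- dplyr::bind_rows(out, dead_cell_day7_targets())
  }
  out <- dplyr::arrange(out, .data$day,
                        match(.data$cell_type, state_names))
  structure(out, class = c("calibrated_targets", class(out)))
}

#' Fixed day-7 targets for the dead populations
#'
#' A single cell/mm^3 each for damaged myonuclei and dead neutrophils at
#' day 7 — debris should be essentially cleared by then. These carry no
#' scale factor and zero spread.
#'
#' @return A tibble in the `calibrated_targets` column layout.
#' @export
dead_cell_day7_targets <- function() {
  tibble::tibble(day = 7, cell_type = c("Md", "Nd"),
                 target = 1, sd = 0, scale_factor = NA_real_)
}

#' Plot calibrated targets
#'
#' Mean +/- one cross-replicate standard deviation per day and population.
#'
#' @param object A `calibrated_targets` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibrated_targets <- function(object, ...) {
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       cell_type = factor(.data$cell_type,
                                          levels = state_names))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$target)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$target - .data$sd, 0),
      ymax = .data$target + .data$sd
    ), linewidth = 0.4, size = 0.3) +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::labs(x = "days post-injury", y = "cells / mm^3") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("day", "replicate"))
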