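# Synthetic replicate-structured count tables with the statistical shape of
# the annotated single-cell time series: per-day replicates, library-size
# scale counts, a lumped "other" category of unmodeled cell types that is
# discarded before proportions are taken, and Dirichlet-multinomial
# cross-replicate proportion noise.

#' Configuration of a synthetic study
#'
#' Defaults mirror the training study's design: six sampling days with 4,
#' 4, 3, 4, 3 and 3 replicates, 10,000-20,000 cells sequenced per
#' replicate, and half of each library belonging to unmodeled cell types
#' (fibro-adipogenic, endothelial, etc.) that are generated as one lumped
#' category and discarded before proportions are computed. Cross-replicate
#' variability is Dirichlet: replicate proportions are drawn from
#' `Dirichlet(dispersion * p_true)`; smaller `dispersion` means noisier
#' replicates (the default 30 gives cross-replicate standard deviations of
#' several percentage points on mid-sized proportions, of the order seen in
#' the real replicates). `dispersion = Inf` disables proportion noise.
#'
#' @param days Sampling days.
#' @param replicates Replicates per day (recycled to `length(days)`).
#' @param cells_range Min/max total cells sequenced per replicate (before
#'   discarding the unmodeled category).
#' @param other_fraction Expected fraction of unmodeled cells per library.
#' @param dispersion Dirichlet concentration multiplier (> 0 or `Inf`).
#' @param ref_days Days at which reference lineage densities are reported.
#' @param ref_noise_sdlog Standard deviation of multiplicative lognormal
#'   noise on the reference lineage densities (0 = noise-free).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `synthetic_study_config` list.
#' @export
synthetic_study_config <- function(days = c(0, 1, 2, 3.5, 5, 7),
                                   replicates = c(4, 4, 3, 4, 3, 3),
                                   cells_range = c(10000, 20000),
                                   other_fraction = 0.5,
                                   dispersion = 30,
                                   ref_days = c(0, 1, 3, 7),
                                   ref_noise_sdlog = 0,
                                   seed = 1L) {
  days <- sort(as.numeric(days))
  replicates <- rep_len(as.integer(replicates), length(days))
  stopifnot(all(replicates >= 1), length(cells_range) == 2,
            cells_range[1] >= 1, cells_range[2] >= cells_range[1],
            other_fraction >= 0, other_fraction < 1,
            dispersion > 0, ref_noise_sdlog >= 0)
  structure(list(
    days = days, replicates = replicates, cells_range = cells_range,
    other_fraction = other_fraction, dispersion = dispersion,
    ref_days = sort(as.numeric(ref_days)),
    ref_noise_sdlog = ref_noise_sdlog, seed = as.integer(seed)
  ), class = "synthetic_study_config")
}

# Dirichlet draw proportional to alpha; zero-alpha components stay exactly
# zero (a population absent from the true composition never appears).
rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
  g / sum(g)
}

#' Generate a ground-truth dataset from known parameters
#'
#' Forward-simulate the model at the configured days, then observe it the
#' way the single-cell study does: per replicate, draw a library size, draw
#' replicate-level observable proportions from a Dirichlet centered on the
#' true composition, allocate cells by multinomial sampling across the
#' seven observable types plus a lumped unmodeled category, and discard the
#' unmodeled category. Reference lineage densities are the true M + M1 +
#' M2 densities at the configured reference days (optionally with
#' lognormal noise). The true per-day observable densities are returned as
#' a `calibrated_targets` table for recovery scoring.
#'
#' @param params A [rate_parameters()] vector (the ground truth).
#' @param initial Day-0 [cell_state()].
#' @param cfg A [synthetic_study_config()].
#' @return A list with `counts` (tibble `day, replicate, cell_type,
#'   count`), `reference` (tibble `day, lineage_count`), and `truth`
#'   (`calibrated_targets` of the true densities, sd 0).
#' @examples
#' gt <- generate_ground_truth(fitted_rate_parameters(),
#'                             default_initial_state(),
#'                             synthetic_study_config(seed = 7))
#' head(gt$counts)
#' @export
generate_ground_truth <- function(params, initial,
                                  cfg = synthetic_study_config()) {
  stopifnot(inherits(cfg, "synthetic_study_config"))
  params <- as_rate_parameters(params)
  initial <- as_cell_state(initial)
  withr::local_seed(cfg$seed)
  sim_days <- sort(unique(c(0, cfg$days, cfg$ref_days)))
  traj <- simulate_regeneration(params, initial, grid = sim_days)
  dens <- as.matrix(tibble::as_tibble(traj)[observable_names])
  rownames(dens) <- as.character(traj$time)
  counts <- purrr::map2_dfr(cfg$days, cfg$replicates, function(d, k) {
    true_d <- dens[as.character(d), ]
    if (sum(true_d) == 0) {
      stop("all observable densities are zero at day ", d, call. = FALSE)
    }
    p_true <- true_d / sum(true_d)
    purrr::map_dfr(seq_len(k), function(r) {
      p_rep <- if (is.finite(cfg$dispersion)) {
        rdirichlet1(cfg$dispersion * p_true)
      } else p_true
      n_cells <- round(stats::runif(1, cfg$cells_range[1],
                                    cfg$cells_range[2]))
      probs <- c(p_rep * (1 - cfg$other_fraction), cfg$other_fraction)
      drawn <- stats::rmultinom(1, size = n_cells, prob = probs)[, 1]
      tibble::tibble(day = d, replicate = r,
                     cell_type = observable_names,
                     count = as.integer(drawn[seq_along(observable_names)]))
    })
  })
  lineage_true <- rowSums(dens[as.character(cfg$ref_days), c("M", "M1", "M2"),
                               drop = FALSE])
  lineage <- if (cfg$ref_noise_sdlog > 0) {
    lineage_true * stats::rlnorm(length(lineage_true), 0,
                                 cfg$ref_noise_sdlog)
  } else lineage_true
  reference <- tibble::tibble(day = cfg$ref_days,
                              lineage_count = as.numeric(lineage))
  truth <- purrr::map_dfr(cfg$days, function(d) {
    tibble::tibble(day = d, cell_type = observable_names,
                   target = dens[as.character(d), ], sd = 0,
                   scale_factor = NA_real_)
  })
  truth <- structure(truth, class = c("calibrated_targets", class(truth)))
  list(counts = counts, reference = reference, truth = truth)
}

#' Generate a validation-style count table
#'
#' Same generative process as [generate_ground_truth()], but restricted to
#' the validation study's day structure `{0, 2, 5, 7}` (no day-1 sample)
#' with 4, 3, 4 and 3 replicates. Returns the count table only.
#'
#' @inheritParams generate_ground_truth
#' @param cfg A [synthetic_study_config()]; its `days`/`replicates` are
#'   replaced by the validation design.
#' @return A tibble `(day, replicate, cell_type, count)`.
#' @export
generate_validation_set <- function(params, initial,
                                    cfg = synthetic_study_config()) {
  stopifnot(inherits(cfg, "synthetic_study_config"))
  cfg$days <- c(0, 2, 5, 7)
  cfg$replicates <- rep_len(c(4L, 3L, 4L, 3L), 4)
  generate_ground_truth(params, initial, cfg)$counts
}

#' Write a synthetic dataset to CSV files
#'
#' Writes `counts.csv`, `reference.csv` and `truth.csv` in the schemas the
#' calibration functions read.
#'
#' @param dataset Output of [generate_ground_truth()].
#' @param path Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_synthetic_csv <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(path, "counts.csv"),
             reference = file.path(path, "reference.csv"),
             truth = file.path(path, "truth.csv"))
  readr::write_csv(dataset$counts, paths["counts"])
  readr::write_csv(dataset$reference, paths["reference"])
  readr::write_csv(tibble::as_tibble(dataset$truth), paths["truth"])
  invisible(paths)
}
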