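test_that("the generator honors the configured study design", {
  cfg <- synthetic_study_config(seed = 21)
  gt <- generate_ground_truth(fitted_rate_parameters(),
                              default_initial_state(), cfg)
  design <- gt$counts |>
    dplyr::distinct(day, replicate) |>
    dplyr::count(day)
  expect_equal(design$day, c(0, 1, 2, 3.5, 5, 7))
  expect_equal(design$n, c(4, 4, 3, 4, 3, 3))
  expect_true(all(gt$counts$cell_type %in% observable_cell_types()))
  expect_false(any(gt$counts$cell_type %in% c("Md", "Nd")))
  # library sizes land in the configured range net of the discarded half
  totals <- gt$counts |>
    dplyr::group_by(day, replicate) |>
    dplyr::summarise(n = sum(count), .groups = "drop")
  expect_true(all(totals$n > 3000 & totals$n < 12000))
  expect_equal(gt$reference$day, c(0, 1, 3, 7))
})

test_that("identical seeds reproduce the dataset; different seeds vary", {
  a <- generate_ground_truth(fitted_rate_parameters(),
                             default_initial_state(),
                             synthetic_study_config(seed = 33))
  b <- generate_ground_truth(fitted_rate_parameters(),
                             default_initial_state(),
                             synthetic_study_config(seed = 33))
  cc <- generate_ground_truth(fitted_rate_parameters(),
                              default_initial_state(),
                              synthetic_study_config(seed = 34))
  expect_identical(a$counts, b$counts)
  expect_identical(a$reference, b$reference)
  expect_false(identical(a$counts, cc$counts))
})

test_that("validation-style sets use the four-day design without day 1", {
  vs <- generate_validation_set(fitted_rate_parameters(),
                                default_initial_state(),
                                synthetic_study_config(seed = 5))
  expect_equal(sort(unique(vs$day)), c(0, 2, 5, 7))
  expect_false(1 %in% vs$day)
  vs2 <- generate_validation_set(fitted_rate_parameters(),
                                 default_initial_state(),
                                 synthetic_study_config(seed = 5))
  expect_identical(vs, vs2)
})

test_that("with no noise and huge libraries calibration recovers truth", {
  cfg <- synthetic_study_config(dispersion = Inf,
                                cells_range = c(1e7, 1e7),
                                ref_days = c(0, 1, 2, 3.5, 5, 7),
                                seed = 3)
  gt <- generate_ground_truth(fitted_rate_parameters(),
                              default_initial_state(), cfg)
  tg <- calibrate_targets(proportions_from_counts(gt$counts),
                          gt$reference, dead_cell_targets = FALSE)
  joined <- dplyr::left_join(
    tibble::as_tibble(tg), tibble::as_tibble(gt$truth),
    by = c("day", "cell_type"), suffix = c("_est", "_true")
  )
  scale <- pmax(joined$target_true, 0.01 * max(joined$target_true))
  expect_lt(max(abs(joined$target_est - joined$target_true) / scale), 0.01)
})

test_that("lower dispersion means noisier replicate proportions", {
  mean_sd <- function(disp, seed) {
    cfg <- synthetic_study_config(dispersion = disp, seed = seed)
    gt <- generate_ground_truth(fitted_rate_parameters(),
                                default_initial_state(), cfg)
    proportions_from_counts(gt$counts) |>
      dplyr::group_by(day, cell_type) |>
      dplyr::summarise(s = stats::sd(proportion), .groups = "drop") |>
      dplyr::pull(s) |>
      mean()
  }
  seeds <- 101:103
  lo <- mean(vapply(seeds, function(s) mean_sd(3, s), numeric(1)))
  mid <- mean(vapply(seeds, function(s) mean_sd(30, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) mean_sd(300, s), numeric(1)))
  expect_gt(lo, mid)
  expect_gt(mid, hi)
})

test_that("generation fails cleanly when nothing is observable", {
  cfg <- synthetic_study_config(seed = 2)
  expect_error(
    generate_ground_truth(fitted_rate_parameters(), cell_state(Md = 1000),
                          cfg),
    "all observable densities are zero"
  )
})

test_that("synthetic CSV files round trip through the calibration readers", {
  gt <- generate_ground_truth(fitted_rate_parameters(),
                              default_initial_state(),
                              synthetic_study_config(seed = 12))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_csv(gt, dir)
  counts <- readr::read_csv(paths[["counts"]], show_col_types = FALSE)
  expect_equal(nrow(counts), nrow(gt$counts))
  tg <- calibrate_targets(proportions_from_counts(counts),
                          readr::read_csv(paths[["reference"]],
                                          show_col_types = FALSE))
  expect_s3_class(tg, "calibrated_targets")
})

test_that("end-to-end: generate, calibrate, fit, score on the truth", {
  gt <- generate_ground_truth(fitted_rate_parameters(),
                              default_initial_state(),
                              synthetic_study_config(seed = 2026))
  targets <- calibrate_targets(proportions_from_counts(gt$counts),
                               gt$reference)
  spec <- heuristic_initial_estimates()
  fit <- fit_parameters(spec, targets, default_initial_state(),
                        max_evals = 4000, restarts = 1, adaptive = TRUE)
  init_params <- rate_parameters(stats::setNames(spec$initial,
                                                 spec$parameter))
  e_true_initial <- fit_error(init_params, gt$truth,
                              default_initial_state())
  e_true_fitted <- fit_error(fit$parameters, gt$truth,
                             default_initial_state())
  expect_lt(e_true_fitted, 0.25 * e_true_initial)
})
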