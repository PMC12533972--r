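test_that("satellite-cell parameters cannot move the immune populations", {
  sens <- fitted_sensitivity()
  for (v in immune_states) {
    block <- sens$raw[[v]][satellite_params, ]
    expect_identical(max(abs(block)), 0)
  }
  # but they do move the myogenic populations
  expect_gt(max(abs(sens$raw$ASC[satellite_params, ])), 0)
})

test_that("matrices are scaled to [-1, 1] with a unit-magnitude entry", {
  sens <- fitted_sensitivity()
  for (v in state_order) {
    m <- sens$normalized[[v]]
    expect_true(all(m >= -1 & m <= 1))
    if (max(abs(sens$raw[[v]])) > 0) {
      expect_identical(max(abs(m)), 1)
    }
    # normalizing an already-normalized matrix changes nothing
    expect_identical(myoregen:::normalize_sensitivity(m), m)
  }
  # the day-0 column is identically zero: perturbations share the initial state
  expect_equal(max(abs(sens$normalized$N[, 1])), 0)
})

test_that("neutrophil-influx perturbation flips sign on dead neutrophils", {
  sens <- fitted_sensitivity()
  nd <- sens$normalized$Nd["cNin", ]
  t <- sens$time
  expect_true(all(nd[t > 0 & t <= 1] > 0))
  expect_true(all(nd[t >= 2] < 0))
  # crossover strictly between days 1 and 2
  expect_equal(sum(diff(sign(nd[t >= 1 & t <= 2])) != 0), 1)
})

test_that("one-sided and central differences agree in sign", {
  params <- fitted_rate_parameters()
  init <- default_initial_state()
  sens <- fitted_sensitivity()
  delta <- sens$rel_delta
  withr::local_seed(88)
  picks <- 0
  while (picks < 5) {
    pn <- sample(param_order, 1)
    v <- sample(state_order, 1)
    j <- sample(seq_along(sens$time), 1)
    raw <- unname(sens$raw[[v]][pn, j])
    traj_max <- max(fitted_hourly_trajectory()[[v]])
    if (abs(raw) <= 1e-6 * traj_max) next
    up <- replace(unclass(params), pn, unclass(params)[[pn]] * (1 + delta))
    dn <- replace(unclass(params), pn, unclass(params)[[pn]] * (1 - delta))
    s_up <- simulate_regeneration(rate_parameters(up), init, grid = "hourly")
    s_dn <- simulate_regeneration(rate_parameters(dn), init, grid = "hourly")
    central <- (s_up[[v]][j] - s_dn[[v]][j]) / 2
    expect_identical(sign(central), sign(raw))
    picks <- picks + 1
  }
})

test_that("derivative scaling only rescales rows, preserving signs", {
  sens_raw <- fitted_sensitivity()
  sens_der <- perturbation_sensitivity(fitted_rate_parameters(),
                                       default_initial_state(),
                                       derivative = TRUE,
                                       grid = c(0, 1, 2, 3))
  raw_short <- perturbation_sensitivity(fitted_rate_parameters(),
                                        default_initial_state(),
                                        grid = c(0, 1, 2, 3))
  for (v in c("Md", "N", "ASC")) {
    both <- sens_der$raw[[v]] != 0 & raw_short$raw[[v]] != 0
    expect_identical(sign(sens_der$raw[[v]][both]),
                     sign(raw_short$raw[[v]][both]))
    expect_gt(sum(both), 0)
  }
  expect_false(sens_der$derivative == raw_short$derivative)
})

test_that("export writes faithful CSV matrices and heatmap images", {
  sens <- perturbation_sensitivity(fitted_rate_parameters(),
                                   default_initial_state(),
                                   grid = c(0, 1, 2, 3.5, 5, 7))
  dir <- withr::local_tempdir()
  files <- export_sensitivity(sens, dir, image = TRUE)
  csvs <- files$file[grepl("[.]csv$", files$file)]
  expect_length(csvs, 9)
  back <- read_sensitivity_csv(file.path(dir, "sensitivity_Md.csv"))
  expect_identical(unname(back), unname(sens$normalized$Md))
  pngs <- files$file[grepl("[.]png$", files$file)]
  expect_true(all(file.exists(pngs)))
  expect_true(all(file.size(pngs) > 0))
})

test_that("a zero initial state yields an all-zero, all-white tensor", {
  sens0 <- perturbation_sensitivity(fitted_rate_parameters(), cell_state(),
                                    grid = c(0, 1, 2))
  expect_identical(max(abs(do.call(cbind, sens0$normalized))), 0)
  dir <- withr::local_tempdir()
  export_sensitivity(sens0, dir, image = FALSE)
  back <- read_sensitivity_csv(file.path(dir, "sensitivity_QSC.csv"))
  expect_identical(max(abs(back)), 0)
})

test_that("invalid perturbation sizes are rejected", {
  expect_error(perturbation_sensitivity(fitted_rate_parameters(),
                                        default_initial_state(),
                                        rel_delta = 0), "rel_delta")
})
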