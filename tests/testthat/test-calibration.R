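obs_types <- observable_cell_types()

test_that("proportions divide counts by the replicate total", {
  counts <- counts_from_props(1, list(
    `1` = stats::setNames(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.4), obs_types)
  ), total = 100)
  props <- proportions_from_counts(counts)
  expect_equal(props$proportion,
               c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.4))

  single <- tibble::tibble(day = 0, replicate = 1, cell_type = "QSC",
                           count = 57)
  props <- proportions_from_counts(single)
  expect_equal(nrow(props), 7)  # absent types filled with zeros
  expect_equal(props$proportion[props$cell_type == "QSC"], 1)
  expect_equal(sum(props$proportion), 1)
})

test_that("proportions sum to one and are scale invariant", {
  withr::local_seed(5)
  for (i in 1:10) {
    counts <- tidyr::expand_grid(day = c(0, 2), replicate = 1:3,
                                 cell_type = obs_types)
    counts$count <- stats::rpois(nrow(counts), 40) + 1
    props <- proportions_from_counts(counts)
    sums <- props |>
      dplyr::group_by(day, replicate) |>
      dplyr::summarise(s = sum(proportion), .groups = "drop")
    expect_equal(sums$s, rep(1, 6), tolerance = 1e-9)

    # multiplying one replicate's counts by a constant changes nothing
    scaled <- dplyr::mutate(
      counts, count = ifelse(replicate == 2, count * 13L, count))
    expect_equal(calibrate_targets(proportions_from_counts(scaled)),
                 calibrate_targets(props))
  }
})

test_that("count tables are validated at load", {
  bad <- tibble::tibble(day = 0, replicate = 1,
                        cell_type = c("N", "FAP"), count = c(5, 7))
  expect_error(proportions_from_counts(bad), "FAP")
  zero <- tibble::tibble(day = 2, replicate = 3, cell_type = "N", count = 0)
  expect_error(proportions_from_counts(zero), "day 2.*replicate 3")
})

test_that("reference interpolation is linear with the day-3.5 reuse rule", {
  at <- interpolate_reference(days = c(0, 1, 2, 3.5, 5, 7))
  expect_equal(at$lineage_count, c(100, 5000, 12500, 20000, 12500, 5000))
  expect_error(interpolate_reference(days = 8), "outside")
  expect_error(interpolate_reference(days = -0.5), "outside")
  # a reference that does measure day 3.5 is used as-is, not substituted
  ref2 <- tibble::tibble(day = c(3, 3.5, 4), lineage_count = c(10, 77, 20))
  expect_equal(interpolate_reference(ref2, 3.5)$lineage_count, 77)
})

test_that("calibration applies the per-day lineage scale factor", {
  # two replicates whose mean lineage proportion is 0.5 at day 1:
  # scale = 5000 / 0.5 = 10000; a type with mean proportion 0.002 -> 20
  p1 <- stats::setNames(c(0.25, 0.2, 0.15, 0.2, 0.198, 0.002, 0), obs_types)
  p2 <- stats::setNames(c(0.25, 0.2, 0.1, 0.15, 0.298, 0.002, 0), obs_types)
  props <- dplyr::bind_rows(
    tibble::tibble(day = 1, replicate = 1L, cell_type = obs_types,
                   proportion = p1),
    tibble::tibble(day = 1, replicate = 2L, cell_type = obs_types,
                   proportion = p2)
  )
  tg <- calibrate_targets(props, dead_cell_targets = FALSE)
  expect_equal(unique(tg$scale_factor), 10000)
  expect_equal(tg$target[tg$cell_type == "ASC"], 20)
  # sd is the scale factor times the cross-replicate sample sd
  expect_equal(tg$sd[tg$cell_type == "M1"], 10000 * stats::sd(c(0.15, 0.1)))

  # single replicate: all sds are zero
  tg1 <- calibrate_targets(props[props$replicate == 1, ],
                           dead_cell_targets = FALSE)
  expect_equal(tg1$sd, rep(0, 7))
})

test_that("calibrated lineage totals reproduce the reference exactly", {
  withr::local_seed(31)
  counts <- tidyr::expand_grid(day = c(0, 1, 2, 3.5, 5, 7),
                               replicate = 1:3, cell_type = obs_types)
  counts$count <- stats::rpois(nrow(counts), 60) + 1
  tg <- calibrate_targets(proportions_from_counts(counts))
  lineage <- tg |>
    dplyr::filter(cell_type %in% c("M", "M1", "M2")) |>
    dplyr::group_by(day) |>
    dplyr::summarise(total = sum(target), .groups = "drop")
  expect_equal(lineage$total, c(100, 5000, 12500, 20000, 12500, 5000),
               tolerance = 1e-9)
  # dead-cell fixed targets attached at day 7
  expect_equal(tg$target[tg$cell_type %in% c("Md", "Nd")], c(1, 1))
  expect_equal(tg$day[tg$cell_type %in% c("Md", "Nd")], c(7, 7))
})

test_that("calibration inverts proportions built from known densities", {
  dens <- stats::setNames(c(120, 800, 1500, 2700, 90, 45, 15), obs_types)
  props <- tibble::tibble(day = 1, replicate = 1L, cell_type = obs_types,
                          proportion = dens / sum(dens))
  ref <- tibble::tibble(day = c(0, 1, 7),
                        lineage_count = c(1, 800 + 1500 + 2700, 1))
  tg <- calibrate_targets(props, ref, dead_cell_targets = FALSE)
  expect_equal(tg$target[match(obs_types, tg$cell_type)], unname(dens),
               tolerance = 1e-12)
})
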