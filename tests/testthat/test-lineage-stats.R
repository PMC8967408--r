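test_that("cycle times cover divided cells only", {
  ct <- cycle_times(toy_forest())
  expect_equal(nrow(ct), 1)
  expect_equal(ct$cycle_time, 2.7)
  # no divisions -> empty
  nodiv <- lineage_forest(data.frame(
    cell_id = "a", parent_id = NA, birth_time = 0, end_time = 5,
    end_fate = "censored"
  ))
  expect_equal(nrow(cycle_times(nodiv)), 0)
})

test_that("cycle-time summary uses the sample standard deviation", {
  s <- cycle_time_summary(c(4, 4, 4))
  expect_equal(unlist(s[c("mean", "sd", "cv")]),
               c(mean = 4, sd = 0, cv = 0))
  s2 <- cycle_time_summary(c(3, 5))
  expect_equal(s2$mean, 4)
  expect_equal(s2$sd, sqrt(2))
  expect_equal(s2$cv, sqrt(2) / 4, tolerance = 1e-12)
  expect_error(cycle_time_summary(4), "at least 2")
})

test_that("per-capita division rate matches the window-mean convention", {
  rs <- division_rate(rate_fixture_forest(), window = 0.875,
                      grid_step = 0.25, t_range = c(1, 9))
  at5 <- rs$rate[abs(rs$time - 5) < 1e-9]
  expect_equal(at5, 1 / (0.875 * 2.5), tolerance = 1e-12)
  # instantaneous denominator counts 3 alive at t = 5
  rs_i <- division_rate(rate_fixture_forest(), window = 0.875,
                        grid_step = 0.25, t_range = c(1, 9),
                        denominator = "instantaneous")
  expect_equal(rs_i$rate[abs(rs_i$time - 5) < 1e-9], 1 / (0.875 * 3),
               tolerance = 1e-12)
  # no divisions anywhere -> rate identically zero
  nodiv <- lineage_forest(data.frame(
    cell_id = c("a", "b"), parent_id = c(NA, NA), birth_time = c(0, 0),
    end_time = c(10, 10), end_fate = "censored"
  ))
  rs0 <- division_rate(nodiv, t_range = c(1, 9))
  expect_true(all(rs0$rate == 0))
})

test_that("event-rate integral identities hold on simulated forests", {
  forest <- simulate_growth(fast_config(), seed = 3)$forest
  total_div <- sum(forest$cells$end_fate == "divided")
  # tiling top-hat windows recover the total division count for any width
  for (w in c(0.5, 0.875, 2)) {
    grid <- seq(min(forest$cells$birth_time) + w / 2,
                forest$movie_end + w, by = w)
    rs <- division_rate(forest, window = w, grid_step = w,
                        t_range = range(grid))
    expect_equal(sum(rs$rate * rs$nbar * w, na.rm = TRUE), total_div,
                 tolerance = 1e-9)
  }
})

test_that("spectrum identifies oscillation frequency and flags bad grids", {
  tt <- seq(16, 28.375, by = 0.125)
  flat <- tibble::tibble(time = tt, rate = 0.2)
  sp <- division_rate_spectrum(flat, t_max = 28.5)
  expect_equal(max(sp$magnitude[sp$frequency > 0]), 0, tolerance = 1e-12)
  osc <- tibble::tibble(time = tt, rate = 0.2 + 0.05 * sin(2 * pi * tt / 4))
  spo <- division_rate_spectrum(osc, t_max = 28.5)
  expect_lt(abs(dominant_frequency(spo) - 0.25), 0.05)
  bad <- tibble::tibble(time = c(16, 16.1, 16.3, 16.7, 17.5),
                        rate = 1:5)
  expect_error(division_rate_spectrum(bad), "resample")
})

test_that("peak counting respects prominence", {
  tt <- seq(16, 28, by = 0.125)
  mono <- tibble::tibble(time = tt, rate = tt / 30)
  expect_equal(count_peaks(mono, 16, 28), 0L)
  sin4 <- tibble::tibble(time = tt, rate = 1 + 0.3 * sin(2 * pi * tt / 4))
  expect_equal(count_peaks(sin4, 16, 28), 3L)
})

test_that("growth decomposition splits the expansion exactly", {
  # constant cell count, every area doubled -> all from area change
  cells <- data.frame(cell_id = c("a", "b"), parent_id = c(NA, NA),
                      birth_time = 0, end_time = 10, end_fate = "censored")
  areas <- tidyr::expand_grid(cell_id = c("a", "b"), t = c(0, 5, 10)) |>
    dplyr::mutate(area = 10 * 2^(t / 10))
  gd <- growth_decomposition(lineage_forest(cells, areas = areas,
                                            movie_end = 10))
  last <- gd[nrow(gd), ]
  expect_equal(last$cum_total, log(2), tolerance = 1e-12)
  expect_equal(last$cum_area_change, log(2), tolerance = 1e-12)
  expect_equal(last$cum_division, 0)
  expect_equal(last$cum_extrusion, 0)

  # one division among constant areas: division ln(3/2) offset by mean area
  cells2 <- data.frame(
    cell_id = c("a", "m", "d1", "d2"), parent_id = c(NA, NA, "m", "m"),
    birth_time = c(0, 0, 1.5, 1.5), end_time = c(3, 1.5, 3, 3),
    end_fate = c("censored", "divided", "censored", "censored")
  )
  areas2 <- dplyr::bind_rows(
    tibble::tibble(cell_id = "a", t = c(0, 1, 2, 3), area = 12),
    tibble::tibble(cell_id = "m", t = c(0, 1), area = 12),
    tibble::tibble(cell_id = "d1", t = c(2, 3), area = 6),
    tibble::tibble(cell_id = "d2", t = c(2, 3), area = 6)
  )
  gd2 <- growth_decomposition(lineage_forest(cells2, areas = areas2,
                                             movie_end = 3))
  last2 <- gd2[nrow(gd2), ]
  expect_equal(last2$cum_total, 0, tolerance = 1e-12)
  expect_equal(last2$cum_division, log(3 / 2), tolerance = 1e-12)
  expect_equal(last2$cum_area_change, -log(3 / 2), tolerance = 1e-12)

  # one extrusion, constant areas of survivors -> negative extrusion term
  cells3 <- data.frame(
    cell_id = c("a", "b", "x"), parent_id = NA,
    birth_time = 0, end_time = c(4, 4, 2),
    end_fate = c("censored", "censored", "extruded")
  )
  areas3 <- dplyr::bind_rows(
    tidyr::expand_grid(cell_id = c("a", "b"), t = c(0, 1, 3, 4)) |>
      dplyr::mutate(area = 10),
    tibble::tibble(cell_id = "x", t = c(0, 1), area = 10)
  )
  gd3 <- growth_decomposition(lineage_forest(cells3, areas = areas3,
                                             movie_end = 4))
  expect_equal(gd3$cum_extrusion[nrow(gd3)], log(2 / 3), tolerance = 1e-12)
  # missing area for an alive cell is reported with cell and frame
  expect_error(
    growth_decomposition(lineage_forest(cells3, areas = areas3[-1, ],
                                        movie_end = 4)),
    "a.*frame"
  )
})

test_that("decomposition closure holds on randomized exact-area forests", {
  for (seed in 1:20) {
    forest <- random_area_forest(seed)
    gd <- growth_decomposition(forest)
    gap <- gd$cum_total -
      (gd$cum_division + gd$cum_area_change + gd$cum_extrusion)
    expect_lt(max(abs(gap)), 1e-9)
  }
})

test_that("sister pairs with identical cycle times correlate perfectly", {
  cells <- data.frame(
    cell_id = c("m1", "m2", "s1a", "s1b", "s2a", "s2b",
                "g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8"),
    parent_id = c(NA, NA, "m1", "m1", "m2", "m2",
                  "s1a", "s1a", "s1b", "s1b", "s2a", "s2a", "s2b", "s2b"),
    birth_time = c(0, 0, 3, 3, 3, 3, 6, 6, 6, 6, 8, 8, 8, 8),
    end_time = c(3, 3, 6, 6, 8, 8, 12, 12, 12, 12, 12, 12, 12, 12),
    end_fate = c(rep("divided", 6), rep("censored", 8))
  )
  forest <- lineage_forest(cells, movie_end = 12)
  res <- pair_correlations(forest, "sister", seed = 1)
  expect_equal(res$pearson, 1)
  expect_equal(res$n_pairs, 2)
})

test_that("degenerate pair sets raise errors", {
  expect_error(pair_correlations(toy_forest(), "sister"), "at least 2")
  # both pairs identical values -> zero variance
  cells <- data.frame(
    cell_id = c("m1", "m2", "a", "b", "c", "d", "k1", "k2", "k3", "k4",
                "k5", "k6", "k7", "k8"),
    parent_id = c(NA, NA, "m1", "m1", "m2", "m2",
                  "a", "a", "b", "b", "c", "c", "d", "d"),
    birth_time = c(0, 0, 2, 2, 2, 2, rep(5, 8)),
    end_time = c(2, 2, 5, 5, 5, 5, rep(9, 8)),
    end_fate = c(rep("divided", 6), rep("censored", 8))
  )
  forest <- lineage_forest(cells, movie_end = 9)
  expect_error(pair_correlations(forest, "sister"), "zero variance")
})

test_that("arrest labels follow the movie-end definition", {
  cells <- data.frame(
    cell_id = c("stay", "div", "d1", "d2", "sop", "lost"),
    parent_id = c(NA, NA, "div", "div", NA, NA),
    birth_time = c(20, 20, 25, 25, 20, 20),
    end_time = c(33, 25, 33, 33, 33, 30),
    end_fate = c("censored", "divided", "censored", "censored",
                 "censored", "censored"),
    is_sop = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  forest <- label_arrested(lineage_forest(cells, movie_end = 33))
  flags <- setNames(forest$cells$arrested, forest$cells$cell_id)
  expect_true(flags[["stay"]])
  expect_true(flags[["d1"]])
  expect_false(flags[["div"]])  # divided cells are never arrested
  expect_false(flags[["sop"]])  # SOPs counted in their own class
  expect_false(flags[["lost"]]) # censored before movie_end
  # min_followup excludes short-lived censored cells
  f2 <- label_arrested(lineage_forest(cells, movie_end = 33),
                       min_followup = 10)
  expect_false(f2$cells$arrested[f2$cells$cell_id == "d1"])
  expect_true(f2$cells$arrested[f2$cells$cell_id == "stay"])
})

test_that("lineage statistics are invariant under record permutation", {
  forest <- simulate_growth(fast_config(), seed = 9)$forest
  set.seed(1)
  perm <- forest
  perm$cells <- perm$cells[sample(nrow(perm$cells)), ]
  ct1 <- dplyr::arrange(cycle_times(forest), cell_id)
  ct2 <- dplyr::arrange(cycle_times(perm), cell_id)
  expect_equal(ct1, ct2)
  r1 <- division_rate(forest, t_range = c(16, 28))
  r2 <- division_rate(perm, t_range = c(16, 28))
  expect_equal(r1$rate, r2$rate)
  a1 <- label_arrested(forest)$cells
  a2 <- label_arrested(perm)$cells
  expect_equal(dplyr::arrange(a1, cell_id)$arrested,
               dplyr::arrange(a2, cell_id)$arrested)
})

test_that("binned relations reproduce exact structure", {
  df <- tibble::tibble(x = seq(0, 1, length.out = 40), y = 2)
  br <- binned_relation(df, x, y, n_bins = 4)
  expect_true(all(br$y_mean == 2))
  expect_true(all(br$y_sem == 0))
  df2 <- tibble::tibble(x = seq(0, 1, length.out = 40))
  df2$y <- 2 * df2$x
  br2 <- binned_relation(df2, x, y, n_bins = 4)
  expect_equal(br2$y_mean, 2 * br2$x_mean, tolerance = 1e-12)
  expect_error(binned_relation(tibble::tibble(x = numeric(), y = numeric()),
                               x, y), "empty")
})

test_that("no x-y dependence yields a flat binned slope", {
  set.seed(1)
  df <- tibble::tibble(x = runif(400, 10, 40), y = rnorm(400, 4.5, 1))
  br <- binned_relation(df, x, y, n_bins = 8)
  fit <- summary(lm(y_mean ~ x_mean, data = br, weights = br$n))
  tstat <- fit$coefficients["x_mean", "t value"]
  expect_lt(abs(tstat), 2)
})

test_that("neighbour cycle-time correlation detects spatial structure", {
  # two spatial blocks with block-constant-ish cycle times
  set.seed(2)
  n <- 20
  cells <- data.frame(
    cell_id = sprintf("m%02d", 1:n), parent_id = NA,
    birth_time = 0, end_time = NA, end_fate = "divided"
  )
  block <- rep(c(0, 1), each = n / 2)
  cells$end_time <- ifelse(block == 0, 3, 6) + rnorm(n, 0, 0.05)
  kids <- data.frame(
    cell_id = sprintf("k%02d", 1:(2 * n)),
    parent_id = rep(cells$cell_id, each = 2),
    birth_time = rep(cells$end_time, each = 2),
    end_time = rep(cells$end_time, each = 2) + 5,
    end_fate = "censored"
  )
  all_cells <- rbind(cells, kids)
  cent <- tibble::tibble(
    cell_id = cells$cell_id, t = 0,
    x = block * 100 + runif(n, 0, 10), y = runif(n, 0, 10)
  )
  forest <- lineage_forest(all_cells, centroids = cent,
                           movie_end = max(all_cells$end_time))
  res <- neighbor_cycle_correlation(forest)
  expect_gt(res$pearson, 0.9)
  # positions shuffled across blocks -> correlation collapses
  cent2 <- cent
  cent2$x <- sample(cent$x)
  f2 <- lineage_forest(all_cells, centroids = cent2,
                       movie_end = max(all_cells$end_time))
  res2 <- neighbor_cycle_correlation(f2)
  expect_lt(abs(res2$pearson), 3 / sqrt(res2$n_pairs) + 0.35)
  expect_error(neighbor_cycle_correlation(toy_forest()), "centroid")
})
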