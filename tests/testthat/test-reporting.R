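test_that("distance helpers behave on simple laws", {
  p <- data.frame(count = 0:1, prob = c(0.5, 0.5))
  q <- data.frame(count = 0:1, prob = c(0.4, 0.6))
  expect_equal(tv_distance(p, q), 0.1)
  expect_equal(tv_distance(p, p), 0)
  # disjoint supports are maximally distant
  r <- data.frame(count = 5:6, prob = c(0.5, 0.5))
  expect_equal(tv_distance(p, r), 1)
  # KS of a discretised Gaussian against itself is small
  grid <- 0:40
  emp <- data.frame(count = grid,
                    prob = stats::pnorm(grid + 0.5, 20, 3) -
                      stats::pnorm(grid - 0.5, 20, 3))
  emp$prob <- emp$prob / sum(emp$prob)
  expect_lt(ks_distance_gaussian(emp, 20, 3), 1e-6)
  # and against a shifted Gaussian is large
  expect_gt(ks_distance_gaussian(emp, 30, 3), 0.5)
})

test_that("density report compares simulation, exact law and Gaussian", {
  cfg <- reference_config(x0 = 20, n_paths = 2000, seed = 2)
  rep <- report_density_comparison(cfg)
  expect_s3_class(rep, "gsm2_density_report")
  expect_equal(nrow(rep$distances), 6)  # 3 times x 2 lesion types
  expect_true(all(rep$distances$tv_cme < 0.1))
  expect_true(all(rep$distances$ks_lna < 0.2))
  # histograms carry both laws and normalise
  sums <- dplyr::summarise(
    dplyr::group_by(rep$histograms, t, lesion),
    ssa = sum(prob_ssa), cme = sum(prob_cme), .groups = "drop")
  expect_equal(sums$ssa, rep(1, 6))
  expect_equal(sums$cme, rep(1, 6), tolerance = 1e-8)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("degenerate single-path report is still well-formed", {
  cfg <- reference_config(x0 = 10, n_paths = 1, seed = 5)
  rep <- report_density_comparison(cfg)
  expect_equal(nrow(rep$distances), 6)
  expect_true(all(is.finite(rep$distances$ks_lna)))
})

test_that("reports are deterministic given the seed and write provenance", {
  cfg <- reference_config(x0 = 15, n_paths = 300, seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- report_density_comparison(cfg, out_dir = d1)
  r2 <- report_density_comparison(cfg, out_dir = d2)
  expect_identical(r1$distances, r2$distances)
  f1 <- file.path(d1, "density_distances.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1),
                   readLines(file.path(d2, "density_distances.csv")))
  # resolved config written beside the outputs round-trips
  back <- read_config(file.path(d1, "density_config.json"))
  expect_equal(back$rates, cfg$rates)
})

test_that("moment report flags the non-Poissonian structure", {
  cfg <- reference_config()
  rep <- report_moments(cfg)
  expect_true(all(unlist(rep$checks)))
  expect_true(all(rep$moments$c_xiups[rep$moments$t > 0] < 0))
  expect_true(all(rep$moments$dispersion_y[rep$moments$t > 0] < 1))
  expect_s3_class(autoplot(rep), "ggplot")
  # frozen rates give constant columns
  frozen_cfg <- run_config(kinetic_rates(0, 0, b_tilde = 0),
                           initial_condition(10), t_points = c(0.5, 1))
  frozen <- report_moments(frozen_cfg)
  expect_equal(length(unique(frozen$moments$mean_x)), 1L)
  expect_equal(length(unique(frozen$moments$mean_y)), 1L)
})

test_that("path report bundles simulation, approximation and mean", {
  cfg <- reference_config(x0 = 30, n_paths = 100, seed = 3)
  rep <- report_paths(cfg, n = 4)
  expect_setequal(unique(rep$paths$source), c("mean", "ssa", "ou"))
  expect_equal(length(unique(rep$paths$path[rep$paths$source == "ssa"])), 4)
  expect_true(all(rep$paths$x >= 0))
  expect_s3_class(autoplot(rep), "ggplot")
  # n = 0: mean curve only
  rep0 <- report_paths(cfg, n = 0)
  expect_setequal(unique(rep0$paths$source), "mean")
  # the mean lies within the large-ensemble envelope at each time
  big <- simulate_ensemble(cfg$rates, cfg$init, cfg$t_points, 2000, cfg$seed)
  env <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(big), t),
                          lo = min(y), hi = max(y), .groups = "drop")
  macro <- solve_mkm(cfg$rates, cfg$init$x0, cfg$init$y0, cfg$t_points)
  expect_true(all(macro$y_bar >= env$lo & macro$y_bar <= env$hi))
})
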