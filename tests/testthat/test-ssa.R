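test_that("propensities follow the master-equation rates", {
  rates <- ref_rates()
  p <- propensities(data.frame(x = c(0, 1, 2)), rates)
  expect_equal(p$repair, c(0, 4, 8))
  expect_equal(p$direct, c(0, 0.1, 0.2))
  # pairwise uses x(x-1) exactly: zero below two lesions
  expect_equal(p$pairwise, c(0, 0, 0.02))
  # logistic death variant
  lr <- kinetic_rates(4, 0.1, b_tilde = 0.01, a_logistic = 0.05)
  pl <- propensities(data.frame(x = 2), lr)
  expect_equal(pl$direct, 2 * (0.1 + 0.05 * 2))
  expect_error(propensities(data.frame(x = -1), rates), "non-negative")
})

test_that("reaction stoichiometry is applied per channel", {
  expect_equal(apply_reaction(data.frame(x = 5, y = 0), "pairwise"),
               tibble::tibble(x = 3, y = 1))
  expect_equal(apply_reaction(data.frame(x = 1, y = 2), "repair"),
               tibble::tibble(x = 0, y = 2))
  expect_equal(apply_reaction(data.frame(x = 1, y = 2), "direct"),
               tibble::tibble(x = 0, y = 3))
  expect_error(apply_reaction(data.frame(x = 1, y = 2), "pairwise"),
               "requires more")
  expect_error(apply_reaction(data.frame(x = 0, y = 0), "repair"),
               "requires more")
})

test_that("degenerate rate sets freeze the expected coordinates", {
  frozen <- kinetic_rates(0, 0, b_tilde = 0)
  path <- simulate_path(frozen, initial_condition(10, 2), t_max = 5, seed = 1)
  expect_equal(nrow(path), 1L)
  expect_equal(path$x, 10L)
  expect_equal(path$y, 2L)
  # no lethal-producing channel: y constant
  repair_only <- kinetic_rates(3, 0, b_tilde = 0)
  p2 <- simulate_path(repair_only, initial_condition(15, 4), t_max = 50,
                      seed = 2)
  expect_true(all(p2$y == 4L))
  expect_equal(p2$x[nrow(p2)], 0L)
})

test_that("trajectories are monotone and conserve the lesion budget", {
  rates <- ref_rates()
  for (seed in 1:5) {
    path <- simulate_path(rates, initial_condition(60), t_max = 2, seed = seed)
    expect_true(all(diff(path$t) > 0))
    expect_true(all(diff(path$x) < 0))
    expect_true(all(diff(path$y) >= 0))
    expect_true(all(path$y - path$y[1] <= path$x[1] - path$x))
  }
})

test_that("ensembles are seed-reproducible and marginals normalised", {
  rates <- small_rates()
  init <- initial_condition(20)
  e1 <- simulate_ensemble(rates, init, c(0.5, 1), n_paths = 200, seed = 42)
  e2 <- simulate_ensemble(rates, init, c(0.5, 1), n_paths = 200, seed = 42)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  e3 <- simulate_ensemble(rates, init, c(0.5, 1), n_paths = 200, seed = 43)
  expect_false(identical(as.data.frame(e1), as.data.frame(e3)))
  marg <- ensemble_marginals(e1)
  sums <- dplyr::summarise(dplyr::group_by(marg, t, lesion),
                           s = sum(prob), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)))
  # single path gives a point mass
  one <- ensemble_marginals(
    simulate_ensemble(rates, init, 0.5, n_paths = 1, seed = 1))
  expect_true(all(one$prob == 1))
})

test_that("linear-network lethal yield matches the binomial law", {
  # with no pairwise channel each initial lesion independently becomes
  # lethal with probability a/(a+r); Y(inf) ~ Binomial(x0, a/(a+r))
  lin <- kinetic_rates(4, 0.1, b_tilde = 0)
  x0 <- 20
  n <- 10000
  ens <- simulate_ensemble(lin, initial_condition(x0), t_points = 10,
                           n_paths = n, seed = 7)
  p <- lin$a / (lin$a + lin$r)
  mom <- ensemble_moments(ens)
  se <- sqrt(x0 * p * (1 - p) / n)
  expect_lt(abs(mom$mean_y - x0 * p), 3 * se)
  expect_equal(mom$mean_x, 0)
})

test_that("ensemble moments agree with the exact master equation", {
  rates <- small_rates()
  init <- initial_condition(20)
  ens <- simulate_ensemble(rates, init, 0.5, n_paths = 10000, seed = 5)
  mom <- ensemble_moments(ens)
  exact <- cme_moments(cme_solve(rates, init, 0.5))
  expect_lt(abs(mom$mean_x - exact$mean_x), 4 * mom$se_mean_x)
  expect_lt(abs(mom$mean_y - exact$mean_y), 4 * mom$se_mean_y)
  expect_lt(abs(mom$var_x - exact$var_x), 4 * mom$se_var_x)
  expect_lt(abs(mom$var_y - exact$var_y), 4 * mom$se_var_y)
  expect_lt(abs(mom$cov_xy - exact$cov_xy), 4 * mom$se_cov_xy)
})
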