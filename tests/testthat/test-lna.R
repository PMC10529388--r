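test_that("centred initial data keep the fluctuation means at zero", {
  fm <- solve_first_moments(ref_rates(), x_bar0 = 1, t_grid = seq(0, 10, 0.1))
  expect_equal(max(abs(fm$xi_bar)), 0)
  expect_equal(max(abs(fm$ups_bar)), 0)
})

test_that("nonzero first moments integrate the linear system", {
  # b = 0 decouples: xi_bar(t) = exp(-(a+r) t)
  lin <- kinetic_rates(4, 0.1, b_tilde = 0)
  tg <- seq(0, 2, 0.2)
  fm <- solve_first_moments(lin, 1, tg, xi0 = 1)
  expect_equal(fm$xi_bar, exp(-4.1 * tg), tolerance = 1e-9)
  # ups_bar(inf) equals the quadrature of (2 b xbar + a) xi_bar
  rates <- ref_rates()
  fm2 <- solve_first_moments(rates, 1, c(0, 20), xi0 = 1)
  f <- function(s) {
    xb <- xbar_closed_form(s, rates, 1, scale = "macro")
    xi <- exp(-vapply(s, function(u) stats::integrate(
      function(v) 4 * rates$b * xbar_closed_form(v, rates, 1, scale = "macro") +
        rates$a + rates$r, 0, u, rel.tol = 1e-10)$value, numeric(1)))
    (2 * rates$b * xb + rates$a) * xi
  }
  ups_inf <- stats::integrate(f, 0, 20, rel.tol = 1e-9)$value
  expect_equal(fm2$ups_bar[2], ups_inf, tolerance = 1e-6)
})

test_that("covariance right-hand side vanishes at equilibrium and matches the Lyapunov form", {
  rates <- ref_rates()
  expect_equal(unname(covariance_rhs(0, 0, 0, 0, rates)), c(0, 0, 0))
  # dC = -A C - C A' + D with the OU drift/diffusion
  xb <- 0.37
  C <- matrix(c(0.05, -0.01, -0.01, 0.08), 2, 2)  # (ups, xi) ordering
  co <- ou_coefficients(rates, xb)
  dC <- -co$A %*% C - C %*% t(co$A) + co$D
  drv <- covariance_rhs(C[1, 1], C[1, 2], C[2, 2], xb, rates)
  expect_equal(as.numeric(drv["c_upsups"]), as.numeric(dC[1, 1]), tolerance = 1e-12)
  expect_equal(as.numeric(drv["c_xiups"]), as.numeric(dC[1, 2]), tolerance = 1e-12)
  expect_equal(as.numeric(drv["c_xixi"]), as.numeric(dC[2, 2]), tolerance = 1e-12)
})

test_that("linear network second moments are exact (binomial oracle and CME)", {
  lin <- kinetic_rates(4, 0.1, b_tilde = 0, K = 20)
  x0 <- 20
  tg <- c(0.5, 1, 15)
  lna <- solve_lna(lin, initial_condition(x0), tg)
  cs <- count_scale_moments(lna)
  race <- linear_race(lin, tg)
  expect_equal(cs$mean_y, x0 * race$p_lethal, tolerance = 1e-6)
  expect_equal(cs$var_y, x0 * race$p_lethal * (1 - race$p_lethal),
               tolerance = 1e-6)
  # sublethal variance is the survivor-binomial variance
  expect_equal(cs$var_x, x0 * race$surv * (1 - race$surv), tolerance = 1e-6)
  # and both agree with the exact master equation
  exact <- cme_moments(cme_solve(lin, initial_condition(x0), tg,
                                 rtol = 1e-10, atol = 1e-13))
  expect_equal(cs$mean_y, exact$mean_y, tolerance = 1e-6)
  expect_equal(cs$var_y, exact$var_y, tolerance = 1e-6)
  expect_equal(cs$var_x, exact$var_x, tolerance = 1e-6)
  expect_equal(cs$cov_xy, exact$cov_xy, tolerance = 1e-6)
})

test_that("reference kinetics are under-dispersed with negative cross-covariance", {
  rates <- ref_rates()
  tg <- seq(0, 10, 0.05)
  lna <- solve_lna(rates, initial_condition(100), tg)
  pos <- lna$t > 0
  expect_true(all(lna$c_xiups[pos] < 0))
  expect_true(all(lna$c_upsups[pos] < lna$y_bar[pos]))
  # positive semidefinite throughout
  mineig <- purrr::map_dbl(seq_len(nrow(lna)), function(i) {
    C <- matrix(c(lna$c_upsups[i], lna$c_xiups[i],
                  lna$c_xiups[i], lna$c_xixi[i]), 2, 2)
    min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_true(all(mineig >= -1e-9))
  # long-time sublethal moments vanish
  expect_lt(abs(lna$c_xixi[nrow(lna)]), 1e-6)
  expect_lt(abs(lna$c_xiups[nrow(lna)]), 1e-6)
  # delta identity and positivity
  expect_true(all(lna$delta >= 0))
  expect_lt(max(abs(lna$c_upsups - (lna$y_bar - lna$delta))), 1e-6)
})

test_that("delta correction reproduces the binomial variance gap when b = 0", {
  lin <- kinetic_rates(4, 0.1, b_tilde = 0, K = 20)
  x0 <- 20
  lna <- solve_lna(lin, initial_condition(x0), c(0, 15))
  d <- delta_correction(lna)
  race <- linear_race(lin, 15)
  # gap between Poisson (mean) and binomial variance: x0 * p^2, on the
  # macroscopic scale divided by K
  expect_equal(d$delta[2], x0 * race$p_lethal^2 / lin$K, tolerance = 1e-6)
  expect_gt(d$delta[2], 0)
  # trapezoid cross-check converges to the stored ODE value on a fine grid
  lna_fine <- solve_lna(lin, initial_condition(x0), seq(0, 15, 0.005))
  d_ode <- delta_correction(lna_fine)
  d_trap <- delta_correction(lna_fine, method = "trapezoid")
  expect_lt(abs(d_trap$delta[nrow(d_trap)] - d_ode$delta[nrow(d_ode)]), 1e-6)
})

test_that("gaussian initial laws enter through the covariance initial condition", {
  rates <- ref_rates(K = 1)  # count-scale convention
  x0 <- 50
  init <- initial_condition(x0, 5, mode = "gaussian", sigma = c(x0, 5))
  lna <- solve_lna(rates, init, c(0, 0.5))
  expect_equal(lna$c_xixi[1], x0)
  expect_equal(lna$c_upsups[1], 5)
  expect_equal(lna$c_xiups[1], 0)
  # identity generalises: c_upsups = y_bar - y_bar0 + c_upsups0 - delta
  expect_lt(max(abs(lna$c_upsups -
                      (lna$y_bar - lna$y_bar[1] + lna$c_upsups[1] - lna$delta))),
            1e-6)
})

test_that("gaussian count marginals integrate to one and centre correctly", {
  rates <- ref_rates()
  lna <- solve_lna(rates, initial_condition(100), c(0.5, 0.9))
  g <- gaussian_marginals(lna)
  expect_setequal(g$lesion, c("sublethal", "lethal"))
  cs <- count_scale_moments(lna)
  lethal <- g[g$lesion == "lethal" & g$t == 0.5, ]
  expect_equal(lethal$mean, cs$mean_y[1])
  expect_equal(lethal$sd, sqrt(cs$var_y[1]))
  # density integrates to 1
  ii <- stats::integrate(stats::dnorm, -Inf, Inf, mean = lethal$mean,
                         sd = lethal$sd)
  expect_equal(ii$value, 1, tolerance = 1e-6)
})

test_that("frozen kinetics leave the covariance at its initial value", {
  frozen <- kinetic_rates(0, 0, b_tilde = 0, K = 1)
  init <- initial_condition(10, 2, mode = "gaussian", sigma = c(10, 2))
  lna <- solve_lna(frozen, init, c(0, 1, 5))
  expect_equal(lna$c_xixi, rep(10, 3))
  expect_equal(lna$c_upsups, rep(2, 3))
  expect_equal(lna$c_xiups, rep(0, 3))
})
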