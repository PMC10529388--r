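#' Linear-noise approximation of the lesion kinetics
#'
#' Expands the master equation in the system size K: counts are written as
#' `X = K*x_bar + sqrt(K)*xi`, `Y = K*y_bar + sqrt(K)*upsilon`. The leading
#' order recovers the deterministic kinetic ODEs ([solve_mkm()]); the next
#' order is a linear Fokker-Planck equation whose solution is a bivariate
#' Gaussian in the fluctuations `(upsilon, xi)`. `solve_lna()` integrates,
#' in one solver call on the macroscopic scale,
#' the macroscopic trajectory, the (identically zero, for centred initial
#' data) first moments, the covariance system
#' \deqn{\dot c_{\upsilon\upsilon} = 2(2b\bar x + a)c_{\xi\upsilon}
#'         + a\bar x + b\bar x^2,}
#' \deqn{\dot c_{\xi\upsilon} = (2b\bar x + a)c_{\xi\xi}
#'         - (4b\bar x + a + r)c_{\xi\upsilon} - (a\bar x + 2b\bar x^2),}
#' \deqn{\dot c_{\xi\xi} = -2(4b\bar x + a + r)c_{\xi\xi}
#'         + (a+r)\bar x + 4b\bar x^2,}
#' and the accumulated non-Poissonian correction
#' `delta(t) = -int_0^t 2(2b*x_bar + a) * c_xiups ds`, which satisfies the
#' identity `c_upsups = y_bar - y_bar(0) + c_upsups(0) - delta` — for a
#' deterministic start from `y0 = 0`, `c_upsups = y_bar - delta`. Because the
#' cross-covariance is negative (lethal lesions grow exactly when sublethal
#' lesions shrink), `delta >= 0` and the lethal count is under-dispersed
#' relative to a Poisson law of the same mean.
#'
#' Initial covariances: a deterministic start gives `C(0) = 0`; a Gaussian
#' start with count-scale covariance `diag(sigma)` gives fluctuation-scale
#' `c_xixi(0) = sigma_x / K`, `c_upsups(0) = sigma_y / K`, `c_xiups(0) = 0`,
#' so that the count-scale variances reproduce `sigma` exactly.
#'
#' @param rates a [kinetic_rates()] object (`b` and `K` set the scale).
#' @param init an [initial_condition()] object (count scale).
#' @param t_grid increasing times (0 is prepended if absent).
#' @param rtol,atol solver tolerances.
#' @return A tibble of class `gsm2_lna` with columns `t`, `x_bar`, `y_bar`
#'   (macroscopic concentrations), `xi_bar`, `ups_bar` (fluctuation means,
#'   identically 0 for centred initial data), `c_upsups`, `c_xiups`,
#'   `c_xixi`, `delta`; attributes `rates`, `init`, `K`. Use
#'   [count_scale_moments()] for count-scale means/variances.
#' @examples
#' rates <- kinetic_rates(4, 0.1, b_tilde = 0.01, K = 100)
#' lna <- solve_lna(rates, initial_condition(100), seq(0, 1, 0.1))
#' count_scale_moments(lna)
#' @export
solve_lna <- function(rates, init, t_grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(rates, "gsm2_rates"), inherits(init, "gsm2_init"))
  K <- rates$K
  xb0 <- init$x0 / K
  yb0 <- init$y0 / K
  c0 <- if (init$mode == "gaussian") init$sigma / K else c(0, 0)
  t_grid <- as.numeric(t_grid)
  times <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  a <- rates$a; r <- rates$r; b <- rates$b
  rhs <- function(t, s, p) {
    xb <- s[["x_bar"]]
    drv <- covariance_rhs(s[["c_upsups"]], s[["c_xiups"]], s[["c_xixi"]],
                          xb, rates, scale = "macro")
    list(c(
      x_bar = -(a + r) * xb - 2 * b * xb^2,
      y_bar = a * xb + b * xb^2,
      xi_bar = -(4 * b * xb + a + r) * s[["xi_bar"]],
      ups_bar = (2 * b * xb + a) * s[["xi_bar"]],
      drv,
      delta = -2 * (2 * b * xb + a) * s[["c_xiups"]]
    ))
  }
  s0 <- c(x_bar = xb0, y_bar = yb0, xi_bar = 0, ups_bar = 0,
          c_upsups = c0[2], c_xiups = 0, c_xixi = c0[1], delta = 0)
  sol <- deSolve::ode(y = s0, times = times, func = rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("linear-noise moment solver failed", call. = FALSE)
  keep <- match(t_grid, sol[, 1])
  out <- tibble::as_tibble(as.data.frame(sol[keep, , drop = FALSE]))
  names(out)[1] <- "t"
  new_gsm2_result(out, "gsm2_lna", rates = rates, init = init, K = K)
}

#' Right-hand side of the fluctuation covariance system
#'
#' The derivative of `(c_upsups, c_xiups, c_xixi)` at one macroscopic point,
#' i.e. the Lyapunov equation `dC/dt = -A C - C A' + D` with the drift `A`
#' and diffusion `D` of the linear Fokker-Planck equation (see
#' [ou_coefficients()]). Exposed for testing and for alternative
#' integrators.
#'
#' @param c_upsups,c_xiups,c_xixi current covariances.
#' @param x_bar macroscopic sublethal value at the evaluation time.
#' @param rates a [kinetic_rates()] object.
#' @param scale `"macro"` (default) or `"count"`; selects the pairwise rate
#'   that multiplies `x_bar`.
#' @return Named numeric vector `(c_upsups, c_xiups, c_xixi)` of derivatives.
#' @export
covariance_rhs <- function(c_upsups, c_xiups, c_xixi, x_bar, rates,
                           scale = c("macro", "count")) {
  scale <- match.arg(scale)
  a <- rates$a; r <- rates$r
  b <- if (scale == "macro") rates$b else rates$b_tilde
  xb <- x_bar
  c(
    c_upsups = 2 * (2 * b * xb + a) * c_xiups + a * xb + b * xb^2,
    c_xiups = (2 * b * xb + a) * c_xixi - (4 * b * xb + a + r) * c_xiups -
      (a * xb + 2 * b * xb^2),
    c_xixi = -2 * (4 * b * xb + a + r) * c_xixi + (a + r) * xb + 4 * b * xb^2
  )
}

#' First-moment equations of the fluctuations
#'
#' Integrates `d ups_bar/dt = (2b*x_bar + a) * xi_bar`,
#' `d xi_bar/dt = -(4b*x_bar + a + r) * xi_bar` along the closed-form
#' macroscopic trajectory. With zero initial data both moments vanish
#' identically — the fluctuations are centred; nonzero initial data decay as
#' the linear homogeneous system dictates.
#'
#' @param rates a [kinetic_rates()] object.
#' @param x_bar0 initial macroscopic sublethal value (macro scale).
#' @param t_grid increasing times.
#' @param xi0,ups0 initial fluctuation means (default 0).
#' @param rtol,atol solver tolerances.
#' @return A tibble with columns `t`, `xi_bar`, `ups_bar`.
#' @examples
#' solve_first_moments(kinetic_rates(4, 0.1, b_tilde = 0.01, K = 100),
#'                     x_bar0 = 1, t_grid = seq(0, 10, 0.1))
#' @export
solve_first_moments <- function(rates, x_bar0, t_grid, xi0 = 0, ups0 = 0,
                                rtol = 1e-12, atol = 1e-14) {
  stopifnot(inherits(rates, "gsm2_rates"), x_bar0 >= 0)
  a <- rates$a; r <- rates$r; b <- rates$b
  rhs <- function(t, s, p) {
    xb <- xbar_closed_form(t, rates, x_bar0, scale = "macro")
    list(c(-(4 * b * xb + a + r) * s[1], (2 * b * xb + a) * s[1]))
  }
  sol <- deSolve::ode(y = c(xi_bar = xi0, ups_bar = ups0),
                      times = as.numeric(t_grid), func = rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("first-moment solver failed", call. = FALSE)
  tibble::tibble(t = sol[, "time"], xi_bar = sol[, "xi_bar"],
                 ups_bar = sol[, "ups_bar"])
}

#' Non-Poissonian correction of the lethal-lesion variance
#'
#' Extracts `delta(t)` — the amount by which the lethal fluctuation variance
#' falls below the macroscopic mean, `c_upsups = y_bar - delta` for a
#' deterministic start from `y0 = 0` — together with its long-time value.
#' The primary trajectory is integrated alongside the covariance ODEs
#' (`method = "ode"`, same integrator and tolerances); a trapezoidal
#' quadrature of `-2(2b*x_bar + a)*c_xiups` on the output grid is provided
#' as an independent cross-check of the stored curve.
#'
#' @param lna a [solve_lna()] trajectory.
#' @param method `"ode"` (stored, solver-accurate) or `"trapezoid"`
#'   (recomputed on the output grid).
#' @return A tibble with columns `t`, `delta`, plus the scalar attribute
#'   `delta_inf` (value at the last grid time).
#' @export
delta_correction <- function(lna, method = c("ode", "trapezoid")) {
  method <- match.arg(method)
  stopifnot(inherits(lna, "gsm2_lna"))
  if (method == "ode") {
    d <- lna$delta
  } else {
    rates <- attr(lna, "rates")
    f <- -2 * (2 * rates$b * lna$x_bar + rates$a) * lna$c_xiups
    d <- cumtrapz(lna$t, f) + lna$delta[1]
  }
  out <- tibble::tibble(t = lna$t, delta = d)
  attr(out, "delta_inf") <- d[length(d)]
  out
}

cumtrapz <- function(t, f) {
  n <- length(t)
  if (n == 1L) return(0)
  c(0, cumsum(diff(t) * (f[-1] + f[-n]) / 2))
}

#' Gaussian count-scale marginals of the linear-noise law
#'
#' The fluctuation law at each time is bivariate Gaussian; mapped to the
#' count scale the lesion marginals are
#' `X ~ N(K*x_bar + sqrt(K)*xi_bar, K*c_xixi)` and
#' `Y ~ N(K*y_bar + sqrt(K)*ups_bar, K*c_upsups)`.
#'
#' @param lna a [solve_lna()] trajectory.
#' @param K system size; defaults to the one stored on `lna`.
#' @return A tibble with columns `t`, `lesion`, `mean`, `sd` (count scale).
#' @examples
#' rates <- kinetic_rates(4, 0.1, b_tilde = 0.01, K = 100)
#' lna <- solve_lna(rates, initial_condition(100), c(0.5, 0.9))
#' gaussian_marginals(lna)
#' @export
gaussian_marginals <- function(lna, K = attr(lna, "K")) {
  stopifnot(inherits(lna, "gsm2_lna"))
  check_K(K)
  if (any(pmin(lna$c_xixi, lna$c_upsups) < -1e-9))
    stop("covariance trajectory is not positive semidefinite", call. = FALSE)
  cs <- count_scale_moments(lna, K)
  dplyr::bind_rows(
    tibble::tibble(t = cs$t, lesion = "sublethal", mean = cs$mean_x,
                   sd = sqrt(pmax(cs$var_x, 0))),
    tibble::tibble(t = cs$t, lesion = "lethal", mean = cs$mean_y,
                   sd = sqrt(pmax(cs$var_y, 0)))
  )
}

#' @export
tidy.gsm2_lna <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"t",
                      names_to = "quantity", values_to = "value")
}

#' @export
glance.gsm2_lna <- function(x, ...) {
  last <- x[nrow(x), ]
  cs <- count_scale_moments(last, attr(x, "K"))
  tibble::tibble(
    t_max = last$t,
    y_bar_final = last$y_bar,
    c_upsups_final = last$c_upsups,
    c_xiups_min = min(x$c_xiups),
    delta_final = last$delta,
    dispersion_y_final = cs$dispersion_y
  )
}

#' @export
autoplot.gsm2_lna <- function(object, ...) {
  keep <- c("x_bar", "y_bar", "c_xixi", "c_xiups", "c_upsups")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", keep)], -"t",
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [a.u.]", y = "moment (macroscopic scale)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
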