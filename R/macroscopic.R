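#' Deterministic macroscopic limit of the lesion kinetics
#'
#' In the large-system limit the mean lesion dynamics obey the kinetic ODEs
#' of the microdosimetric kinetic model,
#' \deqn{d\bar y/dt = a\bar x + b\bar x^2, \qquad
#'       d\bar x/dt = -(a+r)\bar x - 2b\bar x^2,}
#' where each pairwise event consumes two sublethal lesions and produces one
#' lethal lesion. `solve_mkm()` integrates the system numerically;
#' [xbar_closed_form()] gives the exact Bernoulli solution for the sublethal
#' component, used for cross-checks and for evaluating coefficients at
#' arbitrary times.
#'
#' The equations are scale-equivariant: solving on the count scale
#' (`scale = "count"`, quadratic rate `b_tilde`, initial value `x0`) gives
#' exactly `K` times the solution on the macroscopic concentration scale
#' (`scale = "macro"`, rate `b = b_tilde * K`, initial value `x0 / K`).
#'
#' @param rates a [kinetic_rates()] object.
#' @param x0,y0 initial values on the chosen scale.
#' @param t_grid increasing time grid starting at any `t >= 0`.
#' @param scale `"count"` (default) or `"macro"`; selects which pairwise rate
#'   multiplies the quadratic term.
#' @param rtol,atol solver tolerances (passed to [deSolve::ode()]).
#' @return A tibble of class `gsm2_macro` with columns `t`, `x_bar`, `y_bar`
#'   and attributes `rates`, `scale`, `solver`.
#' @examples
#' rates <- kinetic_rates(4, 0.1, b_tilde = 0.01, K = 100)
#' solve_mkm(rates, x0 = 100, y0 = 0, t_grid = c(0, 0.5, 0.7, 0.9))
#' @export
solve_mkm <- function(rates, x0, y0 = 0, t_grid, scale = c("count", "macro"),
                      rtol = 1e-10, atol = 1e-12) {
  scale <- match.arg(scale)
  stopifnot(inherits(rates, "gsm2_rates"), x0 >= 0, y0 >= 0)
  bq <- if (scale == "count") rates$b_tilde else rates$b
  ar <- rates$a + rates$r
  rhs <- function(t, s, p) {
    xb <- s[1]
    list(c(-ar * xb - 2 * bq * xb^2, rates$a * xb + bq * xb^2))
  }
  t_grid <- as.numeric(t_grid)
  sol <- deSolve::ode(y = c(x_bar = x0, y_bar = y0), times = t_grid,
                      func = rhs, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("macroscopic ODE solver failed", call. = FALSE)
  out <- tibble::tibble(t = sol[, "time"],
                        x_bar = pmax(sol[, "x_bar"], 0),
                        y_bar = sol[, "y_bar"])
  new_gsm2_result(out, "gsm2_macro", rates = rates, scale = scale,
                  solver = list(method = "lsoda", rtol = rtol, atol = atol))
}

#' Closed-form sublethal decay (Bernoulli solution)
#'
#' The sublethal ODE `dx/dt = -(a+r)x - 2bx^2` is a Bernoulli equation with
#' explicit solution
#' \deqn{\bar x(t) = \frac{a+r}{c\,e^{(a+r)t} - 2b}, \qquad
#'       c = \frac{a+r}{x_0} + 2b.}
#' It equals `x0` at `t = 0`, decreases strictly, and tends to 0.
#'
#' @inheritParams solve_mkm
#' @param t time or vector of times, `>= 0`.
#' @return Numeric vector of `x_bar(t)`.
#' @examples
#' xbar_closed_form(c(0, 0.5, 10), kinetic_rates(4, 0.1, b_tilde = 0.01), 100)
#' @export
xbar_closed_form <- function(t, rates, x0, scale = c("count", "macro")) {
  scale <- match.arg(scale)
  stopifnot(inherits(rates, "gsm2_rates"), x0 >= 0)
  if (x0 == 0) return(rep(0, length(t)))
  bq <- if (scale == "count") rates$b_tilde else rates$b
  ar <- rates$a + rates$r
  cc <- ar / x0 + 2 * bq
  ar / (cc * exp(ar * t) - 2 * bq)
}

#' Stationary limits of the macroscopic system
#'
#' The sublethal concentration always decays to 0. The lethal limit follows
#' from dividing the two kinetic ODEs and integrating over the sublethal
#' variable,
#' \deqn{\bar y_\infty = y_0 + \int_0^{x_0}
#'   \frac{a + b u}{(a+r) + 2 b u}\,du
#'   = y_0 + \frac{x_0}{2} + \frac{a-r}{4b}
#'     \log\!\Big(1 + \frac{2 b x_0}{a+r}\Big),}
#' with the `b -> 0` limit `y0 + x0 * a / (a+r)`. The quadrature form is
#' cross-checked against long-horizon ODE integration in the test suite.
#'
#' @inheritParams solve_mkm
#' @return A one-row tibble with columns `x_inf` (exactly 0) and `y_inf`.
#' @examples
#' stationary_limits(kinetic_rates(4, 0.1, b_tilde = 0.01), x0 = 100)
#' @export
stationary_limits <- function(rates, x0, y0 = 0, scale = c("count", "macro")) {
  scale <- match.arg(scale)
  stopifnot(inherits(rates, "gsm2_rates"), x0 >= 0, y0 >= 0)
  bq <- if (scale == "count") rates$b_tilde else rates$b
  ar <- rates$a + rates$r
  y_inf <- if (x0 == 0) {
    y0
  } else if (bq == 0) {
    if (ar == 0) y0 else y0 + x0 * rates$a / ar
  } else if (ar == 0) {
    # pure pairwise: every two sublethal lesions make one lethal
    y0 + x0 / 2
  } else {
    y0 + x0 / 2 + (rates$a - rates$r) / (4 * bq) * log1p(2 * bq * x0 / ar)
  }
  tibble::tibble(x_inf = 0, y_inf = y_inf)
}

#' Simplified low-LET kinetics
#'
#' Under sparsely ionising radiation the quadratic loss term is negligible
#' against linear removal, `(a+r)x >> 2bx^2`, and the sublethal equation is
#' taken as pure exponential decay while the lethal production keeps its
#' quadratic term:
#' \deqn{\bar x(t) = x_0 e^{-(a+r)t}, \qquad
#'   \bar y(t) = y_0 + \frac{a x_0}{a+r}\big(1-e^{-(a+r)t}\big)
#'   + \frac{b x_0^2}{2(a+r)}\big(1-e^{-2(a+r)t}\big).}
#' The lethal closed form is obtained by direct integration of
#' `dy/dt = a*x + b*x^2` under the exponential `x`; it is validated against
#' numerical integration in the test suite.
#'
#' @inheritParams solve_mkm
#' @return A tibble of class `gsm2_macro` with columns `t`, `x_bar`, `y_bar`.
#' @examples
#' solve_simplified(kinetic_rates(4, 0.1, b_tilde = 0.01), 100,
#'                  t_grid = seq(0, 2, 0.5))
#' @export
solve_simplified <- function(rates, x0, y0 = 0, t_grid,
                             scale = c("count", "macro")) {
  scale <- match.arg(scale)
  stopifnot(inherits(rates, "gsm2_rates"), x0 >= 0, y0 >= 0)
  bq <- if (scale == "count") rates$b_tilde else rates$b
  ar <- rates$a + rates$r
  t_grid <- as.numeric(t_grid)
  if (ar == 0) {
    x_bar <- rep(x0, length(t_grid))
    y_bar <- y0 + bq * x0^2 * t_grid
  } else {
    x_bar <- x0 * exp(-ar * t_grid)
    y_bar <- y0 + rates$a * x0 * (1 - exp(-ar * t_grid)) / ar +
      bq * x0^2 * (1 - exp(-2 * ar * t_grid)) / (2 * ar)
  }
  out <- tibble::tibble(t = t_grid, x_bar = x_bar, y_bar = y_bar)
  new_gsm2_result(out, "gsm2_macro", rates = rates, scale = scale,
                  solver = list(method = "closed_form_simplified"))
}

new_gsm2_result <- function(df, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(df, nm) <- attrs[[nm]]
  class(df) <- c(class, class(df))
  df
}

#' @export
tidy.gsm2_macro <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"t",
                      names_to = "quantity", values_to = "value")
}

#' @export
glance.gsm2_macro <- function(x, ...) {
  rates <- attr(x, "rates")
  lim <- stationary_limits(rates, x0 = x$x_bar[1], y0 = x$y_bar[1],
                           scale = attr(x, "scale"))
  tibble::tibble(
    t_max = max(x$t),
    x_bar_final = x$x_bar[nrow(x)],
    y_bar_final = x$y_bar[nrow(x)],
    x_inf = lim$x_inf,
    y_inf = lim$y_inf
  )
}

#' @export
autoplot.gsm2_macro <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$t, y = .data$value,
                               colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [a.u.]", y = "mean lesion number",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
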