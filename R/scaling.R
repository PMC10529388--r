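#' Map lesion counts to fluctuation coordinates
#'
#' The system-size ansatz writes counts as `X = K * x_bar + sqrt(K) * xi`,
#' `Y = K * y_bar + sqrt(K) * upsilon`, splitting each count into a
#' macroscopic concentration and a centred fluctuation. `to_fluctuations()`
#' inverts the ansatz; `from_fluctuations()` applies it. The returned counts
#' are real-valued and may be negative — clamping at the absorbing boundary
#' `x = 0` is the responsibility of sampling and reporting layers.
#'
#' @param states a data frame with integer (or real) count columns `x`, `y`.
#' @param macro a one-row data frame (or list) with macroscopic concentrations
#'   `x_bar`, `y_bar`, or a data frame with one row per row of `states`.
#' @param K system size, `> 0`.
#' @return `to_fluctuations()`: a tibble with columns `xi`, `upsilon`.
#'   `from_fluctuations()`: a tibble with real-valued columns `x`, `y`.
#' @examples
#' to_fluctuations(data.frame(x = 110, y = 5),
#'                 list(x_bar = 1, y_bar = 0), K = 100)
#' @export
to_fluctuations <- function(states, macro, K) {
  check_K(K)
  tibble::tibble(
    xi = (states$x - K * macro$x_bar) / sqrt(K),
    upsilon = (states$y - K * macro$y_bar) / sqrt(K)
  )
}

#' @rdname to_fluctuations
#' @param fluct a data frame with fluctuation columns `xi`, `upsilon`.
#' @export
from_fluctuations <- function(fluct, macro, K) {
  check_K(K)
  tibble::tibble(
    x = K * macro$x_bar + sqrt(K) * fluct$xi,
    y = K * macro$y_bar + sqrt(K) * fluct$upsilon
  )
}

check_K <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0)
    stop("system size `K` must be a positive scalar", call. = FALSE)
  invisible(K)
}

#' Count-scale moments from fluctuation moments
#'
#' Translates fluctuation-scale moments to the count scale:
#' `E[X] = K * x_bar + sqrt(K) * xi_bar`, `Var[X] = K * c_xixi`, and
#' analogously for Y, with `Cov[X, Y] = K * c_xiups`. The input is typically a
#' [solve_lna()] trajectory, which carries both the macroscopic and the
#' fluctuation-moment columns; `K` defaults to the system size stored on it.
#'
#' @param moments a data frame with columns `t`, `x_bar`, `y_bar`, `xi_bar`,
#'   `ups_bar`, `c_xixi`, `c_xiups`, `c_upsups` (as returned by
#'   [solve_lna()]; missing `xi_bar`/`ups_bar` are taken as 0).
#' @param K system size; defaults to `attr(moments, "K")`.
#' @return A tibble with columns `t`, `mean_x`, `var_x`, `mean_y`, `var_y`,
#'   `cov_xy` and the lethal dispersion index `dispersion_y = var_y / mean_y`
#'   (`NaN` where `mean_y = 0`).
#' @examples
#' lna <- solve_lna(kinetic_rates(4, 0.1, b_tilde = 0.01, K = 100),
#'                  initial_condition(100), t_grid = c(0, 0.5, 0.9))
#' count_scale_moments(lna)
#' @export
count_scale_moments <- function(moments, K = attr(moments, "K")) {
  check_K(K)
  if (any(moments$c_xixi < -1e-12) || any(moments$c_upsups < -1e-12))
    stop("negative fluctuation variance in `moments`", call. = FALSE)
  xi_bar <- moments$xi_bar %||% rep(0, nrow(moments))
  ups_bar <- moments$ups_bar %||% rep(0, nrow(moments))
  mean_y <- K * moments$y_bar + sqrt(K) * ups_bar
  var_y <- K * moments$c_upsups
  tibble::tibble(
    t = moments$t,
    mean_x = K * moments$x_bar + sqrt(K) * xi_bar,
    var_x = K * moments$c_xixi,
    mean_y = mean_y,
    var_y = var_y,
    cov_xy = K * moments$c_xiups,
    dispersion_y = ifelse(mean_y > 0, var_y / mean_y, NaN)
  )
}
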