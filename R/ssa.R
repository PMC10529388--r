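#' Reaction propensities of the lesion network
#'
#' For a state with `x` sublethal lesions the three channels fire at rates
#' `repair = r * x`, `direct = x * (a + a_logistic * x)` and
#' `pairwise = b_tilde * x * (x - 1)`. The pairwise propensity uses
#' `x * (x - 1)` exactly (no 1/2 symmetry factor), matching the master
#' equation, so that simulation, exact integration and the expansion share
#' one convention. At `x = 0` all propensities vanish: the state is absorbing.
#'
#' @param states a data frame with a count column `x` (a column `y` is
#'   allowed and ignored: no propensity depends on the lethal count).
#' @param rates a [kinetic_rates()] object.
#' @return A tibble with non-negative columns `repair`, `direct`, `pairwise`.
#' @examples
#' propensities(data.frame(x = c(0, 1, 2)),
#'              kinetic_rates(4, 0.1, b_tilde = 0.01))
#' @export
propensities <- function(states, rates) {
  stopifnot(inherits(rates, "gsm2_rates"))
  x <- states$x
  if (any(x < 0)) stop("lesion counts must be non-negative", call. = FALSE)
  tibble::tibble(
    repair = rates$r * x,
    direct = x * (rates$a + rates$a_logistic * x),
    pairwise = rates$b_tilde * x * (x - 1)
  )
}

#' Apply one reaction channel to a state
#'
#' Stoichiometry: `repair` removes one sublethal lesion; `direct` converts
#' one sublethal into one lethal; `pairwise` merges two sublethal lesions
#' into one lethal. A channel may only fire where its propensity is positive.
#'
#' @param states a data frame with count columns `x`, `y`.
#' @param channel one of `"repair"`, `"direct"`, `"pairwise"` (recycled).
#' @return A tibble with updated columns `x`, `y`.
#' @examples
#' apply_reaction(data.frame(x = 5, y = 0), "pairwise")
#' @export
apply_reaction <- function(states, channel) {
  channel <- match.arg(channel, c("repair", "direct", "pairwise"),
                       several.ok = TRUE)
  x <- states$x; y <- states$y
  need <- ifelse(channel == "pairwise", 2L, 1L)
  if (any(x < need))
    stop("channel requires more sublethal lesions than the state holds",
         call. = FALSE)
  tibble::tibble(
    x = x - need,
    y = y + as.integer(channel != "repair")
  )
}

#' Simulate one exact sample path (Gillespie direct method)
#'
#' Draws a statistically exact realisation of the master equation: waiting
#' times are exponential with the total propensity, channels are chosen
#' categorically. Simulation stops when `x = 0` (absorbing) or the next event
#' would pass `t_max`. A Gaussian initial condition is realised by sampling a
#' bivariate normal, rounding to the nearest integer and clamping at 0 (an
#' approximation, since the master equation needs integer states).
#'
#' @param rates a [kinetic_rates()] object.
#' @param init an [initial_condition()] object.
#' @param t_max simulation horizon.
#' @param seed integer RNG seed.
#' @return A tibble of class `gsm2_path` with columns `t`, `x`, `y` (state
#'   after each event, first row the initial state) and attributes `rates`,
#'   `seed`.
#' @examples
#' simulate_path(kinetic_rates(4, 0.1, b_tilde = 0.01),
#'               initial_condition(20), t_max = 1, seed = 42)
#' @export
simulate_path <- function(rates, init, t_max, seed = NULL) {
  stopifnot(inherits(rates, "gsm2_rates"), inherits(init, "gsm2_init"),
            t_max >= 0)
  if (!is.null(seed)) set.seed(seed)
  s0 <- draw_initial_state(init)
  m <- .simulate_path_cpp(s0[1], s0[2], t_max, rates$r, rates$a,
                          rates$b_tilde, rates$a_logistic)
  out <- tibble::tibble(t = m[, 1], x = as.integer(m[, 2]),
                        y = as.integer(m[, 3]))
  new_gsm2_result(out, "gsm2_path", rates = rates, seed = seed)
}

draw_initial_state <- function(init) {
  if (init$mode == "deterministic") {
    c(as.integer(round(init$x0)), as.integer(round(init$y0)))
  } else {
    z <- stats::rnorm(2, mean = c(init$x0, init$y0), sd = sqrt(init$sigma))
    pmax(as.integer(round(z)), 0L)
  }
}

#' Simulate a seeded ensemble of exact paths
#'
#' Runs `n_paths` independent Gillespie paths and records the state at each
#' observation time (event-driven paths are resampled onto the grid as
#' right-continuous step functions). Each path uses its own RNG stream seeded
#' from `(seed, path index)`, so the ensemble is reproducible and independent
#' of execution order.
#'
#' @inheritParams simulate_path
#' @param t_points increasing observation times.
#' @param n_paths number of paths, `>= 1`.
#' @return A tibble of class `gsm2_ensemble`, long format with columns
#'   `path`, `t`, `x`, `y`, and attributes `rates`, `init`, `seed`,
#'   `n_paths`.
#' @examples
#' ens <- simulate_ensemble(kinetic_rates(4, 0.1, b_tilde = 0.01),
#'                          initial_condition(20), t_points = c(0.5, 1),
#'                          n_paths = 100, seed = 1)
#' ensemble_moments(ens)
#' @export
simulate_ensemble <- function(rates, init, t_points, n_paths = 10000,
                              seed = 1L) {
  stopifnot(inherits(rates, "gsm2_rates"), inherits(init, "gsm2_init"))
  if (length(t_points) == 0L) stop("`t_points` must be non-empty", call. = FALSE)
  t_points <- as.numeric(t_points)
  if (is.unsorted(t_points)) stop("`t_points` must be increasing", call. = FALSE)
  if (n_paths < 1) stop("`n_paths` must be at least 1", call. = FALSE)
  set.seed(seed)
  path_seeds <- sample.int(.Machine$integer.max, n_paths)
  t_max <- max(t_points)
  m <- length(t_points)
  xs <- matrix(0L, nrow = n_paths, ncol = m)
  ys <- matrix(0L, nrow = n_paths, ncol = m)
  for (i in seq_len(n_paths)) {
    set.seed(path_seeds[i])
    s0 <- draw_initial_state(init)
    p <- .simulate_path_cpp(s0[1], s0[2], t_max, rates$r, rates$a,
                            rates$b_tilde, rates$a_logistic)
    g <- .sample_on_grid_cpp(p, t_points)
    xs[i, ] <- g[, 1]
    ys[i, ] <- g[, 2]
  }
  out <- tibble::tibble(
    path = rep(seq_len(n_paths), times = m),
    t = rep(t_points, each = n_paths),
    x = as.vector(xs),
    y = as.vector(ys)
  )
  new_gsm2_result(out, "gsm2_ensemble", rates = rates, init = init,
                  seed = seed, n_paths = n_paths)
}

#' Empirical marginals of an ensemble
#'
#' Normalised count histograms of X and Y at each observation time, on
#' unit-width integer bins.
#'
#' @param ensemble a [simulate_ensemble()] result (or any long data frame
#'   with columns `t`, `x`, `y`).
#' @return A tibble with columns `t`, `lesion` (`"sublethal"`/`"lethal"`),
#'   `count`, `prob`; probabilities sum to 1 within each `(t, lesion)`.
#' @export
ensemble_marginals <- function(ensemble) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(ensemble), "t", "x", "y"),
    c("x", "y"), names_to = "lesion", values_to = "count")
  long$lesion <- ifelse(long$lesion == "x", "sublethal", "lethal")
  counted <- dplyr::count(long, .data$t, .data$lesion, .data$count)
  out <- dplyr::mutate(dplyr::group_by(counted, .data$t, .data$lesion),
                       prob = .data$n / sum(.data$n))
  dplyr::select(dplyr::ungroup(out), -"n")
}

#' Empirical moments of an ensemble
#'
#' @inheritParams ensemble_marginals
#' @return A tibble with per-time columns `mean_x`, `var_x`, `mean_y`,
#'   `var_y`, `cov_xy`, `n_paths`, and standard errors `se_mean_x`,
#'   `se_mean_y`, `se_var_x`, `se_var_y`, `se_cov_xy` (moment-based
#'   large-sample errors, suitable for z-type comparisons against exact
#'   moments).
#' @export
ensemble_moments <- function(ensemble) {
  df <- tibble::as_tibble(ensemble)
  dplyr::summarise(
    dplyr::group_by(df, .data$t),
    mean_x = mean(.data$x), var_x = stats::var(.data$x),
    mean_y = mean(.data$y), var_y = stats::var(.data$y),
    cov_xy = stats::cov(.data$x, .data$y),
    n_paths = dplyr::n(),
    se_mean_x = sqrt(.data$var_x / .data$n_paths),
    se_mean_y = sqrt(.data$var_y / .data$n_paths),
    se_var_x = se_var(.data$x),
    se_var_y = se_var(.data$y),
    se_cov_xy = se_cov(.data$x, .data$y),
    .groups = "drop"
  )
}

# large-sample standard error of a sample variance: sqrt((m4 - s^4)/n)
se_var <- function(v) {
  n <- length(v)
  m <- mean(v)
  m4 <- mean((v - m)^4)
  s2 <- stats::var(v)
  sqrt(max(m4 - s2^2, 0) / n)
}

# large-sample standard error of a sample covariance
se_cov <- function(v, w) {
  n <- length(v)
  dv <- v - mean(v); dw <- w - mean(w)
  s11 <- stats::cov(v, w)
  sqrt(max(mean(dv^2 * dw^2) - s11^2, 0) / n)
}

#' @export
tidy.gsm2_ensemble <- function(x, ...) ensemble_moments(x)

#' @export
glance.gsm2_ensemble <- function(x, ...) {
  mom <- ensemble_moments(x)
  last <- mom[nrow(mom), ]
  tibble::tibble(
    n_paths = attr(x, "n_paths"),
    seed = attr(x, "seed"),
    t_final = last$t,
    mean_y_final = last$mean_y,
    dispersion_y_final = ifelse(last$mean_y > 0, last$var_y / last$mean_y, NaN)
  )
}

#' @export
autoplot.gsm2_ensemble <- function(object, ...) {
  marg <- ensemble_marginals(object)
  ggplot2::ggplot(marg, ggplot2::aes(x = .data$count, y = .data$prob)) +
    ggplot2::geom_col(width = 1, fill = "grey70", colour = "grey40") +
    ggplot2::facet_grid(lesion ~ t, scales = "free") +
    ggplot2::labs(x = "lesion count", y = "probability") +
    ggplot2::theme_minimal()
}
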