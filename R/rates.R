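#' Kinetic rate parameters of the lesion network
#'
#' The model tracks sublethal lesions X and lethal lesions Y in a single cell
#' nucleus. A sublethal lesion is repaired at rate `r`, converts directly to a
#' lethal lesion at rate `a`, or pairs with another sublethal lesion to form a
#' lethal one. The pairwise channel has two equivalent parameterisations tied
#' together by the system size `K`:
#' the count-scale rate `b_tilde` (the propensity of the pairwise channel is
#' `b_tilde * x * (x - 1)`) and the macroscopic rate `b = b_tilde * K`, which
#' is the quadratic coefficient of the deterministic limit. Supply either one;
#' the other is derived.
#'
#' @param r repair rate (1/time), `>= 0`.
#' @param a direct lethal-conversion rate (1/time), `>= 0`.
#' @param b macroscopic pairwise-interaction rate (1/time); give `b` or
#'   `b_tilde`, not both.
#' @param b_tilde count-scale pairwise rate (1/time).
#' @param a_logistic optional logistic death increment: with
#'   `a_logistic > 0` the direct-death propensity becomes
#'   `x * (a + a_logistic * x)`. Default 0 (constant death rate).
#' @param K system size (dimensionless, `> 0`). Counts relate to macroscopic
#'   concentrations through `X = K * x_bar + sqrt(K) * xi`.
#'
#' @return An object of class `gsm2_rates`: a named list with fields `r`,
#'   `a`, `b`, `b_tilde`, `a_logistic`, `K`.
#'
#' @examples
#' kinetic_rates(r = 4, a = 0.1, b_tilde = 0.01, K = 100)
#' @export
kinetic_rates <- function(r, a, b = NULL, b_tilde = NULL, a_logistic = 0, K = 1) {
  stopifnot(is.numeric(r), length(r) == 1L, is.numeric(a), length(a) == 1L,
            is.numeric(K), length(K) == 1L, is.numeric(a_logistic),
            length(a_logistic) == 1L)
  if (r < 0 || a < 0 || a_logistic < 0)
    stop("rates `r`, `a`, `a_logistic` must be non-negative", call. = FALSE)
  if (K <= 0) stop("system size `K` must be positive", call. = FALSE)
  if (is.null(b) && is.null(b_tilde))
    stop("supply one of `b` or `b_tilde`", call. = FALSE)
  if (!is.null(b) && !is.null(b_tilde) &&
      abs(b - b_tilde * K) > 1e-12 * max(1, abs(b)))
    stop("`b` and `b_tilde` are inconsistent: `b` must equal `b_tilde * K`",
         call. = FALSE)
  if (is.null(b)) b <- b_tilde * K
  if (is.null(b_tilde)) b_tilde <- b / K
  if (b < 0) stop("pairwise rate must be non-negative", call. = FALSE)
  structure(
    list(r = as.numeric(r), a = as.numeric(a), b = as.numeric(b),
         b_tilde = as.numeric(b_tilde), a_logistic = as.numeric(a_logistic),
         K = as.numeric(K)),
    class = "gsm2_rates"
  )
}

#' @method print gsm2_rates
#' @export
print.gsm2_rates <- function(x, ...) {
  cat("<gsm2_rates>\n")
  cat(sprintf("  repair r = %g, direct lethal a = %g", x$r, x$a))
  if (x$a_logistic > 0) cat(sprintf(" (+ logistic %g per lesion)", x$a_logistic))
  cat("\n")
  cat(sprintf("  pairwise b_tilde = %g (count scale), b = %g (macroscopic), K = %g\n",
              x$b_tilde, x$b, x$K))
  invisible(x)
}

#' Initial lesion counts, deterministic or Gaussian
#'
#' In `deterministic` mode the initial law is a point mass at `(x0, y0)`. In
#' `gaussian` mode the initial counts follow a bivariate normal with mean
#' `(x0, y0)` and diagonal covariance `sigma`; the default is Poisson-like,
#' variance equal to the mean on each coordinate. Samplers that need integer
#' states round and clamp at zero (documented approximation).
#'
#' @param x0 initial sublethal lesion count, `>= 0`.
#' @param y0 initial lethal lesion count, `>= 0`.
#' @param mode `"deterministic"` or `"gaussian"`.
#' @param sigma length-2 vector `(var_x, var_y)` of the diagonal initial
#'   covariance on the count scale; used only in gaussian mode.
#'
#' @return An object of class `gsm2_init`.
#' @examples
#' initial_condition(100)
#' initial_condition(100, 0, mode = "gaussian")
#' @export
initial_condition <- function(x0, y0 = 0,
                              mode = c("deterministic", "gaussian"),
                              sigma = c(x0, y0)) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(x0), length(x0) == 1L, is.numeric(y0), length(y0) == 1L)
  if (x0 < 0 || y0 < 0) stop("initial counts must be non-negative", call. = FALSE)
  sigma <- as.numeric(sigma)
  if (length(sigma) != 2L || any(sigma < 0))
    stop("`sigma` must be two non-negative variances (var_x, var_y)",
         call. = FALSE)
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0), mode = mode,
                 sigma = sigma),
            class = "gsm2_init")
}

#' @method print gsm2_init
#' @export
print.gsm2_init <- function(x, ...) {
  cat(sprintf("<gsm2_init> x0 = %g, y0 = %g (%s", x$x0, x$y0, x$mode))
  if (x$mode == "gaussian")
    cat(sprintf(", sigma = diag(%g, %g)", x$sigma[1], x$sigma[2]))
  cat(")\n")
  invisible(x)
}

#' Reference configuration of the damage-kinetics study
#'
#' The parameter set used throughout the worked examples and reports:
#' `r = 4`, `a = 0.1`, `b_tilde = 0.01` (all in 1/time, arbitrary units),
#' deterministic initial counts `x0 = 100`, `y0 = 0`, observation times
#' 0.5, 0.7, 0.9 a.u. The system size follows the convention `K = x0`, so the
#' macroscopic initial concentration is 1 and the macroscopic pairwise rate is
#' `b = b_tilde * K`. All count-scale results are invariant to this choice.
#'
#' @param x0,y0 initial counts (defaults 100 and 0).
#' @param n_paths default ensemble size for simulation-based reports.
#' @param seed default RNG seed.
#' @return A `gsm2_config` list with elements `rates`, `init`, `t_points`,
#'   `n_paths`, `dt`, `seed`.
#' @examples
#' cfg <- reference_config()
#' cfg$rates
#' @export
reference_config <- function(x0 = 100, y0 = 0, n_paths = 10000, seed = 1L) {
  run_config(
    rates = kinetic_rates(r = 4, a = 0.1, b_tilde = 0.01, K = x0),
    init = initial_condition(x0, y0),
    t_points = c(0.5, 0.7, 0.9),
    n_paths = n_paths,
    dt = 1e-3,
    seed = seed
  )
}

#' Assemble a run configuration
#'
#' Bundles rates, initial condition, observation grid and simulation controls
#' into a single validated object consumed by the `report_*()` functions and
#' the command-line front end.
#'
#' @param rates a [kinetic_rates()] object.
#' @param init an [initial_condition()] object.
#' @param t_points increasing positive observation times.
#' @param n_paths ensemble size for stochastic simulation, `>= 1`.
#' @param dt Euler-Maruyama step for the Ornstein-Uhlenbeck sampler.
#' @param seed integer RNG seed.
#' @return A `gsm2_config` list.
#' @export
run_config <- function(rates, init, t_points = c(0.5, 0.7, 0.9),
                       n_paths = 10000, dt = 1e-3, seed = 1L) {
  stopifnot(inherits(rates, "gsm2_rates"), inherits(init, "gsm2_init"))
  t_points <- as.numeric(t_points)
  if (length(t_points) == 0L || any(t_points < 0) || is.unsorted(t_points, strictly = TRUE))
    stop("`t_points` must be strictly increasing and non-negative", call. = FALSE)
  if (n_paths < 1) stop("`n_paths` must be at least 1", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  structure(list(rates = rates, init = init, t_points = t_points,
                 n_paths = as.integer(n_paths), dt = as.numeric(dt),
                 seed = as.integer(seed)),
            class = "gsm2_config")
}

#' @method print gsm2_config
#' @export
print.gsm2_config <- function(x, ...) {
  cat("<gsm2_config>\n")
  print(x$rates)
  print(x$init)
  cat(sprintf("  t_points = [%s], n_paths = %d, dt = %g, seed = %d\n",
              paste(signif(x$t_points, 4), collapse = ", "),
              x$n_paths, x$dt, x$seed))
  invisible(x)
}

#' Read or write a run configuration as JSON
#'
#' The JSON schema is a flat block
#' `{r, a, b | b_tilde, a_logistic, K, x0, y0, mode, sigma, t_points,
#' n_paths, dt, seed}`. Missing simulation controls fall back to defaults.
#'
#' @param path file path.
#' @return `read_config()` returns a `gsm2_config`; `write_config()` returns
#'   `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_config(reference_config(), path)
#' read_config(path)
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rates <- kinetic_rates(
    r = j$r, a = j$a,
    b = if (!is.null(j$b) && is.null(j$b_tilde)) j$b else NULL,
    b_tilde = j$b_tilde,
    a_logistic = j$a_logistic %||% 0,
    K = j$K %||% 1
  )
  init <- initial_condition(
    x0 = j$x0, y0 = j$y0 %||% 0,
    mode = j$mode %||% "deterministic",
    sigma = j$sigma %||% c(j$x0, j$y0 %||% 0)
  )
  run_config(rates, init,
             t_points = j$t_points %||% c(0.5, 0.7, 0.9),
             n_paths = j$n_paths %||% 10000,
             dt = j$dt %||% 1e-3,
             seed = j$seed %||% 1L)
}

#' @rdname read_config
#' @param config a `gsm2_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "gsm2_config"))
  block <- c(unclass(config$rates), unclass(config$init),
             list(t_points = config$t_points, n_paths = config$n_paths,
                  dt = config$dt, seed = config$seed))
  jsonlite::write_json(block, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
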