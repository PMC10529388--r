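#' Drift and diffusion of the fluctuation Ornstein-Uhlenbeck process
#'
#' The linear Fokker-Planck equation for the fluctuations `(upsilon, xi)` is
#' the law of a time-dependent Ornstein-Uhlenbeck process
#' `dZ = -A(t) Z dt + Q(t) dW` with, on the `(upsilon, xi)` ordering,
#' \deqn{A(t) = \begin{pmatrix} 0 & -(2b\bar x + a) \\
#'                              0 & 4b\bar x + a + r \end{pmatrix}, \quad
#'       D(t) = \begin{pmatrix} a\bar x + b\bar x^2 &
#'                              -(a\bar x + 2b\bar x^2) \\
#'                              -(a\bar x + 2b\bar x^2) &
#'                              (a+r)\bar x + 4b\bar x^2 \end{pmatrix},}
#' W a two-dimensional standard Brownian motion, and `Q` any factor with
#' `Q Q' = D` (the law depends only on `D`; a closed-form 2x2 Cholesky factor
#' is used, valid because `det D = x_bar^2 (a r + b x_bar (a + r)) >= 0`).
#'
#' @param rates a [kinetic_rates()] object.
#' @param x_bar macroscopic sublethal value (macro scale) at the time of
#'   interest, e.g. from [xbar_closed_form()].
#' @return A list with matrices `A`, `D`, `Q` (2x2, `(upsilon, xi)`
#'   ordering).
#' @examples
#' ou_coefficients(kinetic_rates(4, 0.1, b_tilde = 0.01, K = 100), x_bar = 1)
#' @export
ou_coefficients <- function(rates, x_bar) {
  stopifnot(inherits(rates, "gsm2_rates"), length(x_bar) == 1L)
  if (x_bar < 0) stop("`x_bar` must be non-negative", call. = FALSE)
  a <- rates$a; r <- rates$r; b <- rates$b
  xb <- x_bar
  A <- matrix(c(0, 0, -(2 * b * xb + a), 4 * b * xb + a + r), 2, 2,
              dimnames = list(c("upsilon", "xi"), c("upsilon", "xi")))
  d11 <- a * xb + b * xb^2
  d12 <- -(a * xb + 2 * b * xb^2)
  d22 <- (a + r) * xb + 4 * b * xb^2
  D <- matrix(c(d11, d12, d12, d22), 2, 2, dimnames = dimnames(A))
  Q <- chol2_psd(d11, d12, d22)
  dimnames(Q) <- dimnames(A)
  list(A = A, D = D, Q = Q)
}

# lower-triangular factor of a symmetric PSD 2x2 [[d11, d12], [d12, d22]]
chol2_psd <- function(d11, d12, d22) {
  if (min(d11, d22) < -1e-9 || d11 * d22 - d12^2 < -1e-9 * max(1, d11 * d22))
    stop("diffusion matrix has a negative eigenvalue: invalid macroscopic state",
         call. = FALSE)
  if (d11 <= 0) {
    # first coordinate noiseless (only at x_bar = 0, where D = 0)
    return(matrix(c(0, 0, 0, sqrt(max(d22, 0))), 2, 2))
  }
  l11 <- sqrt(d11)
  l21 <- d12 / l11
  l22 <- sqrt(max(d22 - l21^2, 0))
  matrix(c(l11, l21, 0, l22), 2, 2)
}

#' Euler-Maruyama ensemble of the fluctuation OU process
#'
#' Simulates `n_paths` trajectories of the time-dependent OU process whose
#' law solves the linear Fokker-Planck equation, evaluating the macroscopic
#' coefficient `x_bar(t)` at every substep through the closed-form Bernoulli
#' solution. With `boundary = "absorb"` a path whose count-scale sublethal
#' number `X = K*x_bar + sqrt(K)*xi` reaches 0 is pinned there: `xi` follows
#' the boundary value `-sqrt(K)*x_bar(t)` and `upsilon` is frozen
#' simultaneously, since no reaction can fire without sublethal lesions.
#'
#' @param rates a [kinetic_rates()] object.
#' @param init an [initial_condition()] object; deterministic gives `Z(0)=0`,
#'   Gaussian gives centred normal fluctuations with count-scale covariance
#'   `diag(sigma)` (fluctuation-scale `sigma / K`).
#' @param t_points increasing recording times.
#' @param n_paths ensemble size.
#' @param dt Euler-Maruyama step (default 1e-3 a.u.; the macroscopic decay
#'   time is `1/(a+r)`, about 0.24 a.u. at the reference rates).
#' @param seed integer RNG seed.
#' @param boundary `"none"` (free Gaussian dynamics) or `"absorb"`.
#' @return A tibble of class `gsm2_ou`, long format with columns `path`,
#'   `t`, `upsilon`, `xi` and count-scale `x`, `y`; attributes `rates`,
#'   `init`, `seed`, `dt`, `boundary`, `n_paths`.
#' @examples
#' rates <- kinetic_rates(4, 0.1, b_tilde = 0.01, K = 100)
#' ou <- simulate_ou(rates, initial_condition(100), t_points = c(0.5, 0.9),
#'                   n_paths = 200, seed = 1)
#' @export
simulate_ou <- function(rates, init, t_points, n_paths = 10000, dt = 1e-3,
                        seed = 1L, boundary = c("none", "absorb")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(rates, "gsm2_rates"), inherits(init, "gsm2_init"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  t_points <- as.numeric(t_points)
  if (length(t_points) == 0L || is.unsorted(t_points))
    stop("`t_points` must be non-empty and increasing", call. = FALSE)
  K <- rates$K
  x_bar0 <- init$x0 / K
  a <- rates$a; r <- rates$r; b <- rates$b

  # step grid: multiples of dt, with the recording times spliced in
  t_max <- max(t_points)
  grid <- sort(unique(c(seq(0, t_max, by = dt), t_points)))
  rec <- match(t_points, grid)

  set.seed(seed)
  if (init$mode == "gaussian") {
    ups <- stats::rnorm(n_paths, 0, sqrt(init$sigma[2] / K))
    xi <- stats::rnorm(n_paths, 0, sqrt(init$sigma[1] / K))
  } else {
    ups <- numeric(n_paths)
    xi <- numeric(n_paths)
  }
  absorbed <- rep(FALSE, n_paths)
  ups_rec <- matrix(0, n_paths, length(t_points))
  xi_rec <- matrix(0, n_paths, length(t_points))

  if (1 %in% rec) {
    j <- which(rec == 1)
    ups_rec[, j] <- ups; xi_rec[, j] <- xi
  }
  for (k in seq_len(length(grid) - 1L)) {
    h <- grid[k + 1L] - grid[k]
    xb <- xbar_closed_form(grid[k], rates, x_bar0, scale = "macro")
    drift_u <- (2 * b * xb + a) * xi
    drift_x <- -(4 * b * xb + a + r) * xi
    co <- ou_coefficients(rates, xb)
    w1 <- stats::rnorm(n_paths, 0, sqrt(h))
    w2 <- stats::rnorm(n_paths, 0, sqrt(h))
    ups_new <- ups + drift_u * h + co$Q[1, 1] * w1
    xi_new <- xi + drift_x * h + co$Q[2, 1] * w1 + co$Q[2, 2] * w2
    if (boundary == "absorb") {
      xb_next <- xbar_closed_form(grid[k + 1L], rates, x_bar0, scale = "macro")
      hit <- !absorbed & (K * xb_next + sqrt(K) * xi_new <= 0)
      absorbed <- absorbed | hit
      # frozen paths: X pinned at 0, upsilon constant
      xi_new[absorbed] <- -sqrt(K) * xb_next
      ups_new[absorbed] <- ups[absorbed]
    }
    ups <- ups_new
    xi <- xi_new
    j <- which(rec == k + 1L)
    if (length(j)) { ups_rec[, j] <- ups; xi_rec[, j] <- xi }
  }

  xb_rec <- xbar_closed_form(t_points, rates, x_bar0, scale = "macro")
  macro <- solve_mkm(rates, x_bar0, init$y0 / K,
                     t_grid = unique(c(0, t_points)), scale = "macro")
  yb_rec <- macro$y_bar[match(t_points, macro$t)]
  m <- length(t_points)
  out <- tibble::tibble(
    path = rep(seq_len(n_paths), times = m),
    t = rep(t_points, each = n_paths),
    upsilon = as.vector(ups_rec),
    xi = as.vector(xi_rec),
    x = rep(K * xb_rec, each = n_paths) + sqrt(K) * as.vector(xi_rec),
    y = rep(K * yb_rec, each = n_paths) + sqrt(K) * as.vector(ups_rec)
  )
  new_gsm2_result(out, "gsm2_ou", rates = rates, init = init, seed = seed,
                  dt = dt, boundary = boundary, n_paths = n_paths)
}

#' Empirical fluctuation moments of an OU ensemble
#'
#' @param ou a [simulate_ou()] result.
#' @return A tibble with per-time sample means, variances and covariance of
#'   `(upsilon, xi)` plus large-sample standard errors.
#' @export
ou_moments <- function(ou) {
  df <- tibble::as_tibble(ou)
  dplyr::summarise(
    dplyr::group_by(df, .data$t),
    mean_ups = mean(.data$upsilon), mean_xi = mean(.data$xi),
    c_upsups = stats::var(.data$upsilon),
    c_xiups = stats::cov(.data$xi, .data$upsilon),
    c_xixi = stats::var(.data$xi),
    n_paths = dplyr::n(),
    se_mean_ups = sqrt(.data$c_upsups / .data$n_paths),
    se_mean_xi = sqrt(.data$c_xixi / .data$n_paths),
    se_c_upsups = se_var(.data$upsilon),
    se_c_xiups = se_cov(.data$xi, .data$upsilon),
    se_c_xixi = se_var(.data$xi),
    .groups = "drop"
  )
}

#' @export
tidy.gsm2_ou <- function(x, ...) ou_moments(x)

#' @export
glance.gsm2_ou <- function(x, ...) {
  mom <- ou_moments(x)
  last <- mom[nrow(mom), ]
  tibble::tibble(
    n_paths = attr(x, "n_paths"),
    dt = attr(x, "dt"),
    boundary = attr(x, "boundary"),
    t_final = last$t,
    c_upsups_final = last$c_upsups,
    c_xiups_final = last$c_xiups
  )
}
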