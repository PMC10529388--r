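#' Transition-rate generator of the master equation on a finite lattice
#'
#' Builds the sparse generator G of the master equation
#' `dp/dt = G p` over the lattice `0 <= x <= x_max`, `0 <= y <= y_max`,
#' states enumerated row-major over `(y, x)` with `x` fastest. Since every
#' channel removes sublethal lesions and each lethal lesion consumes at least
#' one sublethal, the reachable set from `(x0, y0)` is contained in
#' `x <= x0`, `y <= y0 + x0`: with bounds at least that large the generator is
#' conservative (all column sums are zero) and truncation introduces no error.
#' Channels whose target would leave the lattice are dropped together with
#' their outflow, so conservation holds by construction on any bounds.
#'
#' @param rates a [kinetic_rates()] object (count-scale `b_tilde` is used).
#' @param x_max,y_max lattice bounds.
#' @return A `dgCMatrix` of dimension `(x_max+1)(y_max+1)` squared, with
#'   attributes `x_max`, `y_max` and the state enumeration helpers used by
#'   [cme_solve()].
#' @examples
#' G <- cme_generator(kinetic_rates(4, 0.1, b_tilde = 0.01), 5, 5)
#' max(abs(Matrix::colSums(G)))
#' @export
cme_generator <- function(rates, x_max, y_max) {
  stopifnot(inherits(rates, "gsm2_rates"), x_max >= 0, y_max >= 0)
  nx <- x_max + 1L
  ny <- y_max + 1L
  idx <- function(y, x) y * nx + x + 1L   # row-major over (y, x), x fastest
  x <- rep(0:x_max, times = ny)
  y <- rep(0:y_max, each = nx)
  from <- idx(y, x)

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(sel, to, rate) {
    ii <<- c(ii, to, from[sel])
    jj <<- c(jj, from[sel], from[sel])
    vv <<- c(vv, rate, -rate)
  }
  # repair: (y, x) -> (y, x-1) at r*x
  sel <- x >= 1
  if (any(sel)) add(sel, idx(y[sel], x[sel] - 1L), rates$r * x[sel])
  # direct lethal: (y, x) -> (y+1, x-1) at x*(a + a_logistic*x)
  sel <- x >= 1 & y + 1L <= y_max
  if (any(sel)) add(sel, idx(y[sel] + 1L, x[sel] - 1L),
                    x[sel] * (rates$a + rates$a_logistic * x[sel]))
  # pairwise: (y, x) -> (y+1, x-2) at b_tilde*x*(x-1)
  sel <- x >= 2 & y + 1L <= y_max
  if (any(sel)) add(sel, idx(y[sel] + 1L, x[sel] - 2L),
                    rates$b_tilde * x[sel] * (x[sel] - 1))
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nx * ny, nx * ny))
  attr(G, "x_max") <- x_max
  attr(G, "y_max") <- y_max
  G
}

#' Exact integration of the truncated master equation
#'
#' Integrates `dp/dt = G p` with a sparse stiff solver
#' ([deSolve::lsodes()]), the generator's own sparsity pattern supplied as
#' the Jacobian structure (the system is linear, so G is its Jacobian).
#' Feasible up to roughly `x0 = 200` (about 40k states); larger problems
#' should use [simulate_ensemble()] or [solve_lna()].
#'
#' @param rates a [kinetic_rates()] object.
#' @param init an [initial_condition()] object; a deterministic start places
#'   a point mass, a Gaussian start discretises the rounded/clamped normal
#'   law onto the lattice.
#' @param t_grid increasing times (0 is prepended if absent).
#' @param x_max,y_max lattice bounds; defaults are reachability-tight
#'   (`x_max = x0`, `y_max = y0 + x0`), within which no truncation error
#'   exists.
#' @param rtol,atol solver tolerances.
#' @return An object of class `gsm2_cme`: a list with `t_grid`, `mass` (list
#'   of `(y_max+1) x (x_max+1)` probability matrices, rows = y), `rates`,
#'   and lattice bounds. Mass conservation is checked to 1e-9 and solver
#'   failure is an error, never silently clipped.
#' @examples
#' sol <- cme_solve(kinetic_rates(4, 0.1, b_tilde = 0.01),
#'                  initial_condition(10), t_grid = c(0.5, 1))
#' cme_moments(sol)
#' @export
cme_solve <- function(rates, init, t_grid, x_max = NULL, y_max = NULL,
                      rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(rates, "gsm2_rates"), inherits(init, "gsm2_init"))
  x0 <- as.integer(round(init$x0)); y0 <- as.integer(round(init$y0))
  if (is.null(x_max)) x_max <- x0 + if (init$mode == "gaussian")
    as.integer(ceiling(6 * sqrt(max(init$sigma[1], 1)))) else 0L
  if (is.null(y_max)) y_max <- y0 + x_max + if (init$mode == "gaussian")
    as.integer(ceiling(6 * sqrt(max(init$sigma[2], 1)))) else 0L
  if (x_max < x0 || y_max < y0 + x0)
    stop("lattice bounds too small for the initial condition", call. = FALSE)
  nx <- x_max + 1L; ny <- y_max + 1L
  G <- cme_generator(rates, x_max, y_max)

  p0 <- initial_mass(init, x_max, y_max)
  t_grid <- as.numeric(t_grid)
  if (is.unsorted(t_grid)) stop("`t_grid` must be increasing", call. = FALSE)
  times <- if (t_grid[1] > 0) c(0, t_grid) else t_grid

  if (max(times) == 0) {
    sol <- matrix(c(0, p0), nrow = 1)
  } else {
    Gt <- methods::as(G, "TsparseMatrix")
    inz <- cbind(Gt@i + 1L, Gt@j + 1L)
    rhs <- function(t, p, parms) list(as.numeric(G %*% p))
    sol <- deSolve::lsodes(y = p0, times = times, func = rhs, parms = NULL,
                           rtol = rtol, atol = atol, sparsetype = "sparseusr",
                           inz = inz, lrw = max(200000, 80 * nrow(inz)))
    if (attr(sol, "istate")[1] < 0)
      stop("master-equation solver failed", call. = FALSE)
  }
  keep <- match(t_grid, sol[, 1])
  mass <- lapply(keep, function(k) {
    p <- sol[k, -1]
    drift <- abs(sum(p) - 1)
    if (drift > 1e-9)
      stop(sprintf("probability mass drifted by %.2e (> 1e-9)", drift),
           call. = FALSE)
    matrix(p, nrow = ny, ncol = nx, byrow = TRUE,
           dimnames = list(y = 0:y_max, x = 0:x_max))
  })
  structure(list(t_grid = t_grid, mass = mass, rates = rates, init = init,
                 x_max = x_max, y_max = y_max),
            class = "gsm2_cme")
}

# point mass, or a rounded/clamped discretisation of the Gaussian initial law
initial_mass <- function(init, x_max, y_max) {
  nx <- x_max + 1L; ny <- y_max + 1L
  if (init$mode == "deterministic") {
    p0 <- numeric(nx * ny)
    p0[round(init$y0) * nx + round(init$x0) + 1L] <- 1
    return(p0)
  }
  px <- discretised_normal(0:x_max, init$x0, sqrt(init$sigma[1]))
  py <- discretised_normal(0:y_max, init$y0, sqrt(init$sigma[2]))
  as.numeric(outer(px, py))  # vec over (y, x) with x fastest
}

# P(round(clamp(Z)) = k) for Z ~ N(mean, sd), mass below 0 folded into 0
discretised_normal <- function(k, mean, sd) {
  if (sd == 0) return(as.numeric(k == round(mean)))
  hi <- stats::pnorm(k + 0.5, mean, sd)
  lo <- stats::pnorm(k - 0.5, mean, sd)
  p <- hi - lo
  p[1] <- hi[1]                       # fold negative mass into 0
  p[length(p)] <- p[length(p)] + stats::pnorm(max(k) + 0.5, mean, sd,
                                              lower.tail = FALSE)
  p / sum(p)
}

#' @method print gsm2_cme
#' @export
print.gsm2_cme <- function(x, ...) {
  cat(sprintf("<gsm2_cme> lattice x <= %d, y <= %d (%d states), times [%s]\n",
              x$x_max, x$y_max, (x$x_max + 1) * (x$y_max + 1),
              paste(signif(x$t_grid, 4), collapse = ", ")))
  invisible(x)
}

#' Marginal laws from an exact master-equation solution
#'
#' @param sol a [cme_solve()] result.
#' @return A tibble with columns `t`, `lesion` (`"sublethal"`/`"lethal"`),
#'   `count`, `prob`.
#' @export
cme_marginals <- function(sol) {
  stopifnot(inherits(sol, "gsm2_cme"))
  purrr::list_rbind(purrr::map2(sol$mass, sol$t_grid, function(m, t) {
    dplyr::bind_rows(
      tibble::tibble(t = t, lesion = "sublethal", count = 0:sol$x_max,
                     prob = unname(colSums(m))),
      tibble::tibble(t = t, lesion = "lethal", count = 0:sol$y_max,
                     prob = unname(rowSums(m)))
    )
  }))
}

#' Exact moments from a master-equation solution
#'
#' Means, variances and the covariance of the lesion counts by direct
#' summation over the lattice.
#'
#' @param sol a [cme_solve()] result.
#' @return A tibble with columns `t`, `mean_x`, `var_x`, `mean_y`, `var_y`,
#'   `cov_xy`, `dispersion_y` (`var_y / mean_y`, `NaN` at `mean_y = 0`).
#' @export
cme_moments <- function(sol) {
  stopifnot(inherits(sol, "gsm2_cme"))
  xg <- 0:sol$x_max
  yg <- 0:sol$y_max
  purrr::list_rbind(purrr::map2(sol$mass, sol$t_grid, function(m, t) {
    px <- colSums(m); py <- rowSums(m)
    ex <- sum(xg * px); ey <- sum(yg * py)
    vx <- sum(xg^2 * px) - ex^2
    vy <- sum(yg^2 * py) - ey^2
    exy <- as.numeric(t(yg) %*% m %*% xg)
    tibble::tibble(t = t, mean_x = ex, var_x = max(vx, 0),
                   mean_y = ey, var_y = max(vy, 0),
                   cov_xy = exy - ex * ey,
                   dispersion_y = ifelse(ey > 0, max(vy, 0) / ey, NaN))
  }))
}

#' @export
tidy.gsm2_cme <- function(x, ...) cme_moments(x)

#' @export
glance.gsm2_cme <- function(x, ...) {
  mom <- cme_moments(x)
  last <- mom[nrow(mom), ]
  tibble::tibble(
    n_states = (x$x_max + 1) * (x$y_max + 1),
    t_final = last$t,
    mean_y_final = last$mean_y,
    var_y_final = last$var_y,
    dispersion_y_final = last$dispersion_y
  )
}
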