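#' Total-variation distance between two discrete count laws
#'
#' `0.5 * sum |p - q|` over the union of the integer supports; missing
#' counts carry zero mass.
#'
#' @param p,q data frames with columns `count`, `prob`.
#' @return A number in `[0, 1]`.
#' @examples
#' tv_distance(data.frame(count = 0:1, prob = c(0.5, 0.5)),
#'             data.frame(count = 0:1, prob = c(0.4, 0.6)))
#' @export
tv_distance <- function(p, q) {
  j <- dplyr::full_join(
    tibble::tibble(count = p$count, p = p$prob),
    tibble::tibble(count = q$count, q = q$prob),
    by = "count"
  )
  j[is.na(j)] <- 0
  sum(abs(j$p - j$q)) / 2
}

#' Kolmogorov-Smirnov distance between an empirical count law and a Gaussian
#'
#' Compares the empirical CDF of integer counts with a normal CDF evaluated
#' with continuity correction (at `count + 0.5`), the fair discrete-versus-
#' continuous comparison on unit-width bins.
#'
#' @param emp a data frame with columns `count`, `prob` (empirical law).
#' @param mean,sd parameters of the Gaussian.
#' @return The supremum CDF discrepancy.
#' @export
ks_distance_gaussian <- function(emp, mean, sd) {
  o <- order(emp$count)
  counts <- emp$count[o]
  cdf_emp <- cumsum(emp$prob[o])
  # include a grid point below the support, where the empirical CDF is 0
  grid <- c(min(counts) - 1, counts)
  cdf_e <- c(0, cdf_emp)
  cdf_g <- stats::pnorm(grid + 0.5, mean, sd)
  max(abs(cdf_e - cdf_g))
}

#' Density comparison report (exact simulation vs Gaussian approximation)
#'
#' For each observation time, draws a seeded exact ensemble, computes the
#' linear-noise Gaussian count marginals and (when the lattice is small
#' enough) the exact master-equation marginals, and reports KS and TV
#' distances per lesion type. This is the data behind the classic
#' histogram-with-Gaussian-overlay figure.
#'
#' @param config a [run_config()] / [reference_config()] object.
#' @param include_cme logical or `"auto"` (exact marginals included when
#'   `x0 <= 200`).
#' @param out_dir optional directory; when given, the tables and the
#'   resolved configuration are written there as CSV/JSON.
#' @return A list of class `gsm2_density_report` with tibbles `distances`
#'   (`t`, `lesion`, `ks_lna`, `tv_cme`, `n_paths`), `histograms`
#'   (`t`, `lesion`, `count`, `prob_ssa`, `prob_cme`), and `gaussians`
#'   (`t`, `lesion`, `mean`, `sd`).
#' @examples
#' cfg <- reference_config(x0 = 20, n_paths = 500)
#' rep <- report_density_comparison(cfg)
#' rep$distances
#' @export
report_density_comparison <- function(config, include_cme = "auto",
                                      out_dir = NULL) {
  stopifnot(inherits(config, "gsm2_config"))
  if (identical(include_cme, "auto")) include_cme <- config$init$x0 <= 200
  ens <- simulate_ensemble(config$rates, config$init, config$t_points,
                           config$n_paths, config$seed)
  emp <- ensemble_marginals(ens)
  lna <- solve_lna(config$rates, config$init, config$t_points)
  gau <- gaussian_marginals(lna)
  cme_marg <- NULL
  if (include_cme) {
    sol <- cme_solve(config$rates, config$init, config$t_points)
    cme_marg <- cme_marginals(sol)
  }

  cases <- tidyr::expand_grid(t = config$t_points,
                              lesion = c("sublethal", "lethal"))
  distances <- purrr::pmap(cases, function(t, lesion) {
    e <- emp[emp$t == t & emp$lesion == lesion, ]
    g <- gau[gau$t == t & gau$lesion == lesion, ]
    tv <- NA_real_
    if (!is.null(cme_marg)) {
      m <- cme_marg[cme_marg$t == t & cme_marg$lesion == lesion, ]
      tv <- tv_distance(e, m)
    }
    tibble::tibble(t = t, lesion = lesion,
                   ks_lna = ks_distance_gaussian(e, g$mean, g$sd),
                   tv_cme = tv, n_paths = config$n_paths)
  })
  distances <- purrr::list_rbind(distances)

  histograms <- dplyr::rename(emp, prob_ssa = "prob")
  if (!is.null(cme_marg)) {
    histograms <- dplyr::full_join(
      histograms, dplyr::rename(cme_marg, prob_cme = "prob"),
      by = c("t", "lesion", "count"))
    histograms$prob_ssa[is.na(histograms$prob_ssa)] <- 0
  }
  out <- structure(list(distances = distances, histograms = histograms,
                        gaussians = gau, config = config),
                   class = "gsm2_density_report")
  if (!is.null(out_dir)) write_report(out, out_dir, "density")
  out
}

#' Moment-trajectory report
#'
#' Time evolution of the macroscopic means, the fluctuation covariances, the
#' non-Poissonian correction and the lethal dispersion index, together with
#' the qualitative sign/limit checks: negative cross-covariance, vanishing
#' sublethal moments at long times, and the variance deficit
#' `c_upsups = y_bar - delta`.
#'
#' @param config a [run_config()] object.
#' @param t_grid optional dense grid; defaults to 201 points spanning
#'   `[0, 4 * max(t_points)]`.
#' @param out_dir optional output directory.
#' @return A list of class `gsm2_moment_report` with `moments` (a tibble
#'   with count-scale `mean_x`, `mean_y`, fluctuation covariances, `delta`,
#'   `dispersion_y`) and `checks` (one-row logical tibble).
#' @export
report_moments <- function(config, t_grid = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "gsm2_config"))
  if (is.null(t_grid))
    t_grid <- seq(0, 4 * max(config$t_points), length.out = 201)
  lna <- solve_lna(config$rates, config$init, t_grid)
  cs <- count_scale_moments(lna)
  moments <- tibble::tibble(
    t = lna$t,
    mean_x = cs$mean_x, mean_y = cs$mean_y,
    c_xixi = lna$c_xixi, c_xiups = lna$c_xiups, c_upsups = lna$c_upsups,
    delta = lna$delta,
    var_x = cs$var_x, var_y = cs$var_y,
    dispersion_y = cs$dispersion_y
  )
  pos <- lna$t > 0
  checks <- tibble::tibble(
    covariance_negative = all(lna$c_xiups[pos] < 0) || !any(pos),
    sublethal_moments_vanish =
      abs(lna$c_xixi[nrow(lna)]) < 1e-4 && abs(lna$c_xiups[nrow(lna)]) < 1e-4,
    variance_below_mean = all(lna$c_upsups[pos] < lna$y_bar[pos]) || !any(pos),
    identity_holds = max(abs(lna$c_upsups -
                               (lna$y_bar - lna$y_bar[1] +
                                  lna$c_upsups[1] - lna$delta))) < 1e-6
  )
  out <- structure(list(moments = moments, checks = checks, config = config),
                   class = "gsm2_moment_report")
  if (!is.null(out_dir)) write_report(out, out_dir, "moments")
  out
}

#' Sample-path comparison report
#'
#' A small bundle of exact Gillespie paths, Ornstein-Uhlenbeck approximation
#' paths and the macroscopic mean curve on a shared time grid — the data
#' behind the classic spaghetti-plot comparison.
#'
#' @param config a [run_config()] object.
#' @param n paths per method (default 10); `n = 0` returns the mean curve
#'   only.
#' @param t_grid shared grid; defaults to 101 points over
#'   `[0, max(t_points)]`.
#' @param out_dir optional output directory.
#' @return A list of class `gsm2_path_report` with tibble `paths`
#'   (`source` in `"ssa"`, `"ou"`, `"mean"`; `path`; `t`; `x`; `y`).
#' @export
report_paths <- function(config, n = 10, t_grid = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "gsm2_config"), n >= 0)
  if (is.null(t_grid))
    t_grid <- seq(0, max(config$t_points), length.out = 101)
  t_pos <- t_grid[t_grid > 0]
  macro <- solve_mkm(config$rates, config$init$x0, config$init$y0, t_grid,
                     scale = "count")
  paths <- tibble::tibble(source = "mean", path = 0L, t = macro$t,
                          x = macro$x_bar, y = macro$y_bar)
  if (n > 0) {
    ens <- simulate_ensemble(config$rates, config$init, t_pos, n, config$seed)
    ssa <- dplyr::mutate(tibble::as_tibble(ens), source = "ssa",
                         x = as.numeric(.data$x), y = as.numeric(.data$y))
    ou <- simulate_ou(config$rates, config$init, t_pos, n_paths = n,
                      dt = config$dt, seed = config$seed, boundary = "absorb")
    ou <- dplyr::mutate(
      dplyr::select(tibble::as_tibble(ou), "path", "t", "x", "y"),
      source = "ou", x = pmax(.data$x, 0))
    paths <- dplyr::bind_rows(
      paths,
      dplyr::select(ssa, "source", "path", "t", "x", "y"),
      dplyr::select(ou, "source", "path", "t", "x", "y"))
  }
  out <- structure(list(paths = paths, config = config),
                   class = "gsm2_path_report")
  if (!is.null(out_dir)) write_report(out, out_dir, "paths")
  out
}

write_report <- function(report, out_dir, stem) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in setdiff(names(report), "config")) {
    utils::write.csv(report[[nm]],
                     file.path(out_dir, paste0(stem, "_", nm, ".csv")),
                     row.names = FALSE)
  }
  write_config(report$config, file.path(out_dir, paste0(stem, "_config.json")))
  invisible(out_dir)
}

#' @method print gsm2_density_report
#' @export
print.gsm2_density_report <- function(x, ...) {
  cat("<gsm2_density_report>\n")
  print(x$distances)
  invisible(x)
}

#' @method print gsm2_moment_report
#' @export
print.gsm2_moment_report <- function(x, ...) {
  cat("<gsm2_moment_report>\n")
  print(x$checks)
  invisible(x)
}

#' @method print gsm2_path_report
#' @export
print.gsm2_path_report <- function(x, ...) {
  cat(sprintf("<gsm2_path_report> %d path rows, sources: %s\n",
              nrow(x$paths), paste(unique(x$paths$source), collapse = ", ")))
  invisible(x)
}

#' @export
autoplot.gsm2_density_report <- function(object, ...) {
  h <- object$histograms
  g <- object$gaussians
  dens <- purrr::list_rbind(purrr::pmap(g, function(t, lesion, mean, sd) {
    lo <- floor(mean - 4 * sd); hi <- ceiling(mean + 4 * sd)
    grid <- seq(max(lo, 0), hi, length.out = 200)
    tibble::tibble(t = t, lesion = lesion, count = grid,
                   density = stats::dnorm(grid, mean, sd))
  }))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$count, y = .data$prob_ssa)) +
    ggplot2::geom_col(width = 1, fill = "grey80", colour = "grey55") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density), colour = "goldenrod",
                       linewidth = 0.8) +
    ggplot2::facet_grid(lesion ~ t, scales = "free") +
    ggplot2::labs(x = "lesion count", y = "probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gsm2_moment_report <- function(object, ...) {
  keep <- c("mean_x", "mean_y", "c_xixi", "c_xiups", "c_upsups")
  long <- tidyr::pivot_longer(object$moments[, c("t", keep)], -"t",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [a.u.]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gsm2_path_report <- function(object, ...) {
  p <- tidyr::pivot_longer(object$paths, c("x", "y"),
                           names_to = "lesion", values_to = "count")
  p$lesion <- ifelse(p$lesion == "x", "sublethal", "lethal")
  ggplot2::ggplot(
    p, ggplot2::aes(x = .data$t, y = .data$count,
                    group = interaction(.data$source, .data$path),
                    colour = .data$source)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_line(data = p[p$source == "mean", ], colour = "black",
                       linewidth = 1) +
    ggplot2::facet_wrap(~lesion, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(mean = "black", ssa = "goldenrod",
                                            ou = "steelblue")) +
    ggplot2::labs(x = "time [a.u.]", y = "lesion count", colour = NULL) +
    ggplot2::theme_minimal()
}
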