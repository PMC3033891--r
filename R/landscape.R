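#' Locate and classify the stationary points of the potential
#'
#' Scans the potential gradient on a grid over a search interval, brackets
#' every sign change, refines each root (Brent bracketing plus a
#' curvature-based Newton polish) to a gradient tolerance of 1e-10 in reduced
#' units, classifies each root by its curvature, and assigns a landscape
#' regime:
#'
#' * `double_well` — minimum / maximum / minimum: conducting-dimer well,
#'   transition state, dissociated well (the tug-of-war landscape);
#' * `single_well_dimer` — one minimum held by the subunit-subunit bond
#'   (e.g. `H_B = 0`, or mismatch too small to carve out a second well);
#' * `single_well_dissociated` — one minimum at relieved mismatch (the
#'   membrane has won outright);
#' * `barrierless` — a stationary point with near-zero curvature, i.e. the
#'   landscape is at (or numerically indistinguishable from) the bifurcation
#'   where a well and the transition state coalesce.
#'
#' The default search interval is auto-derived from the parameters so that it
#' brackets both candidate wells with several Morse decay lengths of margin.
#'
#' @param p A [model_params()] object.
#' @param lower,upper Search interval (nm). Defaults derived from `p`; the
#'   interval must contain `r_e`.
#' @param n_grid Number of grid points used for bracketing (default 4001).
#' @param grad_tol Gradient tolerance at reported roots, reduced units
#'   (kBT per r_e; default 1e-10).
#' @param merge_tol Roots closer than `merge_tol * r_e` are merged
#'   (default 1e-6).
#' @param degen_tol Curvature magnitudes below `degen_tol` (reduced units,
#'   kBT per r_e^2) are treated as degenerate and flag the landscape
#'   barrierless (default 1e-8).
#'
#' @return An object of class `memtug_landscape`: a list with `parameters`,
#'   `points` (a tibble of stationary points ordered by `r`, columns `r`,
#'   `energy`, `curvature`, `kind`), `regime`, and the separations `r_dim`,
#'   `r_ts`, `r_diss` (NA where the regime lacks them). Has [tidy()],
#'   [glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' p <- model_params(D_e = 1, r_e = 1, beta = 10, l0 = 2.2, d = 3, H_B = 1)
#' L <- analyze_landscape(p)
#' L$regime
#' tidy(L)
#' @export
analyze_landscape <- function(p, lower = NULL, upper = NULL, n_grid = 4001,
                              grad_tol = 1e-10, merge_tol = 1e-6,
                              degen_tol = 1e-8) {
  p <- validate_params(unclass(p))
  iv <- default_interval(p, lower, upper)
  lower <- iv[1]; upper <- iv[2]
  if (lower >= p$r_e || upper <= p$r_e) {
    stop_domain("search interval [", signif(lower, 6), ", ", signif(upper, 6),
                "] does not contain r_e = ", p$r_e)
  }
  # physical-unit tolerances from the reduced-unit ones
  gtol <- grad_tol * p$kBT / p$r_e
  ctol <- degen_tol * p$kBT / p$r_e^2
  mtol <- merge_tol * p$r_e

  grid <- seq(lower, upper, length.out = n_grid)
  g <- potential_gradient(grid, p)
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1L)) {
    if (g[i] == 0) {
      roots <- c(roots, grid[i])
    } else if (g[i] * g[i + 1L] < 0) {
      roots <- c(roots, refine_root(grid[i], grid[i + 1L], p, gtol))
    }
  }
  if (g[n_grid] == 0) roots <- c(roots, grid[n_grid])
  roots <- sort(roots)
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > mtol)
    roots <- roots[keep]
  }

  points <- tibble::tibble(
    r = roots,
    energy = if (length(roots)) total_potential(roots, p) else numeric(0),
    curvature = if (length(roots)) potential_curvature(roots, p) else numeric(0),
    kind = dplyr::case_when(
      abs(curvature) < ctol ~ "degenerate",
      curvature > 0 ~ "minimum",
      TRUE ~ "maximum"
    )
  )
  classify_landscape(p, points, ctol)
}

default_interval <- function(p, lower, upper) {
  shift <- (p$d - p$l0) / p$coupling_slope # separation change relieving mismatch
  decay <- 5 / p$beta
  lo_auto <- max(1e-3 * p$r_e, min(p$r_e, p$r_e + shift) - decay)
  hi_auto <- max(p$r_e, p$r_e + shift) + decay + 0.5 * p$r_e
  c(if (is.null(lower)) lo_auto else lower,
    if (is.null(upper)) hi_auto else upper)
}

refine_root <- function(lo, hi, p, gtol) {
  f <- function(r) potential_gradient(r, p)
  root <- tryCatch(
    stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.8 * p$r_e)$root,
    error = function(e) {
      stop_numeric("bracket [", signif(lo, 8), ", ", signif(hi, 8),
                   "] lost during refinement: ", conditionMessage(e))
    }
  )
  # Newton polish with the analytic curvature, kept inside the bracket
  for (i in 1:20) {
    g <- f(root)
    if (abs(g) <= gtol) break
    c2 <- potential_curvature(root, p)
    if (c2 == 0) break
    step <- g / c2
    cand <- root - step
    if (cand <= lo || cand >= hi) break
    root <- cand
  }
  root
}

classify_landscape <- function(p, points, ctol) {
  mins <- points[points$kind == "minimum", , drop = FALSE]
  maxs <- points[points$kind == "maximum", , drop = FALSE]
  degen <- any(points$kind == "degenerate")
  relief <- p$r_e + (p$d - p$l0) / p$coupling_slope
  r_dim <- r_ts <- r_diss <- NA_real_

  if (degen) {
    regime <- "barrierless"
    if (nrow(mins) > 0) {
      r_dim <- mins$r[which.min(abs(mins$r - p$r_e))]
    }
  } else if (nrow(mins) == 2 && nrow(maxs) == 1 &&
             identical(points$kind, c("minimum", "maximum", "minimum"))) {
    regime <- "double_well"
    r_dim <- points$r[1]; r_ts <- points$r[2]; r_diss <- points$r[3]
  } else if (nrow(mins) == 1 && nrow(maxs) == 0) {
    if (abs(mins$r - p$r_e) <= abs(mins$r - relief)) {
      regime <- "single_well_dimer"
      r_dim <- mins$r
    } else {
      regime <- "single_well_dissociated"
      r_diss <- mins$r
    }
  } else {
    stop_numeric("unexpected stationary-point pattern (",
                 paste(points$kind, collapse = "-"),
                 "); widen the search interval or refine the grid")
  }

  structure(
    list(parameters = p, points = points, regime = regime,
         r_dim = r_dim, r_ts = r_ts, r_diss = r_diss),
    class = c("memtug_landscape", "list")
  )
}

#' Brute-force grid oracle for stationary points
#'
#' Locates stationary points purely by evaluating the total potential on a
#' dense grid and flagging interior samples that are strict local extrema of
#' the sampled values. No derivative information is used, so the result is an
#' independent check on [analyze_landscape()]; accuracy is limited by the
#' grid step. Curvatures are central finite differences of the sampled
#' values.
#'
#' @param p A [model_params()] object.
#' @param lower,upper Search interval (nm); defaults as in
#'   [analyze_landscape()].
#' @param n_points Number of grid points, at least 10^4.
#' @return A tibble of stationary points: `r`, `energy`, `curvature`, `kind`.
#' @export
oracle_grid_search <- function(p, lower = NULL, upper = NULL,
                               n_points = 20001) {
  p <- validate_params(unclass(p))
  if (n_points < 1e4) stop_domain("'n_points' must be at least 10^4")
  iv <- default_interval(p, lower, upper)
  grid <- seq(iv[1], iv[2], length.out = n_points)
  v <- total_potential(grid, p)
  h <- grid[2] - grid[1]
  i <- 2:(n_points - 1L)
  is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  idx <- i[is_min | is_max]
  tibble::tibble(
    r = grid[idx],
    energy = v[idx],
    curvature = (v[idx - 1L] - 2 * v[idx] + v[idx + 1L]) / h^2,
    kind = ifelse(is_min[match(idx, i)], "minimum", "maximum")
  )
}

#' @export
print.memtug_landscape <- function(x, ...) {
  cat("<memtug landscape> regime:", x$regime, "\n")
  cat(sprintf("  r_dim = %s, r_ts = %s, r_diss = %s (nm)\n",
              signif(x$r_dim, 6), signif(x$r_ts, 6), signif(x$r_diss, 6)))
  print(x$points)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy memtug_landscape
#' @export
tidy.memtug_landscape <- function(x, ...) x$points

#' @method glance memtug_landscape
#' @export
glance.memtug_landscape <- function(x, ...) {
  tibble::tibble(
    regime = x$regime,
    n_stationary = nrow(x$points),
    r_dim = x$r_dim, r_ts = x$r_ts, r_diss = x$r_diss,
    barrier = if (x$regime == "double_well") {
      x$points$energy[2] - x$points$energy[1]
    } else NA_real_
  )
}

#' Plot a potential landscape
#'
#' Draws the total potential over the search interval with the stationary
#' points marked, the analogue of the classic double-well figure.
#'
#' @param object A `memtug_landscape`.
#' @param n Number of curve samples.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot memtug_landscape
#' @export
autoplot.memtug_landscape <- function(object, n = 512, ...) {
  p <- object$parameters
  iv <- default_interval(p, NULL, NULL)
  curve <- tibble::tibble(r = seq(iv[1], iv[2], length.out = n))
  curve$energy <- total_potential(curve$r, p)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$r, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$points,
                        ggplot2::aes(shape = .data$kind), size = 3) +
    ggplot2::labs(
      x = "centre-of-mass separation r (nm)",
      y = "potential energy (kBT)",
      title = paste("Dimer-bilayer potential:", object$regime)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.memtug_landscape
#' @export
plot_landscape <- function(object, n = 512, ...) autoplot(object, n = n, ...)
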