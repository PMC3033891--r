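#' Sweep bilayer thickness or stiffness
#'
#' Recomputes the landscape and kinetics at each value of the swept bilayer
#' property and collects one row per point. Thicker bilayers (at fixed channel
#' length) increase the hydrophobic mismatch, lower the dissociation barrier
#' and shorten the channel lifetime; stiffer bilayers do the same at fixed
#' mismatch. Over the double-well range both trends are approximately linear
#' in `ln(tau * A)`, which is what single-channel experiments report.
#'
#' Rows whose regime is not `double_well` are retained in the output (their
#' barrier-derived columns are `NA`) but excluded from the linear fit; the
#' number of fitted rows is recorded. The fit is performed only when at least
#' three double-well rows exist.
#'
#' @param p A [model_params()] object. For `scan_thickness()` its `d` is
#'   replaced by each swept value; for `scan_stiffness()` its `H_B` is, with
#'   `d` held fixed.
#' @param d_values,hb_values Sorted (non-decreasing) swept values; thickness
#'   values must be > 0, stiffness values >= 0. Defaults: 9 points spanning
#'   `p$d` +/- 0.4 nm, or `p$H_B` +/- 50%.
#' @param ... Passed to [analyze_landscape()].
#' @return An object of class `memtug_scan`: list with `swept_variable`
#'   (`"thickness"` or `"stiffness"`), `parameters` (the base set), `rows`
#'   (tibble: swept value, `r_dim`, `r_ts`, `r_diss`, `barrier`,
#'   `ln_lifetime`, `distance_to_ts`, `disjoining_force`, `regime`), `fit`
#'   (one-row tibble from [linear_fit()] of `ln_lifetime` on the swept value
#'   over double-well rows, or `NULL` if fewer than three), `n_fit_rows`, and
#'   `meta` (the r-squared reporting thresholds, so outputs are
#'   self-describing). Has [tidy()], [glance()] and [ggplot2::autoplot()]
#'   methods.
#' @examples
#' p <- model_params(D_e = 1, r_e = 1, beta = 10, l0 = 2.2, d = 3, H_B = 1)
#' sc <- scan_thickness(p, seq(2.9, 3.4, by = 0.1))
#' glance(sc)
#' @export
scan_thickness <- function(p, d_values = NULL, ...) {
  p <- validate_params(unclass(p))
  if (is.null(d_values)) d_values <- seq(p$d - 0.4, p$d + 0.4, length.out = 9)
  check_sweep(d_values, "d_values", min_ok = FALSE)
  run_scan(p, "thickness", "d", d_values, ...)
}

#' @rdname scan_thickness
#' @export
scan_stiffness <- function(p, hb_values = NULL, ...) {
  p <- validate_params(unclass(p))
  if (is.null(hb_values)) {
    hb_values <- seq(0.5 * p$H_B, 1.5 * p$H_B, length.out = 9)
  }
  check_sweep(hb_values, "hb_values", min_ok = TRUE)
  run_scan(p, "stiffness", "H_B", hb_values, ...)
}

check_sweep <- function(x, name, min_ok) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    stop_domain("'", name, "' must be a non-empty finite numeric vector")
  }
  if (is.unsorted(x)) stop_domain("'", name, "' must be sorted increasing")
  if (min_ok) {
    if (any(x < 0)) stop_domain("'", name, "' must be >= 0")
  } else if (any(x <= 0)) stop_domain("'", name, "' must be > 0")
}

run_scan <- function(p, swept_variable, field, values, ...) {
  rows <- purrr::map(values, function(v) {
    q <- unclass(p)
    q[[field]] <- v
    ks <- kinetics_summary(validate_params(q), ...)
    tibble::tibble(
      value = v,
      r_dim = ks$r_dim, r_ts = ks$r_ts, r_diss = ks$r_diss,
      barrier = ks$barrier, ln_lifetime = ks$ln_lifetime,
      distance_to_ts = ks$distance_to_ts,
      disjoining_force = ks$disjoining_force,
      regime = ks$regime
    )
  })
  rows <- dplyr::bind_rows(rows)
  names(rows)[names(rows) == "value"] <- field
  dw <- rows[rows$regime == "double_well", , drop = FALSE]
  fit <- if (nrow(dw) >= 3) linear_fit(dw[[field]], dw$ln_lifetime) else NULL
  structure(
    list(
      swept_variable = swept_variable,
      parameters = p,
      rows = rows,
      fit = fit,
      n_fit_rows = nrow(dw),
      meta = list(r_squared_threshold_lifetime = 0.98,
                  r_squared_threshold_force = 0.99)
    ),
    class = c("memtug_scan", "list")
  )
}

#' Ordinary least-squares line with degenerate-case conventions
#'
#' Fits `y ~ x` by OLS (via [stats::lm()]) and reports slope, intercept and
#' r-squared. Conventions for degenerate inputs: fewer than three finite
#' pairs, or zero variance in `x`, is an error; constant `y` (zero residual
#' and zero total variance) returns slope 0 with `r_squared = 1` and is
#' flagged degenerate.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `n`,
#'   `degenerate`.
#' @examples
#' linear_fit(1:5, 2 * (1:5) + 1)
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_domain("linear_fit needs at least 3 finite pairs")
  if (stats::var(x) == 0) stop_domain("linear_fit: zero variance in x")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  degenerate <- ss_tot == 0
  r2 <- if (degenerate) 1 else 1 - ss_res / ss_tot
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n = length(x),
    degenerate = degenerate
  )
}

#' Lifetime slope against hydrophobic mismatch
#'
#' OLS slope of `ln(tau * A)` against the mismatch `d - l0` over the
#' double-well rows of a thickness scan. Because `d` and `d - l0` differ by a
#' constant, this equals the thickness-scan fit slope; it is the quantity
#' whose experimental analogue is used to extract bilayer spring coefficients.
#'
#' @param scan A `memtug_scan` from [scan_thickness()].
#' @return One-row tibble as from [linear_fit()].
#' @export
mismatch_slope <- function(scan) {
  if (!inherits(scan, "memtug_scan") || scan$swept_variable != "thickness") {
    stop_domain("mismatch_slope requires a thickness scan")
  }
  dw <- scan$rows[scan$rows$regime == "double_well", , drop = FALSE]
  if (nrow(dw) < 3) {
    stop_domain("mismatch_slope needs at least 3 double-well rows, got ",
                nrow(dw))
  }
  linear_fit(dw$d - scan$parameters$l0, dw$ln_lifetime)
}

#' @export
print.memtug_scan <- function(x, ...) {
  cat("<memtug scan> swept:", x$swept_variable,
      sprintf("(%d points, %d in double-well fit)\n",
              nrow(x$rows), x$n_fit_rows))
  print(x$rows)
  if (!is.null(x$fit)) {
    cat(sprintf("  ln_lifetime fit: slope %.4g, intercept %.4g, r^2 %.4f\n",
                x$fit$slope, x$fit$intercept, x$fit$r_squared))
  }
  invisible(x)
}

#' @method tidy memtug_scan
#' @export
tidy.memtug_scan <- function(x, ...) x$rows

#' @method glance memtug_scan
#' @export
glance.memtug_scan <- function(x, ...) {
  base <- tibble::tibble(
    swept_variable = x$swept_variable,
    n_rows = nrow(x$rows),
    n_fit_rows = x$n_fit_rows
  )
  if (is.null(x$fit)) {
    dplyr::mutate(base, slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_)
  } else {
    dplyr::bind_cols(base, x$fit[, c("slope", "intercept", "r_squared")])
  }
}

#' Plot a scan
#'
#' Lifetime trend (`ln(tau * A)` against the swept bilayer property) with the
#' OLS line over the double-well rows, the analogue of the lifetime-vs-
#' thickness and lifetime-vs-stiffness result figures.
#'
#' @param object A `memtug_scan`.
#' @param y Column to plot (default `ln_lifetime`; `distance_to_ts` gives the
#'   transition-state-distance analogue).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot memtug_scan
#' @export
autoplot.memtug_scan <- function(object, y = "ln_lifetime", ...) {
  xvar <- if (object$swept_variable == "thickness") "d" else "H_B"
  xlab <- if (object$swept_variable == "thickness") {
    "bilayer hydrophobic thickness d (nm)"
  } else {
    "membrane Hookean coefficient H_B (kBT/nm²)"
  }
  gg <- ggplot2::ggplot(object$rows,
                        ggplot2::aes(x = .data[[xvar]], y = .data[[y]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$regime), size = 2.5) +
    ggplot2::labs(x = xlab, y = y) +
    ggplot2::theme_minimal()
  if (y == "ln_lifetime" && !is.null(object$fit)) {
    gg <- gg + ggplot2::geom_abline(slope = object$fit$slope,
                                    intercept = object$fit$intercept,
                                    linetype = "dashed")
  }
  gg
}

#' @rdname autoplot.memtug_scan
#' @export
plot_scan <- function(object, y = "ln_lifetime", ...) {
  autoplot(object, y = y, ...)
}
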