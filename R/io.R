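#' Load, validate and write run configurations
#'
#' Run configurations are YAML files with sections `model` (the
#' [model_params()] fields), `units` (see [unit_system()]), and optionally
#' `scan` (`variable`, `min`, `max`, `n_points`), plus top-level `profile`,
#' `output_dir`, `seed` and `verbosity`. Fields missing from `model` are
#' filled from the named profile (default `"paper2011"`, shipped with the
#' package); explicit `overrides` (e.g. from CLI flags) are applied last.
#' Validation enforces every parameter invariant with a message naming the
#' offending field. Load -> write -> load is the identity.
#'
#' @param path Path to a YAML config file, or `NULL` to start from the
#'   profile alone.
#' @param overrides Named list applied on top of the file (names as in the
#'   `model` section, plus `output_dir`, `seed`, `verbosity`).
#' @param profile Profile name used to fill defaults when the file does not
#'   name one.
#' @return An object of class `memtug_config`: list with `profile`, `params`
#'   (a `memtug_params`), `units` (a `memtug_units`), `scan` (list or NULL),
#'   `output_dir`, `seed`, `verbosity`.
#' @examples
#' cfg <- load_config(NULL) # pure profile defaults
#' cfg$params$D_e
#' @export
load_config <- function(path = NULL, overrides = list(),
                        profile = "paper2011") {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (!is.list(raw)) stop_config("config file is not a YAML mapping: ", path)
  }
  profile <- raw$profile %||% profile
  prof <- read_profile(profile)
  model <- utils::modifyList(prof$model, raw$model %||% list())
  units <- utils::modifyList(prof$units %||% list(), raw$units %||% list())
  scan <- raw$scan %||% prof$scan

  model_overrides <- overrides[names(overrides) %in% names(prof$model)]
  model <- utils::modifyList(model, model_overrides)
  top <- function(key, default) {
    overrides[[key]] %||% raw[[key]] %||% default
  }
  validate_config(structure(
    list(
      profile = profile,
      params = model,
      units = units,
      scan = scan,
      output_dir = top("output_dir", "."),
      seed = top("seed", 1L),
      verbosity = top("verbosity", 1L)
    ),
    class = c("memtug_config", "list")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_profile <- function(profile) {
  path <- system.file("extdata", "profiles", paste0(profile, ".yaml"),
                      package = "memtug")
  if (!nzchar(path)) stop_config("unknown parameter profile: '", profile, "'")
  yaml::read_yaml(path)
}

#' @rdname load_config
#' @param cfg A `memtug_config` object.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop_config("config must be a list")
  cfg$params <- validate_params(unclass(cfg$params))
  cfg$units <- do.call(unit_system, cfg$units %||% list())
  if (!is.null(cfg$scan)) {
    for (f in c("variable", "min", "max", "n_points")) {
      if (is.null(cfg$scan[[f]])) stop_config("scan section missing field '", f, "'")
    }
    if (!cfg$scan$variable %in% c("thickness", "stiffness")) {
      stop_config("scan variable must be 'thickness' or 'stiffness', got '",
                  cfg$scan$variable, "'")
    }
    if (cfg$scan$min > cfg$scan$max) stop_config("scan min exceeds max")
    if (cfg$scan$n_points < 1) stop_config("scan n_points must be >= 1")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    stop_config("seed must be a single integer")
  }
  structure(cfg, class = c("memtug_config", "list"))
}

#' @rdname load_config
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  out <- list(
    profile = cfg$profile,
    model = lapply(unclass(cfg$params), as.numeric),
    units = unclass(cfg$units),
    scan = cfg$scan,
    output_dir = cfg$output_dir,
    seed = cfg$seed,
    verbosity = cfg$verbosity
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Randomized valid parameter sets for property tests
#'
#' Draws `n` parameter sets uniformly within physically sensible bounds
#' (bond energies of a few to a few tens of kBT, Morse decay lengths a small
#' fraction of the separation, mismatch from -0.5 to +1.5 nm, membrane
#' stiffness limited so the frustration energy at the dimer well does not
#' exceed the bond energy) and annotates each with the landscape regime found
#' by a coarse pass of the derivative-free grid oracle. Deterministic for a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n Number of parameter sets, >= 1.
#' @return A tibble with one row per set: the [model_params()] fields plus
#'   `expected_regime`.
#' @export
generate_fixture_parameters <- function(seed, n) {
  if (n < 1) stop_domain("'n' must be >= 1")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  D_e <- stats::runif(n, 2, 30)
  r_e <- stats::runif(n, 0.5, 2)
  beta <- stats::runif(n, 2, 30) / r_e
  l0 <- stats::runif(n, 1.5, 3)
  mismatch <- stats::runif(n, -0.5, 1.5)
  d <- l0 + mismatch
  # mismatch energy at r_e stays within [0, D_e]; cap spring for tiny mismatch
  hb_max <- pmin(2 * D_e / pmax(mismatch^2, 1e-6), 20 * D_e / r_e^2)
  H_B <- stats::runif(n, 0, 1) * hb_max
  sets <- tibble::tibble(
    D_e = D_e, r_e = r_e, beta = beta, l0 = l0, d = d, H_B = H_B,
    A = 1, kBT = 1, coupling_slope = 1
  )
  sets$expected_regime <- purrr::map_chr(seq_len(n), function(i) {
    p <- validate_params(as.list(sets[i, names(sets) != "expected_regime"]))
    pts <- oracle_grid_search(p, n_points = 10001)
    n_min <- sum(pts$kind == "minimum")
    n_max <- sum(pts$kind == "maximum")
    if (n_min == 2 && n_max == 1) {
      "double_well"
    } else if (n_min == 1 && n_max == 0) {
      relief <- p$r_e + (p$d - p$l0) / p$coupling_slope
      if (abs(pts$r[1] - p$r_e) <= abs(pts$r[1] - relief)) {
        "single_well_dimer"
      } else {
        "single_well_dissociated"
      }
    } else {
      "barrierless"
    }
  })
  sets
}

#' Writers for scan tables and structured summaries
#'
#' `write_scan_csv()` writes the per-point rows of a scan (fixed, documented
#' header: the swept column `d` or `H_B`, then `r_dim`, `r_ts`, `r_diss`,
#' `barrier`, `ln_lifetime`, `distance_to_ts`, `disjoining_force`, `regime`)
#' with full double precision, so a read-back reproduces every numeric column
#' exactly. `write_json()` writes any package object (landscapes and scans
#' are converted to plain lists) as stable, human-readable JSON.
#' `render_plot()` saves the autoplot of a landscape or scan.
#'
#' @param scan A `memtug_scan` or a data frame of scan rows.
#' @param obj Object to serialize (e.g. `memtug_landscape`, `memtug_scan`,
#'   or any list/tibble).
#' @param path Output file path.
#' @param ... Passed to [ggplot2::ggsave()] (for `render_plot`) or
#'   [autoplot()].
#' @return The path, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  rows <- if (inherits(scan, "memtug_scan")) scan$rows else tibble::as_tibble(scan)
  readr::write_csv(rows, path)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
write_json <- function(obj, path) {
  jsonlite::write_json(as_plain(obj), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

as_plain <- function(obj) {
  if (inherits(obj, "memtug_landscape")) {
    list(parameters = unclass(obj$parameters),
         regime = obj$regime,
         r_dim = obj$r_dim, r_ts = obj$r_ts, r_diss = obj$r_diss,
         points = as.data.frame(obj$points))
  } else if (inherits(obj, "memtug_scan")) {
    list(swept_variable = obj$swept_variable,
         parameters = unclass(obj$parameters),
         rows = as.data.frame(obj$rows),
         fit = if (is.null(obj$fit)) NULL else as.list(obj$fit),
         n_fit_rows = obj$n_fit_rows,
         meta = obj$meta)
  } else {
    obj
  }
}

#' @rdname write_scan_csv
#' @export
render_plot <- function(obj, path, ...) {
  gg <- autoplot(obj, ...)
  ggplot2::ggsave(path, gg, width = 6.5, height = 4.5)
  invisible(path)
}
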