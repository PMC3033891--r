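#' Model parameters for the dimer-bilayer tug-of-war potential
#'
#' Bundles the full parameter set of the one-dimensional dissociation model:
#' a Morse subunit-subunit bond of depth `D_e` and stiffness `beta` centred at
#' the equilibrium centre-of-mass separation `r_e`, plus a harmonic membrane
#' term `(H_B/2) (d - l(r))^2` that penalizes hydrophobic mismatch between the
#' bilayer hydrophobic thickness `d` and the dimer hydrophobic length
#' `l(r) = l0 + coupling_slope * (r - r_e)`.
#'
#' Energies are expressed in thermal units (kBT) by default and lengths in
#' nanometres. The thermal energy scale `kBT` enters only the Arrhenius rate
#' expression; with the default conventions it is 1.
#'
#' @param D_e Dissociation energy of the subunit-subunit bond (kBT), > 0.
#' @param r_e Equilibrium centre-of-mass separation of the monomers (nm), > 0.
#' @param beta Morse stiffness parameter (1/nm), > 0. The Morse curvature at
#'   `r_e` is `2 * D_e * beta^2`.
#' @param l0 Equilibrium hydrophobic length of the dimer (nm), > 0.
#' @param d Bilayer hydrophobic thickness (nm), > 0. The mismatch `d - l0`
#'   may have either sign.
#' @param H_B Phenomenological membrane Hookean force coefficient (kBT/nm^2),
#'   >= 0. A single spring constant standing in for the bilayer compression
#'   and bending response.
#' @param A Arrhenius pre-exponential factor (1/time, reduced), > 0. The model
#'   does not fix it; lifetime trends are reported as `ln(tau * A)`, which is
#'   independent of `A`.
#' @param kBT Thermal energy in the same unit as `D_e`, > 0 (default 1, i.e.
#'   energies are already thermal).
#' @param coupling_slope Dimensionless slope of the hydrophobic length with
#'   axial separation, `dl/dr` (default 1: each nm of extra subunit
#'   separation adds one nm of hydrophobic length).
#'
#' @return An object of class `memtug_params` (a validated named list).
#' @examples
#' p <- model_params(D_e = 1, r_e = 1, beta = 10, l0 = 2.2, d = 3, H_B = 1)
#' total_potential(p$r_e, p)
#' @export
model_params <- function(D_e, r_e, beta, l0, d, H_B,
                         A = 1, kBT = 1, coupling_slope = 1) {
  p <- list(
    D_e = D_e, r_e = r_e, beta = beta, l0 = l0, d = d, H_B = H_B,
    A = A, kBT = kBT, coupling_slope = coupling_slope
  )
  validate_params(p)
}

#' @keywords internal
validate_params <- function(p) {
  required <- c("D_e", "r_e", "beta", "l0", "d", "H_B", "A", "kBT",
                "coupling_slope")
  missing <- setdiff(required, names(p))
  if (length(missing) > 0) {
    stop_config("missing model parameter(s): ", paste(missing, collapse = ", "))
  }
  for (f in required) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_config("parameter '", f, "' must be a single finite number")
    }
  }
  strictly_positive <- c("D_e", "r_e", "beta", "l0", "d", "A", "kBT")
  for (f in strictly_positive) {
    if (p[[f]] <= 0) stop_config("parameter '", f, "' must be > 0, got ", p[[f]])
  }
  if (p$H_B < 0) stop_config("parameter 'H_B' must be >= 0, got ", p$H_B)
  if (p$coupling_slope <= 0) {
    stop_config("parameter 'coupling_slope' must be > 0, got ", p$coupling_slope)
  }
  structure(p[required], class = c("memtug_params", "list"))
}

#' @export
print.memtug_params <- function(x, ...) {
  cat("<memtug model parameters>\n")
  cat(sprintf("  D_e = %g kBT, r_e = %g nm, beta = %g /nm\n",
              x$D_e, x$r_e, x$beta))
  cat(sprintf("  l0 = %g nm, d = %g nm (mismatch %g nm), H_B = %g kBT/nm^2\n",
              x$l0, x$d, x$d - x$l0, x$H_B))
  cat(sprintf("  A = %g, kBT = %g, coupling slope = %g\n",
              x$A, x$kBT, x$coupling_slope))
  invisible(x)
}

#' Morse stiffness from a Hookean force constant
#'
#' Maps the harmonic (Hookean) force constant `k` of the subunit-subunit bond
#' near equilibrium onto the Morse stiffness `beta`: expanding the Morse term
#' about its minimum gives curvature `2 * D_e * beta^2`, so matching it to `k`
#' yields `beta = sqrt(k / (2 * D_e))`.
#'
#' @param k Hookean force constant (kBT/nm^2), > 0.
#' @param D_e Dissociation energy (kBT), > 0.
#' @return Morse stiffness `beta` (1/nm).
#' @examples
#' beta_from_hooke(2, 1) # 1
#' @export
beta_from_hooke <- function(k, D_e) {
  if (!is.numeric(k) || any(k <= 0)) stop_domain("'k' must be > 0")
  if (!is.numeric(D_e) || any(D_e <= 0)) stop_domain("'D_e' must be > 0")
  sqrt(k / (2 * D_e))
}

#' Unit systems and reduced-unit conversion
#'
#' A `unit_system` records how a parameter set's units relate to the package's
#' canonical units (energies in kBT, lengths in nm). `to_reduced()` rescales a
#' parameter set to reduced units — energies in thermal units and lengths in
#' units of the equilibrium separation `r_e` — and attaches the unit system
#' needed to undo the scaling; `to_physical()` applies a unit system to map a
#' parameter set back. Every reported barrier (kBT) and length is invariant
#' under the round trip.
#'
#' @param energy_label,length_label Unit names (informational).
#' @param energy_to_kBT Scale factor: one energy unit in kBT, > 0.
#' @param length_to_nm Scale factor: one length unit in nm, > 0.
#' @return `unit_system()` returns an object of class `memtug_units`.
#' @examples
#' p <- model_params(D_e = 1, r_e = 1, beta = 10, l0 = 2.2, d = 3, H_B = 1)
#' pr <- to_reduced(p)
#' pr$r_e # 1
#' @export
unit_system <- function(energy_label = "kBT", energy_to_kBT = 1,
                        length_label = "nm", length_to_nm = 1) {
  if (!is.numeric(energy_to_kBT) || energy_to_kBT <= 0) {
    stop_domain("'energy_to_kBT' must be > 0")
  }
  if (!is.numeric(length_to_nm) || length_to_nm <= 0) {
    stop_domain("'length_to_nm' must be > 0")
  }
  structure(
    list(energy_label = energy_label, energy_to_kBT = energy_to_kBT,
         length_label = length_label, length_to_nm = length_to_nm),
    class = c("memtug_units", "list")
  )
}

#' @rdname unit_system
#' @param p A `memtug_params` object.
#' @export
to_reduced <- function(p) {
  p <- validate_params(unclass(p))
  s <- p$r_e
  q <- model_params(
    D_e = p$D_e, r_e = 1, beta = p$beta * s,
    l0 = p$l0 / s, d = p$d / s, H_B = p$H_B * s^2,
    A = p$A, kBT = p$kBT, coupling_slope = p$coupling_slope
  )
  attr(q, "units") <- unit_system(length_label = "r_e", length_to_nm = s)
  q
}

#' @rdname unit_system
#' @param u A `memtug_units` object, e.g. the one attached by [to_reduced()].
#' @export
to_physical <- function(p, u) {
  p <- validate_params(unclass(p))
  if (!inherits(u, "memtug_units")) stop_domain("'u' must be a unit_system()")
  e <- u$energy_to_kBT
  s <- u$length_to_nm
  model_params(
    D_e = p$D_e * e, r_e = p$r_e * s, beta = p$beta / s,
    l0 = p$l0 * s, d = p$d * s, H_B = p$H_B * e / s^2,
    A = p$A, kBT = p$kBT * e, coupling_slope = p$coupling_slope
  )
}

# condition helpers shared across the package
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("memtug_config_error", "error")))
}
stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("memtug_domain_error", "error")))
}
stop_regime <- function(...) {
  stop(errorCondition(paste0(...), class = c("memtug_regime_error", "error")))
}
stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("memtug_numeric_error", "error")))
}
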