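#' The dimer-bilayer potential and its derivatives
#'
#' The total potential along the axial separation coordinate `r` is the sum of
#' a Morse subunit-subunit bond and a harmonic membrane deformation term:
#'
#' \deqn{V(r) = D_e [(1 - e^{-\beta (r - r_e)})^2 - 1]
#'            + \frac{H_B}{2} (d - l(r))^2}
#'
#' with the dimer hydrophobic length coupled to separation as
#' `l(r) = l0 + coupling_slope * (r - r_e)`. The Morse term has its minimum
#' `-D_e` at `r = r_e` and plateaus at 0 for large separations, so `D_e` reads
#' directly as the bond dissociation energy; all reported kinetic quantities
#' are energy differences and therefore independent of this offset convention.
#' The membrane term is zero exactly where the mismatch is relieved,
#' `l(r) = d`, and is an unrestricted (two-sided) harmonic.
#'
#' All functions are vectorized over `r`.
#'
#' @param r Centre-of-mass separation(s), nm; must be > 0.
#' @param p A [model_params()] object.
#' @return `hydrophobic_length()`: dimer hydrophobic length l(r), nm.
#'   `morse_energy()`, `mismatch_energy()`, `total_potential()`: energies in
#'   kBT. `potential_gradient()`: dV/dr in kBT/nm. `potential_curvature()`:
#'   d2V/dr2 in kBT/nm^2.
#' @examples
#' p <- model_params(D_e = 1, r_e = 1, beta = 10, l0 = 2.2, d = 3, H_B = 1)
#' total_potential(p$r_e, p) # -1 + 0.32 = -0.68
#' potential_gradient(p$r_e, p)
#' @name potential
NULL

check_r <- function(r) {
  if (!is.numeric(r) || length(r) == 0 || any(!is.finite(r)) || any(r <= 0)) {
    stop_domain("separation 'r' must be finite and > 0")
  }
  r
}

#' @rdname potential
#' @export
hydrophobic_length <- function(r, p) {
  check_r(r)
  p$l0 + p$coupling_slope * (r - p$r_e)
}

#' @rdname potential
#' @export
morse_energy <- function(r, p) {
  check_r(r)
  u <- 1 - exp(-p$beta * (r - p$r_e))
  p$D_e * (u^2 - 1)
}

#' @rdname potential
#' @export
mismatch_energy <- function(r, p) {
  check_r(r)
  0.5 * p$H_B * (p$d - hydrophobic_length(r, p))^2
}

#' @rdname potential
#' @export
total_potential <- function(r, p) {
  morse_energy(r, p) + mismatch_energy(r, p)
}

#' @rdname potential
#' @export
potential_gradient <- function(r, p) {
  check_r(r)
  e <- exp(-p$beta * (r - p$r_e))
  morse <- 2 * p$D_e * p$beta * e * (1 - e)
  memb <- p$H_B * p$coupling_slope * (hydrophobic_length(r, p) - p$d)
  morse + memb
}

#' @rdname potential
#' @export
potential_curvature <- function(r, p) {
  check_r(r)
  e <- exp(-p$beta * (r - p$r_e))
  2 * p$D_e * p$beta^2 * e * (2 * e - 1) + p$H_B * p$coupling_slope^2
}
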