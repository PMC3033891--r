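#' Transition-state kinetics of dimer dissociation
#'
#' In the double-well regime, the activation barrier is the energy of the
#' transition state above the conducting-dimer well,
#' \eqn{\Delta V = V(r_{ts}) - V(r_{dim})}. Transition-state theory then gives
#' the dissociation rate via the Arrhenius equation
#' \eqn{k = A \exp(-\Delta V / k_B T)} and the mean channel lifetime
#' \eqn{\tau = 1/k}. Because the pre-exponential factor `A` is not fixed by
#' the model, lifetime trends are reported as \eqn{\ln(\tau A) =
#' \Delta V / k_B T}, which is independent of `A`.
#'
#' `disjoining_force()` is the membrane pulling force on the dimer evaluated
#' at the dimer well, `H_B * (d - l(r_dim))` — equal in magnitude to the
#' gradient of the mismatch term there.
#'
#' @param L A `memtug_landscape` from [analyze_landscape()].
#' @param barrier Activation barrier (kBT), >= 0.
#' @param rate Dissociation rate (1/time).
#' @param p A [model_params()] object (supplies `A` and `kBT`).
#' @return `activation_barrier()`: kBT. `dissociation_rate()`: 1/time.
#'   `mean_lifetime()`: time. `distance_to_transition()`: nm.
#'   `disjoining_force()`: kBT/nm.
#' @examples
#' p <- model_params(D_e = 1, r_e = 1, beta = 10, l0 = 2.2, d = 3, H_B = 1)
#' L <- analyze_landscape(p)
#' activation_barrier(L)
#' @name kinetics
NULL

require_double_well <- function(L, what) {
  if (!inherits(L, "memtug_landscape")) {
    stop_domain(what, " requires a memtug_landscape")
  }
  if (L$regime != "double_well") {
    stop_regime(what, " is undefined in regime '", L$regime,
                "': no transition state separates the wells")
  }
  L
}

#' @rdname kinetics
#' @export
activation_barrier <- function(L) {
  require_double_well(L, "activation_barrier")
  p <- L$parameters
  total_potential(L$r_ts, p) - total_potential(L$r_dim, p)
}

#' @rdname kinetics
#' @export
dissociation_rate <- function(barrier, p) {
  if (any(barrier < 0)) stop_domain("'barrier' must be >= 0")
  p$A * exp(-barrier / p$kBT)
}

#' @rdname kinetics
#' @export
mean_lifetime <- function(rate) {
  if (any(rate <= 0)) stop_domain("'rate' must be > 0")
  1 / rate
}

#' @rdname kinetics
#' @export
distance_to_transition <- function(L) {
  require_double_well(L, "distance_to_transition")
  L$r_ts - L$r_dim
}

#' @rdname kinetics
#' @export
disjoining_force <- function(L) {
  if (!inherits(L, "memtug_landscape")) {
    stop_domain("disjoining_force requires a memtug_landscape")
  }
  if (is.na(L$r_dim)) {
    stop_regime("disjoining_force is undefined in regime '", L$regime,
                "': the landscape has no dimer well")
  }
  p <- L$parameters
  p$H_B * (p$d - hydrophobic_length(L$r_dim, p))
}

#' Kinetics summary for one parameter set
#'
#' Runs [analyze_landscape()] (unless given one) and collects the kinetic
#' observables into a one-row tibble. In regimes without a transition state
#' the barrier-derived columns are `NA`; when the barrier has vanished
#' (`barrierless` or `single_well_dissociated`), `rate_lower_bound` reports
#' that the dissociation rate is at least `A` rather than fabricating a
#' barrier.
#'
#' @param x A [model_params()] object or a `memtug_landscape`.
#' @param ... Passed to [analyze_landscape()] when `x` is a parameter set.
#' @return A one-row tibble with columns `regime`, `r_dim`, `r_ts`, `r_diss`,
#'   `barrier` (kBT), `ln_lifetime` (= barrier/kBT - ln A, dimensionless),
#'   `rate` (1/time), `lifetime` (time), `rate_lower_bound` (1/time or NA),
#'   `distance_to_ts` (nm), `disjoining_force` (kBT/nm), `mismatch_at_dimer`
#'   (nm).
#' @examples
#' p <- model_params(D_e = 1, r_e = 1, beta = 10, l0 = 2.2, d = 3, H_B = 1)
#' kinetics_summary(p)
#' @export
kinetics_summary <- function(x, ...) {
  L <- if (inherits(x, "memtug_landscape")) x else analyze_landscape(x, ...)
  p <- L$parameters
  dw <- L$regime == "double_well"
  has_dimer <- !is.na(L$r_dim)
  barrier <- if (dw) activation_barrier(L) else NA_real_
  rate <- if (dw) dissociation_rate(barrier, p) else NA_real_
  tibble::tibble(
    regime = L$regime,
    r_dim = L$r_dim, r_ts = L$r_ts, r_diss = L$r_diss,
    barrier = barrier,
    ln_lifetime = if (dw) barrier / p$kBT - log(p$A) else NA_real_,
    rate = rate,
    lifetime = if (dw) mean_lifetime(rate) else NA_real_,
    rate_lower_bound = if (L$regime %in% c("barrierless",
                                           "single_well_dissociated")) {
      p$A
    } else NA_real_,
    distance_to_ts = if (dw) distance_to_transition(L) else NA_real_,
    disjoining_force = if (has_dimer) disjoining_force(L) else NA_real_,
    mismatch_at_dimer = if (has_dimer) {
      p$d - hydrophobic_length(L$r_dim, p)
    } else NA_real_
  )
}
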