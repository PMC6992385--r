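# The polarization field: reference update rule and field access.

#' Once-per-MCS polarization update (reference implementation)
#'
#' Pure-R reference of the field update applied by the engine at the end of
#' every MCS: with rate `mu`, each occupied site relaxes toward the upper
#' bound `eps0 + delta_eps/2` where the regulatory accumulator is positive,
#' toward the lower bound `eps0 - delta_eps/2` where it is negative, and
#' toward the rest value `eps0` where it is zero.  The bounds are fixed
#' points, so the field can never leave
#' `[eps0 - delta_eps/2, eps0 + delta_eps/2]`.
#'
#' @param eps Numeric vector of per-site polarization values (occupied
#'   sites).
#' @param F Integer vector of regulatory accumulators, same length.
#' @param params A [cpm_params()] object (uses `eps0`, `delta_eps`, `mu`).
#' @param delta_eps_eff Effective maximum polarity; defaults to
#'   `params$delta_eps` (cells in the division phase use 0).
#' @return Updated `eps` vector.
#' @examples
#' p <- cpm_params(eps0 = 225, delta_eps = 30, mu = 0.1)
#' polarization_update(225, 1L, p)    # 226.5
#' polarization_update(230, 0L, p)    # 229.5 (relaxing toward eps0)
#' @export
polarization_update <- function(eps, F, params,
                                delta_eps_eff = params$delta_eps) {
  stopifnot(inherits(params, "cpm_params"), length(eps) == length(F))
  target <- ifelse(F > 0, params$eps0 + delta_eps_eff / 2,
            ifelse(F < 0, params$eps0 - delta_eps_eff / 2, params$eps0))
  eps + params$mu * (target - eps)
}

#' Run the engine's end-of-MCS polarization update now
#'
#' Applies the field update to the running simulation using the regulatory
#' accumulators collected so far, then resets them — exactly what the
#' engine does at each MCS boundary.  Intended for tests and custom loops.
#'
#' @param sim A [cpm_simulation()] object.
#' @return `sim`, invisibly.
#' @export
update_polarization <- function(sim) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_update_polarization_cpp(sim$ptr)
  invisible(sim)
}

#' Overwrite the polarization field
#'
#' Sets the per-site polarization values directly (e.g. to prepare a
#' hand-polarized cell in a test).  Values on unoccupied sites are ignored
#' by the dynamics.
#'
#' @param sim A [cpm_simulation()] object.
#' @param eps Numeric vector of length `n_sites`.
#' @return `sim`, invisibly.
#' @export
set_polarization <- function(sim, eps) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_set_eps_cpp(sim$ptr, as.numeric(eps))
  invisible(sim)
}

#' Overwrite the regulatory accumulators
#'
#' @param sim A [cpm_simulation()] object.
#' @param F Integer vector of length `n_sites`.
#' @return `sim`, invisibly.
#' @export
set_regulatory <- function(sim, F) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_set_F_cpp(sim$ptr, as.integer(F))
  invisible(sim)
}
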