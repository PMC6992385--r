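# Model parameters and the effective-energy building blocks.

#' Model parameters of one cell type
#'
#' Validated container for all Hamiltonian, feedback, adhesion and thermal
#' parameters.
#'
#' @param kappa_A Area stiffness (energy per site squared), `>= 0`.
#' @param kappa_P Perimeter stiffness (energy per perimeter-unit squared),
#'   `>= 0`.
#' @param eps0 Rest value of the polarization field (energy per site);
#'   must exceed `delta_eps / 2` so the field stays positive.
#' @param delta_eps Maximum cell polarity: the polarization field is
#'   bounded to `[eps0 - delta_eps/2, eps0 + delta_eps/2]`.  `>= 0`.
#' @param R Signaling radius (hex graph distance) of the regulatory
#'   feedback, non-negative integer.
#' @param mu Cytoskeletal update rate per MCS, in `(0, 1]`.
#' @param B Cell-cell adhesion benefit per contact edge, `>= 0`.
#' @param delta_B Cell-cell friction: extra dissipative cost per ruptured
#'   contact edge (kinetic only, not part of the state energy), `>= 0`.
#' @param D Cell-substrate dissipation per lost site (kinetic only), `>= 0`.
#' @param kBT Thermal energy scale, `> 0` (the model's reference value
#'   is 1).
#' @param perimeter_unit `"contour"` (default) measures the perimeter as
#'   contour length, i.e. boundary-edge count times the hexagon side
#'   \eqn{1/\sqrt{3}}; `"edges"` uses the raw boundary-edge count.  The
#'   contour convention makes the protrusion barrier of a fully polarized
#'   cell vanish at specific polarizability `delta_eps / kappa_P` near 500
#'   at the single-cell reference parameters, which is where the motility
#'   onset lies; the raw edge count inflates the perimeter energy ninefold
#'   per edge and freezes the same cells.
#' @return An object of class `cpm_params` (a validated named list).
#' @examples
#' p <- cpm_params(kappa_A = 0.18, kappa_P = 0.06, eps0 = 225,
#'                 delta_eps = 45, R = 5)
#' @export
cpm_params <- function(kappa_A = 0.18, kappa_P = 0.06, eps0 = 225,
                       delta_eps = 0, R = 5, mu = 0.1,
                       B = 0, delta_B = 0, D = 0, kBT = 1,
                       perimeter_unit = c("contour", "edges")) {
  perimeter_unit <- match.arg(perimeter_unit)
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(is.numeric(kappa_A) && kappa_A >= 0, "kappa_A must be >= 0")
  chk(is.numeric(kappa_P) && kappa_P >= 0, "kappa_P must be >= 0")
  chk(is.numeric(delta_eps) && delta_eps >= 0, "delta_eps must be >= 0")
  chk(is.numeric(eps0) && eps0 > delta_eps / 2,
      "eps0 must exceed delta_eps / 2")
  chk(is.numeric(R) && R >= 0 && R == round(R),
      "R must be a non-negative integer")
  chk(is.numeric(mu) && mu > 0 && mu <= 1, "mu must lie in (0, 1]")
  chk(is.numeric(B) && B >= 0, "B must be >= 0")
  chk(is.numeric(delta_B) && delta_B >= 0, "delta_B must be >= 0")
  chk(is.numeric(D) && D >= 0, "D must be >= 0")
  chk(is.numeric(kBT) && kBT > 0, "kBT must be > 0")
  structure(list(kappa_A = kappa_A, kappa_P = kappa_P, eps0 = eps0,
                 delta_eps = delta_eps, R = as.integer(R), mu = mu,
                 B = B, delta_B = delta_B, D = D, kBT = kBT,
                 perimeter_unit = perimeter_unit),
            class = "cpm_params")
}

#' @export
print.cpm_params <- function(x, ...) {
  cat(sprintf(paste0("<cpm_params: kappa_A=%g kappa_P=%g eps0=%g ",
                     "delta_eps=%g R=%d mu=%g B=%g delta_B=%g D=%g ",
                     "kBT=%g perimeter=%s>\n"),
              x$kappa_A, x$kappa_P, x$eps0, x$delta_eps, x$R, x$mu,
              x$B, x$delta_B, x$D, x$kBT, x$perimeter_unit))
  invisible(x)
}

# Squared-perimeter unit factor: the energy term is
# kappa_P * (ps * edge_count)^2 with ps = 1/sqrt(3) (contour) or 1 (edges).
perimeter_scale2 <- function(perimeter_unit) {
  if (identical(perimeter_unit, "edges")) 1 else 1 / 3
}

#' Contractile energy of a cell
#'
#' The elastic membrane/cortex energy `kappa_A * A^2 + kappa_P * P^2`,
#' where `P` is the perimeter measured in the unit named by
#' `params$perimeter_unit` (`A` is the site count, `P` is derived from the
#' boundary-edge count `edges`).
#'
#' @param A Area (site count), `>= 0`.
#' @param edges Perimeter boundary-edge count, `>= 0`.
#' @param params A [cpm_params()] object.
#' @return Energy (scalar); vectorized over `A` and `edges`.
#' @examples
#' p <- cpm_params(kappa_A = 0.18, kappa_P = 0.06,
#'                 perimeter_unit = "edges")
#' contractile_energy(625, 90, p)   # 0.18*625^2 + 0.06*90^2 = 70798.5
#' @export
contractile_energy <- function(A, edges, params) {
  stopifnot(inherits(params, "cpm_params"))
  if (any(A < 0) || any(edges < 0)) stop("area and perimeter must be >= 0")
  ps2 <- perimeter_scale2(params$perimeter_unit)
  params$kappa_A * A^2 + params$kappa_P * ps2 * edges^2
}

#' Cytoskeletal energy of a cell
#'
#' The polarization-field contribution `-sum(eps)` over the occupied
#' sites: larger field values make site occupancy more favorable.
#'
#' @param eps Numeric vector of per-site polarization values of the
#'   occupied sites (possibly empty).
#' @return Scalar energy `-sum(eps)`.
#' @examples
#' cytoskeletal_energy(rep(225, 10))  # -2250
#' @export
cytoskeletal_energy <- function(eps) {
  -sum(eps)
}

#' Metropolis acceptance probability
#'
#' `min(1, exp(-delta_H / kBT))`.
#'
#' @param delta_H Energy difference of the proposed event.
#' @param kBT Thermal energy scale, `> 0`.
#' @return Probability in `[0, 1]`; vectorized over `delta_H`.
#' @examples
#' acceptance_probability(-3)       # 1
#' acceptance_probability(log(2))   # 0.5
#' @export
acceptance_probability <- function(delta_H, kBT = 1) {
  if (kBT <= 0) stop("kBT must be > 0")
  pmin(1, exp(-delta_H / kBT))
}

#' Energy difference of an elementary event
#'
#' Evaluates the total energy difference of copying the owner of
#' `source` onto the neighboring site `target` in a running simulation,
#' without applying the move.  The breakdown separates the dissipative
#' (non-state) penalties: `dH` is what the kinetics uses, while
#' `dH_state = dH - delta_B * destroyed - D * lost` equals the change of
#' the state energy [total_energy()] exactly.
#'
#' @param sim A [cpm_simulation()] object.
#' @param source,target Neighboring site indices with distinct owners.
#' @return List with `dH`, `dH_state`, `created` and `destroyed`
#'   (cell-cell contact edges created/destroyed at `target`) and `lost`
#'   (1 if a cell loses the target site, else 0).
#' @seealso [adhesion_delta()], [apply_event()]
#' @export
event_delta <- function(sim, source, target) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_delta_cpp(sim$ptr, as.integer(source), as.integer(target))
}

#' Adhesion energy difference of an elementary event
#'
#' The cell-cell adhesion and friction part of the event energy:
#' `-B * created + (B + delta_B) * destroyed`, with contact edges counted
#' on the 6-neighborhood of the target site.
#'
#' @inheritParams event_delta
#' @return Scalar energy difference.
#' @export
adhesion_delta <- function(sim, source, target) {
  d <- event_delta(sim, source, target)
  p <- sim$params
  -p$B * d$created + (p$B + p$delta_B) * d$destroyed
}

#' Total state energy of a simulation
#'
#' Recomputes the full effective energy from scratch: contractile plus
#' cytoskeletal terms per cell, minus `B` per cell-cell contact edge.
#' Dissipative penalties (`delta_B`, `D`) act only on kinetics and are not
#' part of this state function.
#'
#' @param sim A [cpm_simulation()] object.
#' @return Scalar energy.
#' @export
total_energy <- function(sim) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_total_energy_cpp(sim$ptr)
}
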