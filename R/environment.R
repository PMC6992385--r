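# Substrate micropatterns: the scalar field phi and forbidden (wall) sites.

#' Generic substrate field
#'
#' @param lattice A [build_lattice()] object.
#' @param phi Numeric vector of per-site energy offsets (`<= 0`), recycled
#'   scalar allowed.
#' @param forbidden Logical vector of impenetrable wall sites, recycled
#'   scalar allowed.
#' @return An object of class `substrate_field` with `phi` and `forbidden`
#'   vectors of length `n_sites`.
#' @export
substrate_field <- function(lattice, phi = 0, forbidden = FALSE) {
  stopifnot(inherits(lattice, "hex_lattice"))
  phi <- rep_len(as.numeric(phi), lattice$n_sites)
  forbidden <- rep_len(as.logical(forbidden), lattice$n_sites)
  if (any(phi > 0)) stop("phi must be <= 0 (an adhesion penalty)")
  structure(list(phi = phi, forbidden = forbidden),
            class = "substrate_field")
}

#' Circular adhesive micropattern
#'
#' Admissible disk of radius `r0` around `center`; everything outside is
#' impenetrable (`forbidden`), corresponding to the limit of an infinitely
#' strong adhesion penalty.
#'
#' @param lattice A [build_lattice()] object.
#' @param r0 Pattern radius (Cartesian length), `> 0` and at most half the
#'   smaller lattice extent.
#' @param center Cartesian center `c(x, y)`; defaults to the lattice
#'   center.
#' @return A `substrate_field`.
#' @export
circular_pattern <- function(lattice, r0, center = NULL) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (r0 <= 0) stop("r0 must be > 0")
  wx <- lattice$n_cols
  wy <- lattice$n_rows * sqrt(3) / 2
  if (r0 > min(wx, wy) / 2)
    stop("r0 exceeds half the lattice extent")
  if (is.null(center)) center <- c(wx / 2, wy / 2)
  d2 <- (lattice$coords[, 1] - center[1])^2 +
        (lattice$coords[, 2] - center[2])^2
  substrate_field(lattice, phi = 0, forbidden = d2 >= r0^2)
}

#' Lateral confinement walls for a strip geometry
#'
#' Forbids all sites with Cartesian `x` outside `[x_left, x_right]`; the
#' `y`-direction is typically periodic.  Remove later with
#' [remove_walls()].
#'
#' @param lattice A [build_lattice()] object.
#' @param x_left,x_right Wall positions, `x_left < x_right`.
#' @return A `substrate_field`.
#' @export
strip_walls <- function(lattice, x_left, x_right) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (!(x_left < x_right)) stop("x_left must be less than x_right")
  x <- lattice$coords[, 1]
  substrate_field(lattice, phi = 0, forbidden = x < x_left | x > x_right)
}

#' Remove all walls and adhesion penalties from a running simulation
#'
#' Clears the forbidden mask and sets `phi = 0` everywhere, e.g. to release
#' a confluent strip into free space.
#'
#' @param sim A [cpm_simulation()] object.
#' @return `sim`, invisibly.
#' @export
remove_walls <- function(sim) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_clear_forbidden_cpp(sim$ptr)
  sim$environment$phi[] <- 0
  sim$environment$forbidden[] <- FALSE
  invisible(sim)
}

#' Effective polarization on a penalized substrate site
#'
#' The per-site field value a protruding cell experiences on a site with
#' substrate penalty `phi`: `eps + phi` (additive), `eps * phi`
#' (multiplicative), or a hard rejection sentinel (`-Inf`) on forbidden
#' sites.
#'
#' @param eps Polarization value(s).
#' @param phi Substrate penalty value(s), `<= 0`.
#' @param mode `"additive"`, `"multiplicative"`, or `"forbidden"`.
#' @return Effective field value(s).
#' @export
apply_phi_penalty <- function(eps, phi,
                              mode = c("additive", "multiplicative",
                                       "forbidden")) {
  mode <- match.arg(mode)
  switch(mode,
         additive = eps + phi,
         multiplicative = eps * phi,
         forbidden = rep_len(-Inf, length(eps)))
}
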