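# The three-state cell cycle: parameters, the reference (equilibrium)
# area, and the growth contractility schedule.

#' Cell-cycle parameters
#'
#' Cells start quiescent; once their area exceeds `A_T * A_ref` (contact
#' inhibition threshold) they enter a growth phase of `Tg` MCS during which
#' the contractility is gradually lowered (see [growth_contractility()]),
#' then a division phase of `Td` MCS with polarizability set to zero
#' (mitotic rounding), after which they split into two quiescent,
#' unpolarized daughters.
#'
#' @param Tg Growth duration (MCS), `> 0`.
#' @param Td Division duration (MCS), `> 0`.
#' @param A_T Threshold area in multiples of `A_ref`, `> 0`.
#' @param A_ref Reference area: equilibrium area of a solitary cell, in
#'   sites.  Compute with [equilibrium_area()].
#' @param exit_rate Optional per-MCS hazard for leaving quiescence
#'   stochastically even below the threshold (default 0: purely
#'   size-triggered).
#' @param enabled Master switch.
#' @return An object of class `cycle_params`.
#' @export
cycle_params <- function(Tg = 180L, Td = 20L, A_T = 1, A_ref = NULL,
                         exit_rate = 0, enabled = TRUE) {
  if (Tg <= 0 || Td <= 0) stop("Tg and Td must be positive")
  if (A_T <= 0) stop("A_T must be positive")
  if (!is.null(A_ref) && A_ref <= 0) stop("A_ref must be positive")
  if (exit_rate < 0 || exit_rate > 1) stop("exit_rate must lie in [0, 1]")
  structure(list(enabled = isTRUE(enabled), Tg = as.integer(Tg),
                 Td = as.integer(Td), A_T = A_T, A_ref = A_ref,
                 exit_rate = exit_rate),
            class = "cycle_params")
}

#' Equilibrium area of a solitary cell
#'
#' The reference area `A_ref`: the minimizer over compact lattice shapes of
#' the solitary-cell energy
#' `kappa_A * A^2 + kappa_P * P(A)^2 - eps0 * A`, where `P(A)` is the
#' perimeter of the most compact (disk-like) blob of `A` sites.  The blob
#' perimeters are obtained by construction: sites are added in order of hex
#' distance (ties broken by Cartesian distance) around a center, and
#' boundary edges are counted exactly.
#'
#' @param params A [cpm_params()] object.
#' @param A_max Upper bound of the search range; defaults to a generous
#'   multiple of the continuum estimate `eps0 / (2 * kappa_A)`.
#' @return The minimizing area (sites), a positive integer.
#' @examples
#' equilibrium_area(cpm_params(kappa_A = 0.18, eps0 = 225))
#' @export
equilibrium_area <- function(params, A_max = NULL) {
  stopifnot(inherits(params, "cpm_params"))
  if (is.null(A_max)) {
    A_max <- max(20L, ceiling(1.5 * params$eps0 / (2 * params$kappa_A)))
  }
  side <- 2L * (ceiling(sqrt(A_max)) + 4L)
  if (side %% 2L == 1L) side <- side + 1L
  lat <- build_lattice(side, side, "open", "open")
  center <- (side %/% 2L) * side + side %/% 2L + 1L
  ord <- compact_blob_order(lat, center, A_max)
  perims <- blob_perimeters(lat, ord)
  A <- seq_len(A_max)
  ps2 <- perimeter_scale2(params$perimeter_unit)
  E <- params$kappa_A * A^2 + params$kappa_P * ps2 * perims^2 -
       params$eps0 * A
  which.min(E)
}

# Sites of a compact blob in accretion order: sorted by hex graph distance
# from `center`, ties broken by Cartesian distance, truncated to n sites.
compact_blob_order <- function(lattice, center, n) {
  R <- 0L
  repeat {
    if (1 + 3 * R * (R + 1) >= n) break
    R <- R + 1L
  }
  cand <- disk_neighborhood(lattice, center, R + 1L)
  # hex distance by breadth-first rings
  dist <- rep(NA_integer_, lattice$n_sites)
  dist[center] <- 0L
  frontier <- center
  k <- 0L
  while (length(frontier)) {
    k <- k + 1L
    nxt <- unique(as.vector(lattice$nbr[frontier, , drop = FALSE]))
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[is.na(dist[nxt])]
    nxt <- intersect(nxt, cand)
    dist[nxt] <- k
    frontier <- nxt
  }
  cand <- cand[!is.na(dist[cand])]
  d2 <- (lattice$coords[cand, 1] - lattice$coords[center, 1])^2 +
        (lattice$coords[cand, 2] - lattice$coords[center, 2])^2
  ord <- cand[order(dist[cand], d2)]
  head(ord, n)
}

# Perimeter (boundary-edge count) of each prefix blob of an accretion order.
blob_perimeters <- function(lattice, ord) {
  inblob <- rep(FALSE, lattice$n_sites)
  perims <- integer(length(ord))
  P <- 0L
  for (i in seq_along(ord)) {
    s <- ord[i]
    nb <- lattice$nbr[s, ]
    nb <- nb[!is.na(nb)]
    k_in <- sum(inblob[nb])
    # joining: gains (deg - k_in) new boundary edges, removes k_in old ones
    P <- P + (length(nb) - k_in) - k_in
    inblob[s] <- TRUE
    perims[i] <- P
  }
  perims
}

#' Effective contractility during the growth phase
#'
#' Growth is modeled as a gradual decrease of the effective contractility:
#' `kappa_A` is interpolated linearly from `kappa_A` to `kappa_A / 2` over
#' `Tg` MCS (doubling the target area, which is proportional to
#' `eps0 / kappa_A`), and `kappa_P` is scaled by the square root of the
#' same factor so the perimeter-energy scale per boundary event stays
#' size-invariant.
#'
#' @param params A [cpm_params()] object (base, quiescent values).
#' @param clock MCS spent in the growth phase, `0 <= clock <= Tg`.
#' @param Tg Growth duration (MCS).
#' @return List with `kappa_A` and `kappa_P` (effective values).
#' @examples
#' p <- cpm_params(kappa_A = 0.18, kappa_P = 0.12, eps0 = 35)
#' growth_contractility(p, 0, 180)    # base values
#' growth_contractility(p, 180, 180)  # kappa_A/2, kappa_P/sqrt(2)
#' @export
growth_contractility <- function(params, clock, Tg) {
  stopifnot(inherits(params, "cpm_params"))
  if (clock < 0 || clock > Tg) stop("clock must lie in [0, Tg]")
  f <- 1 - 0.5 * clock / Tg
  list(kappa_A = params$kappa_A * f, kappa_P = params$kappa_P * sqrt(f))
}
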