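# Simulation construction, the Monte-Carlo-step loop, and state access.

#' Create a cellular Potts simulation
#'
#' Builds a complete simulation state: lattice, per-site polarization and
#' regulatory fields, substrate field, seeded cells, and the Monte-Carlo
#' engine (C++).  One MCS performs `N` elementary copy attempts across
#' directed boundary pairs, where `N` is the boundary-pair count at the
#' start of the step, then applies the once-per-MCS polarization update and
#' (if enabled) the cell-cycle update.
#'
#' @param lattice A [build_lattice()] object.
#' @param params A [cpm_params()] object.
#' @param cells List of integer site vectors, one per initial cell.  Each
#'   must be non-empty, connected, disjoint from the others and from
#'   forbidden sites.  Cells start unpolarized (`eps = eps0`, `F = 0`) and
#'   quiescent.
#' @param environment Optional substrate field from [circular_pattern()],
#'   [strip_walls()] or [substrate_field()]; `NULL` means a uniform
#'   substrate (`phi = 0`, nothing forbidden).
#' @param cycle Optional [cycle_params()]; `NULL` disables division.
#' @param seed Integer random seed; together with the configuration it
#'   fully determines the trajectory.
#' @param hastings If `TRUE` (default) the acceptance includes the
#'   proposal-ratio factor `|pairs before| / |pairs after|`, giving exact
#'   detailed balance with respect to the state energy under the
#'   boundary-pair-uniform proposal law when the feedback is off
#'   (`mu`-independent equilibrium sampling).  `FALSE` uses the plain
#'   Metropolis rule of [acceptance_probability()].
#' @param phi_mode How a finite substrate field enters the energy:
#'   `"additive"` (`eps + phi`, default) or `"multiplicative"`
#'   (`eps * phi`).
#' @param feedback `"sign"` (default): the polarization update depends only
#'   on the sign of the regulatory accumulator; `"magnitude"` scales the
#'   update rate by its absolute value (capped at 1).
#' @return An object of class `cpm_simulation`.
#' @examples
#' lat <- build_lattice(30, 30)
#' p <- cpm_params(eps0 = 60, kappa_P = 0.06, delta_eps = 0)
#' sim <- cpm_simulation(lat, p, cells = list(disk_neighborhood(lat, 435, 3)))
#' run_mcs(sim, 10)
#' sim_cells(sim)
#' @export
cpm_simulation <- function(lattice, params, cells,
                           environment = NULL, cycle = NULL, seed = 1L,
                           hastings = TRUE,
                           phi_mode = c("additive", "multiplicative"),
                           feedback = c("sign", "magnitude")) {
  stopifnot(inherits(lattice, "hex_lattice"), inherits(params, "cpm_params"))
  phi_mode <- match.arg(phi_mode)
  feedback <- match.arg(feedback)
  if (!is.list(cells) || length(cells) == 0L)
    stop("at least one initial cell is required")
  if (is.null(environment)) {
    environment <- substrate_field(lattice)
  }
  stopifnot(inherits(environment, "substrate_field"))
  if (length(environment$phi) != lattice$n_sites)
    stop("substrate field does not match the lattice")
  if (is.null(cycle)) {
    cyc <- list(enabled = FALSE)
  } else {
    stopifnot(inherits(cycle, "cycle_params"))
    if (is.null(cycle$A_ref))
      stop("cycle_params needs a concrete A_ref; see equilibrium_area()")
    cyc <- cycle
  }
  cfg <- list(ncol = lattice$n_cols, nrow = lattice$n_rows,
              periodic_x = lattice$periodic_x, periodic_y = lattice$periodic_y,
              kappa_A = params$kappa_A, kappa_P = params$kappa_P,
              eps0 = params$eps0, delta_eps = params$delta_eps,
              R = params$R, mu = params$mu,
              B = params$B, delta_B = params$delta_B, D = params$D,
              kBT = params$kBT,
              phi = as.numeric(environment$phi),
              forbidden = as.logical(environment$forbidden),
              phi_mode = phi_mode,
              perimeter_unit = params$perimeter_unit,
              hastings = isTRUE(hastings),
              feedback = feedback,
              cells = lapply(cells, as.integer),
              cycle = cyc,
              seed = as.numeric(seed))
  ptr <- cpm_create_cpp(cfg)
  structure(list(ptr = ptr, lattice = lattice, params = params,
                 cycle = if (is.null(cycle)) NULL else cyc,
                 environment = environment, seed = seed,
                 hastings = isTRUE(hastings), phi_mode = phi_mode,
                 feedback = feedback),
            class = "cpm_simulation")
}

#' @export
print.cpm_simulation <- function(x, ...) {
  st <- sim_state(x)
  cells <- sim_cells(x)
  cat(sprintf("<cpm_simulation: %d cells, %d occupied sites, mcs=%d>\n",
              nrow(cells), sum(st$owner > 0), as.integer(st$mcs)))
  invisible(x)
}

#' Advance a simulation by whole Monte-Carlo steps
#'
#' @param sim A [cpm_simulation()] object.
#' @param n Number of MCS to run.
#' @return `sim`, invisibly (the state is updated in place).
#' @export
run_mcs <- function(sim, n = 1L) {
  stopifnot(inherits(sim, "cpm_simulation"))
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("n must be a non-negative integer")
  cpm_run_cpp(sim$ptr, n)
  invisible(sim)
}

#' Per-site simulation state
#'
#' @param sim A [cpm_simulation()] object.
#' @return List with `owner` (integer cell id per site, 0 = empty), `eps`
#'   (polarization field, 0 on unoccupied sites), `F` (regulatory
#'   accumulators of the current, unfinished MCS), `mcs` (completed steps),
#'   `n_pairs` (current directed boundary-pair count) and `ps2` (squared
#'   perimeter-unit factor in use).
#' @export
sim_state <- function(sim) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_state_cpp(sim$ptr)
}

#' Per-cell summary table
#'
#' @param sim A [cpm_simulation()] object.
#' @return Data frame with one row per living cell: `cell`, `area`,
#'   `perimeter` (boundary-edge count), unwrapped center of mass `x`, `y`,
#'   cycle `phase` (0 quiescent, 1 growth, 2 division) and `clock`,
#'   `mean_eps`, and the effective `kappa_A_eff`, `kappa_P_eff`,
#'   `delta_eps_eff`.
#' @export
sim_cells <- function(sim) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_cells_cpp(sim$ptr)
}

#' Current directed boundary pairs
#'
#' The proposal set of the engine: all directed lattice-neighbor pairs
#' `(source, target)` with distinct owners, at least one of them a cell,
#' and neither site forbidden.
#'
#' @param sim A [cpm_simulation()] object.
#' @return Data frame with columns `source` and `target` (site indices).
#' @export
boundary_pairs <- function(sim) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_pairs_cpp(sim$ptr)
}

#' Apply one elementary event directly
#'
#' Copies the owner of `source` onto `target` (bypassing the acceptance
#' step), updating all caches; optionally records the regulatory feedback
#' of the event.  Moves that would fragment or annihilate a cell are
#' errors.  Intended for tests and custom kinetics.
#'
#' @inheritParams event_delta
#' @param feedback Record the regulatory feedback of the event?
#' @return `sim`, invisibly.
#' @export
apply_event <- function(sim, source, target, feedback = TRUE) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_apply_cpp(sim$ptr, as.integer(source), as.integer(target),
                isTRUE(feedback))
  invisible(sim)
}

#' Consistency audit of all cached state
#'
#' Recomputes areas, perimeters, center-of-mass sums, connectivity,
#' polarization bounds and the boundary-pair set from scratch and compares
#' them with the engine's incremental caches.
#'
#' @param sim A [cpm_simulation()] object.
#' @return List with `ok` (logical) and `messages` (character vector of
#'   discrepancies, empty when `ok`).
#' @export
sim_audit <- function(sim) {
  stopifnot(inherits(sim, "cpm_simulation"))
  cpm_audit_cpp(sim$ptr)
}

#' Run a simulation and record per-cell trajectories
#'
#' Runs `t_sim` MCS, recording the per-cell table every `record_every` MCS
#' (including the initial state at `mcs = 0` relative to the call).
#'
#' @param sim A [cpm_simulation()] object.
#' @param t_sim Total MCS to run, `>= 1`.
#' @param record_every Recording interval in MCS.
#' @param record_state Also keep the per-site `owner` vector at each
#'   recording time (needed for kymographs and front roughness)?
#' @return List with `trajectory` (long data frame: recorded [sim_cells()]
#'   tables with an `mcs` column), `record_every`, and—when requested—
#'   `owners` (list of integer vectors) with `owner_mcs`.
#' @export
run_simulation <- function(sim, t_sim, record_every = 10L,
                           record_state = FALSE) {
  stopifnot(inherits(sim, "cpm_simulation"))
  t_sim <- as.integer(t_sim)
  record_every <- as.integer(record_every)
  if (is.na(t_sim) || t_sim < 1) stop("t_sim must be >= 1")
  if (is.na(record_every) || record_every < 1)
    stop("record_every must be >= 1")
  times <- unique(c(seq(0L, t_sim, by = record_every), t_sim))
  traj <- vector("list", length(times))
  owners <- if (record_state) vector("list", length(times)) else NULL
  t0 <- as.integer(sim_state(sim)$mcs)
  prev <- 0L
  for (i in seq_along(times)) {
    if (times[i] > prev) run_mcs(sim, times[i] - prev)
    prev <- times[i]
    cells <- sim_cells(sim)
    cells$mcs <- times[i] + t0
    traj[[i]] <- cells
    if (record_state) owners[[i]] <- sim_state(sim)$owner
  }
  out <- list(trajectory = do.call(rbind, traj), record_every = record_every)
  if (record_state) {
    out$owners <- owners
    out$owner_mcs <- times + t0
  }
  out
}
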