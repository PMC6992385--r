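# Experiment harnesses: free single cell, confined cluster on a circular
# micropattern, and expanding proliferating monolayer.

#' Derive independent child seeds from one master seed
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` distinct seeds in `[1, 2^31 - 1]`.
#' @export
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' Simulate a free single cell
#'
#' One cell on a periodic lattice, started as an unpolarized compact blob
#' at its equilibrium area, run for `t_sim` MCS with the center-of-mass
#' trajectory recorded every `record_every` MCS.
#'
#' @param params A [cpm_params()] object.
#' @param t_sim Total MCS.
#' @param record_every Recording interval (MCS).
#' @param seed Integer seed.
#' @param lattice_side Optional lattice side length (even); defaults to a
#'   size comfortably larger than the cell.
#' @param cell_area Initial cell area; defaults to [equilibrium_area()].
#' @return List with `positions` (matrix of unwrapped COM samples),
#'   `trajectory` (full per-cell table with `mcs`), `record_every`,
#'   `params`, and `sim` (the live simulation, e.g. for [cell_shape()]).
#' @export
simulate_single_cell <- function(params, t_sim = 2000, record_every = 10,
                                 seed = 1, lattice_side = NULL,
                                 cell_area = NULL) {
  stopifnot(inherits(params, "cpm_params"))
  if (is.null(cell_area)) cell_area <- equilibrium_area(params)
  if (is.null(lattice_side)) {
    lattice_side <- max(40, ceiling(4.5 * sqrt(cell_area)))
  }
  if (lattice_side %% 2 == 1) lattice_side <- lattice_side + 1
  lat <- build_lattice(lattice_side, lattice_side, "periodic", "periodic")
  center <- (lattice_side %/% 2) * lattice_side + lattice_side %/% 2 + 1
  sim <- cpm_simulation(lat, params,
                        cells = list(place_blob(lat, center, cell_area)),
                        seed = seed)
  rec <- run_simulation(sim, t_sim, record_every)
  traj <- rec$trajectory
  list(positions = cbind(traj$x, traj$y), trajectory = traj,
       record_every = record_every, params = params, sim = sim)
}

#' Simulate a confined cell cluster on a circular micropattern
#'
#' `n_cells` cells tessellating an admissible disk of radius `r0`
#' (impenetrable outside), run for `t_sim` MCS.  The signed cluster
#' angular velocity is computed from the recorded center-of-mass
#' velocities at every recording interval.
#'
#' @param params A [cpm_params()] object (cluster runs typically use
#'   `B = 0`, `delta_B > 0`).
#' @param r0 Pattern radius.
#' @param n_cells Number of cells (default 4).
#' @param t_sim Total MCS.
#' @param record_every Recording interval (MCS).
#' @param seed Integer seed.
#' @param cell_area Initial area per cell (sites); defaults to
#'   [equilibrium_area()], capped so the cluster leaves free room on the
#'   pattern (cells must be able to protrude into empty space; a fully
#'   tessellated pattern with cell-cell friction is kinetically arrested).
#' @return List with `omega` (signed angular-velocity series), `omega_mcs`
#'   (its times), `mean_perimeter` (population-mean perimeter series),
#'   `stats` ([rotation_stats()]), `trajectory`, `params`, `sim`.
#' @export
simulate_rotation <- function(params, r0, n_cells = 4, t_sim = 2000,
                              record_every = 10, seed = 1,
                              cell_area = NULL) {
  stopifnot(inherits(params, "cpm_params"))
  ncols <- ceiling(2 * r0 + 8)
  nrows <- ceiling((2 * r0 + 8) / (sqrt(3) / 2))
  lat <- build_lattice(ncols, nrows, "open", "open")
  env <- circular_pattern(lat, r0)
  # pattern center used by circular_pattern (the lattice center)
  center <- c(lat$n_cols / 2, lat$n_rows * sqrt(3) / 4)
  adm <- which(!env$forbidden)
  if (is.null(cell_area)) cell_area <- equilibrium_area(params)
  cell_area <- min(cell_area, floor(0.85 * length(adm) / n_cells))
  # confluent cluster on a concentric sub-disk, free annulus around it
  d2 <- (lat$coords[adm, 1] - center[1])^2 +
        (lat$coords[adm, 2] - center[2])^2
  core <- adm[order(d2)][seq_len(n_cells * cell_area)]
  r_core <- sqrt(max(d2[order(d2)][n_cells * cell_area]))
  cells <- partition_region(lat, core,
                            cluster_seed_positions(center, r_core, n_cells))
  cells <- cells[vapply(cells, length, integer(1)) > 0]
  sim <- cpm_simulation(lat, params, cells = cells, environment = env,
                        seed = seed)
  rec <- run_simulation(sim, t_sim, record_every)
  traj <- rec$trajectory
  times <- sort(unique(traj$mcs))
  omega <- rep(NA_real_, length(times) - 1L)
  meanP <- vapply(times, function(tt) {
    mean(traj$perimeter[traj$mcs == tt])
  }, numeric(1))
  for (k in 2:length(times)) {
    now <- traj[traj$mcs == times[k], ]
    prev <- traj[traj$mcs == times[k - 1L], ]
    m <- match(now$cell, prev$cell)
    dtk <- times[k] - times[k - 1L]
    vel <- cbind(now$x - prev$x[m], now$y - prev$y[m]) / dtk
    omega[k - 1L] <- cluster_angular_velocity(cbind(now$x, now$y), vel)
  }
  list(omega = omega, omega_mcs = times[-1],
       mean_perimeter = meanP,
       stats = rotation_stats(omega, meanP),
       trajectory = traj, params = params, sim = sim)
}

#' Simulate an expanding (optionally proliferating) monolayer
#'
#' A confluent strip of cells between lateral walls at
#' `x = x_center ± half_width` on a y-periodic lattice.  After `t_relax`
#' MCS of confined relaxation the walls are removed and the expansion is
#' recorded for `t_sim` MCS (per-cell tables plus per-site owner
#' snapshots, for kymographs and front roughness).
#'
#' @param params A [cpm_params()] object.
#' @param n_cells Number of cells tessellating the confined band.
#' @param half_width Wall half-distance (Cartesian length).
#' @param lattice_cols,lattice_rows Lattice dimensions (x open, y
#'   periodic); `lattice_rows` must be even.
#' @param cycle Optional [cycle_params()] (with `A_ref` set) for dividing
#'   cells; `NULL` for a mitostatic sheet.
#' @param t_relax Confined relaxation time before wall removal (MCS).
#' @param t_sim Recorded expansion time after wall removal (MCS).
#' @param record_every Recording interval (MCS).
#' @param seed Integer seed.
#' @return List with `records` (see [run_simulation()] with state), `lattice`,
#'   `wall_x` (the removed wall positions), `params`, `sim`.
#' @export
simulate_tissue <- function(params, n_cells, half_width,
                            lattice_cols, lattice_rows,
                            cycle = NULL, t_relax = 100, t_sim = 1500,
                            record_every = 10, seed = 1) {
  stopifnot(inherits(params, "cpm_params"))
  if (lattice_rows %% 2 == 1) stop("lattice_rows must be even (periodic y)")
  lat <- build_lattice(lattice_cols, lattice_rows, "open", "periodic")
  xc <- lattice_cols / 2
  env <- strip_walls(lat, xc - half_width, xc + half_width)
  admissible <- !env$forbidden
  # seed grid filling the band
  ny <- max(1L, round(sqrt(n_cells * lattice_rows * sqrt(3) / 2 /
                           (2 * half_width))))
  nx <- ceiling(n_cells / ny)
  seeds <- list()
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      if (k >= n_cells) break
      k <- k + 1L
      seeds[[k]] <- c(xc - half_width + (ix - 0.5) * 2 * half_width / nx,
                      (iy - 0.5) * lattice_rows * sqrt(3) / 2 / ny)
    }
  }
  # snap seeds to distinct admissible sites
  seed_sites <- integer(0)
  adm_sites <- which(admissible)
  for (s in seeds) {
    d2 <- (lat$coords[adm_sites, 1] - s[1])^2 +
          (lat$coords[adm_sites, 2] - s[2])^2
    ordc <- adm_sites[order(d2)]
    seed_sites <- c(seed_sites, ordc[!(ordc %in% seed_sites)][1])
  }
  cells <- partition_region(lat, admissible, as.list(seed_sites))
  cells <- cells[vapply(cells, length, integer(1)) > 0]
  sim <- cpm_simulation(lat, params, cells = cells, environment = env,
                        cycle = cycle, seed = seed)
  if (t_relax > 0) run_mcs(sim, t_relax)
  remove_walls(sim)
  rec <- run_simulation(sim, t_sim, record_every, record_state = TRUE)
  list(records = rec, lattice = lat,
       wall_x = c(xc - half_width, xc + half_width),
       params = params, sim = sim)
}

#' Mean cell density series of a tissue run
#'
#' Number of cells divided by the total occupied area at each recording
#' time: the reciprocal mean cell area.  In a proliferating sheet this
#' series oscillates with the cell-cycle period (growth dilutes the
#' density of cells per unit tissue area; division restores it).
#'
#' @param trajectory A recorded trajectory table (from
#'   [run_simulation()]).
#' @return Data frame with `mcs` and `density` (cells per site).
#' @export
mean_density_series <- function(trajectory) {
  times <- sort(unique(trajectory$mcs))
  dens <- vapply(times, function(tt) {
    rows <- trajectory$mcs == tt
    sum(rows) / sum(trajectory$area[rows])
  }, numeric(1))
  data.frame(mcs = times, density = dens)
}
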