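# Analysis layer: trajectory statistics, shape metrics, rotation metrics,
# and tissue kymographs.

#' Mean-squared displacement
#'
#' Time-averaged (and, across replicates, ensemble-averaged) squared
#' displacement \eqn{MSD(\tau) = \langle [R(t+\tau) - R(t)]^2 \rangle}.
#'
#' @param positions An `n x 2` matrix of unwrapped positions sampled at
#'   interval `dt`, or a list of such matrices (replicates).
#' @param lags Integer vector of lags in samples; defaults to
#'   `1..(n - 1)`.
#' @param dt Sampling interval (MCS per sample), used only to label `tau`.
#' @return Data frame with `tau` (`lags * dt`), `msd`, and `n_pairs` (the
#'   number of averaged displacement pairs).
#' @export
msd <- function(positions, lags = NULL, dt = 1) {
  reps <- if (is.list(positions)) positions else list(positions)
  reps <- lapply(reps, as.matrix)
  nmin <- min(vapply(reps, nrow, integer(1)))
  if (nmin < 2) stop("need at least 2 samples")
  if (is.null(lags)) lags <- seq_len(nmin - 1L)
  lags <- as.integer(lags)
  if (length(lags) == 0L) stop("empty lag set")
  if (any(lags < 1L | lags >= nmin)) stop("lags must lie within the series")
  sums <- numeric(length(lags))
  counts <- numeric(length(lags))
  for (xy in reps) {
    n <- nrow(xy)
    for (i in seq_along(lags)) {
      L <- lags[i]
      if (L >= n) next
      d <- xy[(1 + L):n, , drop = FALSE] - xy[1:(n - L), , drop = FALSE]
      sums[i] <- sums[i] + sum(d^2)
      counts[i] <- counts[i] + (n - L)
    }
  }
  data.frame(tau = lags * dt, msd = sums / counts, n_pairs = counts)
}

#' Normalized velocity autocorrelation of the heading
#'
#' \eqn{C(\tau) = \langle \hat v(t+\tau) \cdot \hat v(t) \rangle} of the
#' unit headings \eqn{\hat v}, which are computed from successive
#' displacements; samples with zero displacement have no heading and are
#' excluded pairwise.  `C(0) = 1` by construction.
#'
#' @inheritParams msd
#' @param lags Integer vector of lags in samples (0 allowed); defaults to
#'   `0..(n - 2)`.
#' @return Data frame with `tau`, `vacf`, `n_pairs`.
#' @export
vacf <- function(positions, lags = NULL, dt = 1) {
  reps <- if (is.list(positions)) positions else list(positions)
  reps <- lapply(reps, as.matrix)
  headings <- lapply(reps, function(xy) {
    d <- diff(xy)
    nrm <- sqrt(rowSums(d^2))
    h <- d / nrm
    h[nrm == 0, ] <- NA_real_
    h
  })
  if (all(vapply(headings, function(h) all(is.na(h[, 1])), logical(1))))
    stop("all velocities are zero: headings undefined")
  nmin <- min(vapply(headings, nrow, integer(1)))
  if (is.null(lags)) lags <- 0:(nmin - 2L)
  lags <- as.integer(lags)
  if (length(lags) == 0L) stop("empty lag set")
  sums <- numeric(length(lags))
  counts <- numeric(length(lags))
  for (h in headings) {
    n <- nrow(h)
    for (i in seq_along(lags)) {
      L <- lags[i]
      if (L >= n) next
      dot <- rowSums(h[(1 + L):n, , drop = FALSE] *
                     h[1:(n - L), , drop = FALSE])
      sums[i] <- sums[i] + sum(dot, na.rm = TRUE)
      counts[i] <- counts[i] + sum(!is.na(dot))
    }
  }
  data.frame(tau = lags * dt, vacf = sums / counts, n_pairs = counts)
}

#' Persistent-random-walk (Fuerth) fit of an MSD curve
#'
#' Least-squares fit of the two-dimensional Fuerth form
#' \deqn{MSD(\tau) = 2 v^2 \tau_p [\tau - \tau_p (1 - e^{-\tau/\tau_p})]}
#' yielding the speed `v` and persistence time `tau_p`.
#'
#' @param msd_curve Data frame with columns `tau` and `msd` (from
#'   [msd()]), at least 5 points.
#' @return List with `v`, `tau_p`, `converged` (logical) and `fit` (the
#'   underlying `nls` object, or `NULL` if the fit failed).  Non-
#'   convergence is flagged, never silent.
#' @export
fit_prw <- function(msd_curve) {
  tau <- msd_curve$tau
  y <- msd_curve$msd
  if (length(tau) < 5) stop("need at least 5 lag points")
  keep <- tau > 0 & is.finite(y)
  tau <- tau[keep]; y <- y[keep]
  # starting values: diffusive tail slope gives 4 D = 2 v^2 tau_p;
  # short-lag ballistic level gives v^2
  k <- max(2L, ceiling(length(tau) * 0.1))
  v0 <- sqrt(max(mean(y[seq_len(k)] / tau[seq_len(k)]^2), 1e-12))
  Dtail <- max(mean(tail(y, k) / tail(tau, k)) / 4, 1e-12)
  tp0 <- max(Dtail * 2 / v0^2, tau[2] / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 2 * v^2 * tp * (tau - tp * (1 - exp(-tau / tp))),
      data = data.frame(tau = tau, y = y),
      start = list(v = v0, tp = tp0),
      lower = c(1e-9, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(v = NA_real_, tau_p = NA_real_, converged = FALSE,
                fit = NULL))
  }
  cf <- coef(fit)
  list(v = unname(cf["v"]), tau_p = unname(cf["tp"]),
       converged = fit$convInfo$isConv %||% TRUE, fit = fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gyration-tensor shape metrics
#'
#' Principal lengths \eqn{l_\pm} (square roots of the eigenvalues of the
#' center-of-mass-centered second-moment tensor of the site coordinates)
#' and the aspect ratio \eqn{l_+ / l_-}.
#'
#' @param coords An `n x 2` matrix of (unwrapped) site coordinates of one
#'   cell, `n >= 3`.
#' @return List with `aspect_ratio` (`Inf` for degenerate, collinear
#'   cells), `l` (length-2 vector `c(l_plus, l_minus)`), and `axes` (2x2
#'   matrix of eigenvectors in columns, major first).
#' @export
shape_metrics <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 sites")
  cc <- scale(coords, scale = FALSE)
  S <- crossprod(cc) / nrow(cc)
  e <- eigen(S, symmetric = TRUE)
  l <- sqrt(pmax(e$values, 0))
  ar <- if (l[2] <= .Machine$double.eps * max(1, l[1])) Inf else l[1] / l[2]
  list(aspect_ratio = ar, l = l, axes = e$vectors)
}

#' Shape metrics of a cell in a running simulation
#'
#' @param sim A [cpm_simulation()] object.
#' @param cell Cell id.
#' @return See [shape_metrics()].
#' @export
cell_shape <- function(sim, cell) {
  stopifnot(inherits(sim, "cpm_simulation"))
  sites <- which(sim_state(sim)$owner == cell)
  if (length(sites) == 0L) stop("no such cell")
  uv <- unwrap_sites(sim$lattice, sites)
  shape_metrics(cbind(uv$x, uv$y))
}

#' Mean trajectory curvature
#'
#' Mean magnitude of the arc-length derivative of the smoothed unit
#' tangent, \eqn{\langle |\Delta\theta| / \Delta s \rangle}: positions are
#' boxcar-averaged over `smoothing_window` MCS, tangent angles are taken
#' between successive smoothed points, and the turning angle per arc
#' length is averaged over segments (zero-length segments are skipped).
#'
#' @param positions An `n x 2` matrix of unwrapped positions.
#' @param dt Sampling interval (MCS per sample).
#' @param smoothing_window Smoothing window in MCS (default 10).
#' @return Mean curvature (1 / length).
#' @export
trajectory_curvature <- function(positions, dt = 1, smoothing_window = 10) {
  xy <- as.matrix(positions)
  w <- max(1L, round(smoothing_window / dt))
  if (w > 1L) {
    kern <- rep(1 / w, w)
    n <- nrow(xy) - w + 1L
    if (n < 3) stop("trajectory too short for this smoothing window")
    sm <- apply(xy, 2, function(v) {
      as.numeric(stats::filter(v, kern, sides = 1))[w:nrow(xy)]
    })
  } else {
    sm <- xy
  }
  d <- diff(sm)
  len <- sqrt(rowSums(d^2))
  ok <- len > 0
  d <- d[ok, , drop = FALSE]
  len <- len[ok]
  if (nrow(d) < 2) stop("trajectory has no direction changes to measure")
  th <- atan2(d[, 2], d[, 1])
  dth <- diff(th)
  dth <- atan2(sin(dth), cos(dth))       # wrap to (-pi, pi]
  ds <- (len[-1] + len[-length(len)]) / 2
  mean(abs(dth) / ds)
}

#' Signed angular velocity of a cell cluster
#'
#' \eqn{\omega = e_z \cdot \langle \tilde R \times \tilde v /
#' \|\tilde R\|^2 \rangle} over the cells, with positions and velocities
#' taken relative to the cluster means.  Counterclockwise rotation is
#' positive.  Cells at the cluster centroid are excluded from the average.
#'
#' @param positions,velocities `n_cells x 2` matrices.
#' @return Scalar angular velocity (radians per time unit of `velocities`).
#' @export
cluster_angular_velocity <- function(positions, velocities) {
  R <- as.matrix(positions); V <- as.matrix(velocities)
  if (nrow(R) < 2) stop("need at least 2 cells")
  Rt <- scale(R, scale = FALSE)
  Vt <- scale(V, scale = FALSE)
  r2 <- rowSums(Rt^2)
  ok <- r2 > 1e-12
  if (!any(ok)) stop("all cells at the cluster centroid")
  mean((Rt[ok, 1] * Vt[ok, 2] - Rt[ok, 2] * Vt[ok, 1]) / r2[ok])
}

#' Rotation statistics of a cluster run
#'
#' @param omega Numeric vector: signed angular velocity time series.
#' @param perimeter Optional numeric vector: population-mean cell
#'   perimeter time series.
#' @return List with `mean_abs_omega`, `sd_abs_omega` (standard deviation
#'   of `|omega|`), `sd_omega` (of the signed series), and `sigma_P`
#'   (standard deviation of the perimeter series, `NA` if not given).
#' @export
rotation_stats <- function(omega, perimeter = NULL) {
  if (length(omega) < 2) stop("series too short")
  list(mean_abs_omega = mean(abs(omega)),
       sd_abs_omega = sd(abs(omega)),
       sd_omega = sd(omega),
       sigma_P = if (is.null(perimeter)) NA_real_ else sd(perimeter))
}

#' Per-cell isotropic stress
#'
#' Virtual-dilation stress estimator: the derivative of the cell's energy
#' with respect to a uniform area dilation, per unit area, with tension
#' positive:
#' \deqn{\sigma = 2 \kappa_A^{eff} A + \kappa_P^{eff} P^2 / A -
#'   \bar\epsilon,}
#' where `P` is the perimeter in energy units (see
#' `perimeter_unit` in [cpm_params()]).  A solitary resting cell at its
#' equilibrium area has \eqn{\sigma \approx 0}; compressed cells are at
#' \eqn{\sigma < 0}.
#'
#' @param cells A [sim_cells()] data frame (columns `area`, `perimeter`,
#'   `mean_eps`, `kappa_A_eff`, `kappa_P_eff`).
#' @param ps2 Squared perimeter-unit factor (`sim_state(sim)$ps2`).
#' @return Numeric vector of per-cell stresses.
#' @export
cell_stress <- function(cells, ps2 = 1 / 3) {
  2 * cells$kappa_A_eff * cells$area +
    cells$kappa_P_eff * ps2 * cells$perimeter^2 / cells$area -
    cells$mean_eps
}

#' Tissue kymographs: density, stress, and velocity
#'
#' Space-time maps of the y-averaged cell density (occupied-site
#' fraction), the stress component \eqn{\sigma_{xx}} (per-cell
#' [cell_stress()] apportioned to bins by site occupancy, per unit bin
#' area), and the x-velocity (occupancy-weighted mean center-of-mass
#' velocity), binned along the Cartesian x-axis.
#'
#' When `eps_rest` is supplied, the stress map uses only the mechanical
#' (contractile/elastic) part of the cell stress,
#' \eqn{\sigma_{mech} = \sigma + (\bar\epsilon - \epsilon_0)}: the
#' \eqn{-\bar\epsilon} term of [cell_stress()] is an active "swim
#' pressure" that rises exactly where cells polarize, so in a migrating
#' front it cancels the mechanical stretch signal of the traction-bearing
#' cells; the mechanical part isolates the transmitted tension (the
#' X-shaped pattern of an expanding sheet).
#'
#' @param records Output of [run_simulation()] with `record_state = TRUE`.
#' @param lattice The simulation's [build_lattice()] object.
#' @param x_breaks Numeric vector of x-bin edges covering the admissible
#'   range.
#' @param ps2 Squared perimeter-unit factor (`sim_state(sim)$ps2`).
#' @param eps_rest Optional resting polarization `eps0`; if given, the
#'   stress kymograph shows the mechanical stress part (see above).
#' @return List with `x_mid` (bin centers), `mcs` (recording times), and
#'   matrices `density`, `sigma_xx`, `vx` of dimension
#'   `length(x_mid) x length(mcs)`; bins without cells hold `NA` in
#'   `sigma_xx` and `vx`.
#' @export
tissue_kymographs <- function(records, lattice, x_breaks, ps2 = 1 / 3,
                              eps_rest = NULL) {
  if (is.null(records$owners))
    stop("records must be produced with record_state = TRUE")
  xs <- lattice$coords[, 1]
  bin <- findInterval(xs, x_breaks, rightmost.closed = TRUE)
  nb <- length(x_breaks) - 1L
  inside <- bin >= 1L & bin <= nb
  sites_per_bin <- tabulate(bin[inside], nb)
  times <- records$owner_mcs
  nt <- length(times)
  dens <- matrix(NA_real_, nb, nt)
  sxx <- matrix(NA_real_, nb, nt)
  vx <- matrix(NA_real_, nb, nt)
  traj <- records$trajectory
  for (k in seq_len(nt)) {
    ow <- records$owners[[k]]
    occ <- inside & ow > 0L
    dens[, k] <- tabulate(bin[occ], nb) / pmax(sites_per_bin, 1L)
    cells_k <- traj[traj$mcs == times[k], , drop = FALSE]
    if (nrow(cells_k) == 0L) next
    sig <- cell_stress(cells_k, ps2)
    if (!is.null(eps_rest)) sig <- sig + (cells_k$mean_eps - eps_rest)
    # per-cell x velocity from the previous recording time
    vxc <- rep(NA_real_, nrow(cells_k))
    if (k > 1L) {
      prev <- traj[traj$mcs == times[k - 1L], , drop = FALSE]
      m <- match(cells_k$cell, prev$cell)
      dtk <- times[k] - times[k - 1L]
      vxc <- (cells_k$x - prev$x[m]) / dtk
    }
    # occupancy of each cell per bin (full nb x n_cells count matrix)
    idx <- match(ow[occ], cells_k$cell)
    tab <- table(factor(bin[occ], levels = seq_len(nb)),
                 factor(idx, levels = seq_len(nrow(cells_k))))
    any_cell <- rowSums(tab) > 0
    sxx[any_cell, k] <- (tab %*% sig)[any_cell] /
                        pmax(sites_per_bin[any_cell], 1L)
    if (k > 1L) {
      wv <- tab %*% ifelse(is.na(vxc), 0, vxc)
      ww <- tab %*% as.numeric(!is.na(vxc))
      vx[, k] <- ifelse(ww > 0, wv / ww, NA_real_)
    }
  }
  list(x_mid = (head(x_breaks, -1) + tail(x_breaks, -1)) / 2,
       mcs = times, density = dens, sigma_xx = sxx, vx = vx)
}

#' Front roughness of an expanding tissue
#'
#' Standard deviation of the leading-edge profile `h(y)`: for every
#' lattice row, the outermost occupied Cartesian `x` on the chosen side.
#' Rows with no tissue are excluded.
#'
#' @param owner Integer owner vector (`sim_state(sim)$owner`).
#' @param lattice The simulation's [build_lattice()] object.
#' @param side `"right"` (largest x) or `"left"` (smallest x).
#' @return Roughness `w` (a length).
#' @export
front_roughness <- function(owner, lattice, side = c("right", "left")) {
  side <- match.arg(side)
  occ <- which(owner > 0L)
  if (length(occ) == 0L) stop("no tissue on the lattice")
  row <- (occ - 1L) %/% lattice$n_cols
  x <- lattice$coords[occ, 1]
  f <- if (side == "right") max else min
  h <- tapply(x, row, f)
  sd(h)
}

#' Dominant oscillation period of a time series
#'
#' Linearly detrends the series and returns the period of the largest
#' periodogram peak.
#'
#' @param series Numeric time series.
#' @param dt Sampling interval (MCS per sample).
#' @return Dominant period in MCS.
#' @export
dominant_period <- function(series, dt = 1) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 8) stop("series too short")
  t <- seq_len(n)
  detr <- stats::residuals(lm(series ~ t))
  pg <- spec.pgram(detr, taper = 0, detrend = FALSE, demean = TRUE,
                   plot = FALSE)
  dt / pg$freq[which.max(pg$spec)]
}

#' Growth-burst period from peak spacing of a density series
#'
#' Extracts the period of recurrent growth bursts from a mean-density
#' time series (see [mean_density_series()]) by the spacing of the
#' sharp density rises that mark synchronized division waves.  The
#' series is differentiated; samples whose rise rate exceeds
#' `threshold_frac` of the maximum rise rate are grouped into bursts
#' (gaps larger than `min_gap` separate bursts), and each burst is
#' timestamped by its first sample.  The period is the mean spacing of
#' the first `max_bursts` burst times.
#'
#' Only the earliest bursts are used because the initial condition
#' synchronizes the whole population: the first division waves are full
#' population doublings spaced by exactly one cell-cycle duration,
#' whereas later waves are increasingly front-limited (bulk cells are
#' contact-inhibited) and therefore broadened and delayed.
#'
#' @param density Numeric density series.
#' @param mcs Sample times (MCS), same length.
#' @param threshold_frac Fraction of the maximum rise rate above which a
#'   sample counts as part of a burst.
#' @param min_gap Minimum time separation (MCS) between distinct bursts.
#' @param max_bursts Number of leading bursts used for the spacing.
#' @return Burst period in MCS, or `NA` if fewer than two bursts are
#'   detected.
#' @export
burst_period <- function(density, mcs, threshold_frac = 0.2,
                         min_gap = 40, max_bursts = 3) {
  stopifnot(length(density) == length(mcs), length(density) >= 3)
  rate <- diff(density) / diff(mcs)
  if (max(rate) <= 0) return(NA_real_)
  marks <- mcs[-1][rate > threshold_frac * max(rate)]
  if (length(marks) == 0) return(NA_real_)
  grp <- cumsum(c(TRUE, diff(marks) > min_gap))
  onsets <- vapply(split(marks, grp), min, numeric(1))
  onsets <- head(sort(onsets), max_bursts)
  if (length(onsets) < 2) return(NA_real_)
  (max(onsets) - min(onsets)) / (length(onsets) - 1)
}
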