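# Closed-form synthetic inputs for every observable.

ballistic <- function(v, n, dt = 1, dir = c(1, 0)) {
  cbind(dir[1] * v * dt * (0:n), dir[2] * v * dt * (0:n))
}

circle_path <- function(R, omega, n, dt = 1) {
  th <- omega * dt * (0:n)
  cbind(R * cos(th), R * sin(th))
}

test_that("mean-squared displacement is exact for ballistic and static
           motion", {
  pos <- ballistic(v = 2, n = 50)
  m <- msd(pos, lags = c(1, 5, 10), dt = 1)
  expect_equal(m$msd, (2 * c(1, 5, 10))^2)
  expect_equal(m$tau, c(1, 5, 10))
  still <- matrix(3, 21, 2)
  expect_equal(msd(still, lags = c(1, 4), dt = 1)$msd, c(0, 0))
})

test_that("ensemble averaging pools displacement pairs across
           replicates", {
  a <- ballistic(1, 20)
  b <- ballistic(3, 20)
  m <- msd(list(a, b), lags = 2, dt = 1)
  expect_equal(m$msd, mean(c(2^2, 6^2)))
  expect_equal(m$n_pairs, 2 * 19)
})

test_that("velocity autocorrelation matches closed forms for straight
           and circular motion", {
  v <- vacf(ballistic(1.7, 40), lags = c(0, 3, 7), dt = 1)
  expect_equal(v$vacf, c(1, 1, 1))
  cp <- circle_path(R = 20, omega = 0.1, n = 600)
  v2 <- vacf(cp, lags = c(0, 10, 20), dt = 1)
  # headings rotate at omega: C(tau) = cos(omega * tau)
  expect_equal(v2$vacf, cos(0.1 * c(0, 10, 20)), tolerance = 0.01)
})

test_that("persistent-random-walk fit recovers the parameters of a
           noiseless Fuerth curve exactly", {
  v <- 0.4; tp <- 80
  tau <- seq(5, 400, by = 5)
  curve <- data.frame(tau = tau,
                      msd = 2 * v^2 * tp * (tau - tp * (1 - exp(-tau / tp))))
  fit <- fit_prw(curve)
  expect_true(fit$converged)
  expect_equal(fit$v, v, tolerance = 1e-5)
  expect_equal(fit$tau_p, tp, tolerance = 1e-4)
})

test_that("persistent-random-walk fit recovers generator parameters from
           ensemble trajectories within ten percent", {
  walks <- generate_prw_fixture(v = 0.5, tau_p = 60, n_steps = 1500,
                                n_walkers = 40, seed = 123)
  m <- msd(walks, lags = unique(round(exp(seq(0, log(300), length = 30)))),
           dt = 1)
  fit <- fit_prw(m)
  expect_true(fit$converged)
  expect_lt(abs(fit$v - 0.5) / 0.5, 0.1)
  expect_lt(abs(fit$tau_p - 60) / 60, 0.2)
  # heading autocorrelation decays exponentially with tau_p
  v1 <- vacf(walks[[1]], lags = 60, dt = 1)
  expect_lt(abs(mean(sapply(walks[1:20], function(w)
    vacf(w, lags = 60, dt = 1)$vacf)) - exp(-1)), 0.15)
})

test_that("gyration aspect ratio is one for a symmetric cluster and
           divergent for a line", {
  lat <- build_lattice(20, 20, "periodic", "periodic")
  hexagon <- disk_neighborhood(lat, 10 * 20 + 10, 3)
  sm <- shape_metrics(lat$coords[hexagon, ])
  expect_lt(sm$aspect_ratio, 1.2)
  line <- cbind(seq(0, 10, 0.5), 0)
  expect_true(is.infinite(shape_metrics(line)$aspect_ratio))
})

test_that("trajectory curvature equals the inverse radius on a circle
           and vanishes on a line", {
  cp <- circle_path(R = 25, omega = 0.02, n = 2000)
  expect_equal(trajectory_curvature(cp, dt = 1), 1 / 25, tolerance = 0.05)
  expect_lt(trajectory_curvature(ballistic(0.5, 500), dt = 1), 1e-10)
})

test_that("cluster angular velocity is exact for rigid rotation and zero
           for pure translation", {
  th <- 2 * pi * (0:3) / 4
  pos <- cbind(10 + 5 * cos(th), 8 + 5 * sin(th))
  om <- 0.03
  vel <- om * cbind(-5 * sin(th), 5 * cos(th))
  expect_equal(cluster_angular_velocity(pos, vel), om)
  vel_t <- cbind(rep(0.2, 4), rep(-0.1, 4))
  expect_equal(cluster_angular_velocity(pos, vel_t), 0)
})

test_that("rotation statistics summarize the angular-velocity series", {
  om <- c(0.02, 0.025, 0.015, 0.02)
  per <- c(100, 102, 98, 100)
  rs <- rotation_stats(om, per)
  expect_equal(rs$mean_abs_omega, mean(abs(om)))
  expect_equal(rs$sd_abs_omega, sd(abs(om)))
  expect_equal(rs$sd_omega, sd(om))
  expect_equal(rs$sigma_P, sd(per))
})

test_that("front roughness vanishes for a flat front and grows with a
           protruding finger", {
  lat <- build_lattice(30, 12, "open", "periodic")
  owner <- integer(lat$n_sites)
  # flat front: columns 0..9 occupied in every row
  for (r in 0:11) owner[r * 30 + (1:10)] <- 1L
  w_flat <- front_roughness(owner, lat, "right")
  # protrusion: two rows reach 6 columns farther
  owner2 <- owner
  for (r in 5:6) owner2[r * 30 + (11:16)] <- 1L
  w_rough <- front_roughness(owner2, lat, "right")
  # the flat front only carries the odd-row offset of the hex lattice
  expect_equal(w_flat, sd(rep(c(0, 0.5), 6)))
  expect_gt(w_rough, w_flat + 1)
})

test_that("dominant period recovers a sinusoid over a linear trend", {
  t <- 0:199
  x <- 0.01 * t + sin(2 * pi * t / 25)
  expect_equal(dominant_period(x, dt = 1), 25, tolerance = 0.05)
})

test_that("burst period reads the spacing of sharp rises in a sawtooth
           density series, ignoring a delayed late burst", {
  mcs <- seq(0, 1400, by = 10)
  dens <- numeric(length(mcs))
  level <- 10
  bursts <- c(200, 400, 600, 1050)  # last burst front-limited and late
  for (i in seq_along(mcs)) {
    if (mcs[i] %in% bursts) level <- level + 3
    level <- level - 0.01
    dens[i] <- level
  }
  expect_equal(burst_period(dens, mcs), 200)
})

test_that("kymograph binning reproduces hand-computed density and stress
           of a static two-cell strip", {
  lat <- build_lattice(12, 4, "open", "periodic")
  owner <- integer(lat$n_sites)
  # cell 1 owns columns 0..3, cell 2 columns 4..7, columns 8..11 empty
  for (r in 0:3) {
    owner[r * 12 + (1:4)] <- 1L
    owner[r * 12 + (5:8)] <- 2L
  }
  cells <- data.frame(cell = c(1L, 2L), area = c(16, 16),
                      perimeter = c(10, 10), x = c(2, 6), y = c(1, 1),
                      mean_eps = c(30, 50), kappa_A_eff = 0.1,
                      kappa_P_eff = 0.06)
  traj0 <- transform(cells, mcs = 0L)
  traj1 <- transform(cells, x = x + 1, mcs = 10L)
  records <- list(trajectory = rbind(traj0, traj1),
                  owners = list(owner, owner), owner_mcs = c(0L, 10L))
  ky <- tissue_kymographs(records, lat, x_breaks = c(0, 4, 8, 12))
  expect_equal(dim(ky$density), c(3L, 2L))
  # each 4-column bin holds exactly one 16-site cell; the last is empty
  expect_equal(ky$density[, 1], c(1, 1, 0))
  sig <- cell_stress(cells)
  # a bin fully owned by one cell carries exactly that cell's stress
  # density (stress apportioned by site occupancy over the 16-site bin)
  expect_equal(ky$sigma_xx[1, 1], sig[1])
  expect_equal(ky$sigma_xx[2, 1], sig[2])
  expect_true(is.na(ky$sigma_xx[3, 1]))
  # x-velocity from the center-of-mass displacement
  expect_equal(ky$vx[1, 2], 0.1, tolerance = 1e-9)
  expect_true(all(is.na(ky$vx[, 1])))
})

test_that("a resting solitary cell carries vanishing stress", {
  p <- cpm_params(kappa_A = 0.18, kappa_P = 0.12, eps0 = 35,
                  delta_eps = 0)
  out <- simulate_single_cell(p, t_sim = 400, record_every = 10, seed = 7)
  tail_cells <- out$trajectory[out$trajectory$mcs > 100, ]
  sig <- cell_stress(tail_cells)
  # per-area stress scale: eps0 = 35; the time-averaged stress must be
  # small against it
  expect_lt(abs(mean(sig)), 0.15 * p$eps0)
})
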