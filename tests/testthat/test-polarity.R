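test_that("engine polarization update matches the pure R reference", {
  env <- make_three_cell_sim(seed = 2)
  sim <- env$sim
  p <- env$params
  st <- sim_state(sim)
  occ <- which(st$owner > 0)
  set.seed(9)
  eps <- st$eps
  eps[occ] <- runif(length(occ), p$eps0 - p$delta_eps / 2,
                    p$eps0 + p$delta_eps / 2)
  F <- integer(length(eps))
  F[occ] <- sample(c(-3L, -1L, 0L, 1L, 4L), length(occ), replace = TRUE)
  set_polarization(sim, eps)
  set_regulatory(sim, F)
  ref <- polarization_update(eps[occ], F[occ], p)
  update_polarization(sim)
  st1 <- sim_state(sim)
  expect_equal(st1$eps[occ], ref, tolerance = 1e-12)
  # accumulators are cleared after the once-per-MCS update
  expect_true(all(st1$F == 0))
})

test_that("upregulated sites relax toward the band edges and idle sites
           toward the rest value", {
  p <- cpm_params(eps0 = 100, delta_eps = 40, mu = 0.1)
  up <- polarization_update(100, 5L, p)
  down <- polarization_update(100, -2L, p)
  idle <- polarization_update(111, 0L, p)
  expect_equal(up, 100 + 0.1 * (120 - 100))
  expect_equal(down, 100 + 0.1 * (80 - 100))
  expect_equal(idle, 111 + 0.1 * (100 - 111))
  # band edges are fixed points
  expect_equal(polarization_update(120, 3L, p), 120)
  expect_equal(polarization_update(80, -1L, p), 80)
})

test_that("polarization remains inside the allowed band under the full
           stochastic dynamics", {
  p <- cpm_params(kappa_A = 0.18, kappa_P = 0.06, eps0 = 60,
                  delta_eps = 45, R = 3, mu = 0.1)
  out <- simulate_single_cell(p, t_sim = 150, record_every = 50, seed = 4)
  st <- sim_state(out$sim)
  occ <- which(st$owner > 0)
  expect_true(all(st$eps[occ] >= p$eps0 - p$delta_eps / 2 - 1e-9))
  expect_true(all(st$eps[occ] <= p$eps0 + p$delta_eps / 2 + 1e-9))
  expect_true(sim_audit(out$sim)$ok)
})

test_that("conquered sites inherit the conqueror's polarization", {
  env <- make_three_cell_sim(seed = 6)
  sim <- env$sim
  st <- sim_state(sim)
  pairs <- boundary_pairs(sim)
  # pick an expansion of a cell into another cell's site
  k <- which(st$owner[pairs$source] > 0 & st$owner[pairs$target] > 0)[1]
  s <- pairs$source[k]; t <- pairs$target[k]
  eps_s <- st$eps[s]
  apply_event(sim, s, t)
  st1 <- sim_state(sim)
  expect_equal(st1$owner[t], st1$owner[s])
  expect_equal(st1$eps[t], eps_s)
})

test_that("accepted events upregulate the protruding side and
           downregulate the retracting side within the signaling radius", {
  env <- make_three_cell_sim(seed = 8)
  sim <- env$sim
  lat <- env$lattice
  p <- env$params
  st <- sim_state(sim)
  pairs <- boundary_pairs(sim)
  k <- which(st$owner[pairs$source] > 0 & st$owner[pairs$target] > 0)[1]
  s <- pairs$source[k]; t <- pairs$target[k]
  a <- st$owner[s]; b <- st$owner[t]
  apply_event(sim, s, t, feedback = TRUE)
  st1 <- sim_state(sim)
  disk <- disk_neighborhood(lat, t, p$R)
  up <- disk[st1$owner[disk] == a]
  down <- disk[st1$owner[disk] == b]
  far <- setdiff(which(st1$owner > 0), disk)
  expect_true(all(st1$F[up] >= 1))
  expect_true(all(st1$F[down] <= -1))
  expect_true(all(st1$F[far] == 0))
})
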