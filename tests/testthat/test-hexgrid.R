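test_that("interior sites have six mutually consistent neighbors", {
  lat <- build_lattice(12, 12, "periodic", "periodic")
  expect_equal(lat$n_sites, 144)
  for (s in sample.int(lat$n_sites, 20)) {
    nb <- neighbors(lat, s)
    expect_length(nb, 6)
    expect_false(anyDuplicated(nb) > 0)
    # symmetry: s is a neighbor of each of its neighbors
    for (t in nb) expect_true(s %in% neighbors(lat, t))
  }
})

test_that("open boundaries trim the neighborhood instead of wrapping", {
  lat <- build_lattice(8, 8, "open", "open")
  corner <- 1L
  expect_lt(length(neighbors(lat, corner)), 6)
  # no neighbor pair may span the full lattice width
  for (s in seq_len(lat$n_sites)) {
    dx <- abs(lat$coords[neighbors(lat, s), 1] - lat$coords[s, 1])
    expect_true(all(dx < 2))
  }
})

test_that("all nearest-neighbor distances equal one lattice constant", {
  lat <- build_lattice(10, 10, "periodic", "periodic")
  # interior sites (wrapped pairs would need unwrapping)
  for (s in which(lat$coords[, 1] > 1 & lat$coords[, 1] < 8 &
                  lat$coords[, 2] > 1 & lat$coords[, 2] < 7)) {
    nb <- neighbors(lat, s)
    d <- sqrt((lat$coords[nb, 1] - lat$coords[s, 1])^2 +
              (lat$coords[nb, 2] - lat$coords[s, 2])^2)
    expect_equal(d, rep(1, length(nb)), tolerance = 1e-12)
  }
})

test_that("disk neighborhood equals breadth-first hex distance", {
  lat <- build_lattice(16, 16, "periodic", "periodic")
  center <- 100L
  dist <- hex_bfs_distance(lat, center)
  for (R in 0:4) {
    expect_equal(disk_neighborhood(lat, center, R),
                 sort(which(dist <= R)))
  }
})

test_that("connectivity predicate flags articulation sites of a cell", {
  lat <- build_lattice(16, 16, "open", "open")
  # dumbbell: two blobs joined through one bridge site on a row
  row <- 8L
  at <- function(col) row * lat$n_cols + col + 1L  # 0-based col
  cellsites <- c(at(2), at(3), at(4), at(5), at(6))  # straight chain
  owner <- integer(lat$n_sites)
  owner[cellsites] <- 1L
  # interior chain sites are articulation points, the ends are not
  expect_false(move_preserves_connectivity(lat, owner, at(4)))
  expect_true(move_preserves_connectivity(lat, owner, at(2)))
  expect_true(move_preserves_connectivity(lat, owner, at(6)))
})

test_that("center of mass unwraps cells straddling a periodic seam", {
  lat <- build_lattice(20, 20, "periodic", "periodic")
  # sites on row 4 at columns 19 and 0: adjacent across the x seam
  row <- 4L
  sites <- c(row * 20L + 19L + 1L, row * 20L + 0L + 1L)
  com <- center_of_mass(lat, sites)
  # unwrapped x must lie between the two sites (near the seam), not at
  # the lattice center
  expect_lt(min(abs(com[1] - 19.5), abs(com[1] - (-0.5))), 1)
})

test_that("gyration-axis split yields two connected, balanced halves", {
  lat <- build_lattice(24, 24, "open", "open")
  blob <- place_blob(lat, c(12, 10), 60)
  halves <- split_site_set(lat, blob)
  expect_setequal(c(halves$first, halves$second), blob)
  expect_length(intersect(halves$first, halves$second), 0)
  expect_true(sites_connected(lat, halves$first))
  expect_true(sites_connected(lat, halves$second))
  expect_lte(abs(length(halves$first) - length(halves$second)), 6)
})

test_that("compact blob placement is connected with near-minimal spread", {
  lat <- build_lattice(20, 20, "periodic", "periodic")
  blob <- place_blob(lat, c(10, 8), 37)
  expect_length(blob, 37)
  expect_true(sites_connected(lat, blob))
  com <- center_of_mass(lat, blob)
  r <- sqrt((lat$coords[blob, 1] - com[1])^2 +
            (lat$coords[blob, 2] - com[2])^2)
  # a compact disk of 37 sites has radius ~3.2 lattice constants
  expect_lt(max(r), 5)
})
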