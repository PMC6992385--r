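# Independent reference implementations used as oracles by the tests.
# These deliberately re-derive quantities from the raw site fields with
# plain R code, independent of the engine's cached incremental updates.

# Scratch recount of the configuration energy from the raw owner/eps
# fields: contractility + area terms per cell, minus the (substrate
# modified) polarization of every occupied site, minus B per undirected
# cell-cell contact edge.
scratch_energy <- function(lattice, owner, eps, params,
                           phi = NULL, phi_mode = "additive") {
  ps2 <- if (params$perimeter_unit == "contour") 1 / 3 else 1
  if (is.null(phi)) phi <- numeric(lattice$n_sites)
  H <- 0
  for (id in unique(owner[owner > 0L])) {
    sites <- which(owner == id)
    A <- length(sites)
    P <- 0L
    for (s in sites) {
      nb <- lattice$nbr[s, ]
      nb <- nb[!is.na(nb)]
      P <- P + sum(owner[nb] != id)
    }
    H <- H + params$kappa_A * A^2 + params$kappa_P * ps2 * P^2
  }
  occ <- which(owner > 0L)
  eff <- if (phi_mode == "additive") eps[occ] + phi[occ] else eps[occ] * phi[occ]
  H <- H - sum(eff)
  contacts2 <- 0L
  for (s in occ) {
    nb <- lattice$nbr[s, ]
    nb <- nb[!is.na(nb)]
    contacts2 <- contacts2 + sum(owner[nb] > 0L & owner[nb] != owner[s])
  }
  H - params$B * contacts2 / 2
}

# Brute-force enumeration of the valid directed boundary pairs from the
# raw owner field: neighbor pairs (s, t) with distinct owners, at least
# one of them belonging to a cell, and t not forbidden.
scratch_boundary_pairs <- function(lattice, owner, forbidden = NULL) {
  if (is.null(forbidden)) forbidden <- rep(FALSE, lattice$n_sites)
  out <- list()
  k <- 0L
  for (s in seq_len(lattice$n_sites)) {
    for (t in lattice$nbr[s, ]) {
      if (is.na(t) || forbidden[t]) next
      if (owner[s] != owner[t] && (owner[s] > 0L || owner[t] > 0L)) {
        k <- k + 1L
        out[[k]] <- c(s, t)
      }
    }
  }
  if (k == 0L) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

# Flood fill over the sites of one cell; TRUE if they form one connected
# component on the hex lattice.
sites_connected <- function(lattice, sites) {
  if (length(sites) <= 1L) return(TRUE)
  inset <- rep(FALSE, lattice$n_sites)
  inset[sites] <- TRUE
  seen <- rep(FALSE, lattice$n_sites)
  frontier <- sites[1]
  seen[frontier] <- TRUE
  while (length(frontier)) {
    nb <- as.vector(lattice$nbr[frontier, , drop = FALSE])
    nb <- nb[!is.na(nb)]
    nb <- unique(nb[inset[nb] & !seen[nb]])
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen[sites])
}

# Hex graph distance from one site by breadth-first search.
hex_bfs_distance <- function(lattice, from) {
  dist <- rep(NA_integer_, lattice$n_sites)
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nb <- as.vector(lattice$nbr[frontier, , drop = FALSE])
    nb <- nb[!is.na(nb)]
    nb <- unique(nb[is.na(dist[nb])])
    dist[nb] <- d
    frontier <- nb
  }
  dist
}

# Small three-cell simulation with every interaction term switched on,
# used by the energy-consistency random walks.
make_three_cell_sim <- function(seed = 1, delta_eps = 20, B = 3,
                                delta_B = 2, D = 1) {
  lat <- build_lattice(24, 24, "periodic", "periodic")
  p <- cpm_params(kappa_A = 0.1, kappa_P = 0.06, eps0 = 30,
                  delta_eps = delta_eps, R = 2, mu = 0.1,
                  B = B, delta_B = delta_B, D = D)
  # confluent patch of three mutually touching cells with a free rim
  patch <- place_blob(lat, c(12, 10), 90)
  cells <- partition_region(lat, patch,
                            list(c(10, 8), c(14, 8), c(12, 12)))
  list(sim = cpm_simulation(lat, p, cells = cells, seed = seed),
       lattice = lat, params = p)
}
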