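# Initial cell placement: compact blobs and space-filling partitions.

#' Compact blob of sites around a point
#'
#' A disk-like connected set of `area` sites centered on the site nearest
#' to `center` (or on a site index), built by accreting sites in order of
#' hex distance with Cartesian tie-breaking.  Prefixes of the accretion
#' order are always connected.
#'
#' @param lattice A [build_lattice()] object.
#' @param center Either a single site index, or a Cartesian `c(x, y)`
#'   position whose nearest site is used.
#' @param area Number of sites, `>= 1`.
#' @return Integer vector of `area` site indices.
#' @export
place_blob <- function(lattice, center, area) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (area < 1) stop("area must be >= 1")
  site <- resolve_site(lattice, center)
  compact_blob_order(lattice, site, as.integer(area))
}

resolve_site <- function(lattice, center) {
  if (length(center) == 1L) {
    site <- as.integer(center)
    if (site < 1 || site > lattice$n_sites) stop("site off lattice")
    return(site)
  }
  d2 <- (lattice$coords[, 1] - center[1])^2 +
        (lattice$coords[, 2] - center[2])^2
  which.min(d2)
}

#' Partition an admissible region among several cells
#'
#' Fills all admissible (non-forbidden) sites of a region with `n_cells`
#' connected cells by simultaneous breadth-first growth from seed sites —
#' a lattice Voronoi-like tessellation.  Used to prepare confluent initial
#' states (a filled circular micropattern, a confluent strip).
#'
#' @param lattice A [build_lattice()] object.
#' @param admissible Logical vector (length `n_sites`) or integer site
#'   vector of the region to fill.
#' @param seeds List of seed positions (site indices or Cartesian `c(x,y)`),
#'   one per cell, all admissible and distinct.
#' @return List of integer site vectors, one per cell; disjoint, connected,
#'   jointly covering the admissible sites reachable from the seeds.
#' @export
partition_region <- function(lattice, admissible, seeds) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (is.logical(admissible)) {
    adm <- which(admissible)
  } else {
    adm <- as.integer(admissible)
  }
  inreg <- rep(FALSE, lattice$n_sites)
  inreg[adm] <- TRUE
  seed_sites <- vapply(seeds, function(s) resolve_site(lattice, s),
                       integer(1))
  if (anyDuplicated(seed_sites)) stop("seed sites must be distinct")
  if (!all(inreg[seed_sites])) stop("all seeds must be admissible")
  label <- integer(lattice$n_sites)
  label[seed_sites] <- seq_along(seed_sites)
  frontier <- seed_sites
  while (length(frontier)) {
    nxt <- integer(0)
    for (s in frontier) {
      nb <- lattice$nbr[s, ]
      nb <- nb[!is.na(nb)]
      nb <- nb[inreg[nb] & label[nb] == 0L]
      if (length(nb)) {
        label[nb] <- label[s]
        nxt <- c(nxt, nb)
      }
    }
    frontier <- nxt
  }
  lapply(seq_along(seed_sites), function(i) which(label == i))
}

#' Seed positions for a cluster on a circular pattern
#'
#' Evenly spaced angular positions at radius `r0 / 2` around the pattern
#' center, for seeding `n_cells` cells that then tessellate the disk.
#'
#' @param center Cartesian pattern center `c(x, y)`.
#' @param r0 Pattern radius.
#' @param n_cells Number of cells.
#' @return List of Cartesian positions.
#' @export
cluster_seed_positions <- function(center, r0, n_cells) {
  ang <- 2 * pi * (seq_len(n_cells) - 1) / n_cells + pi / n_cells
  lapply(ang, function(a) center + r0 / 2 * c(cos(a), sin(a)))
}
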