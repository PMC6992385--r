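# Hexagonal lattice geometry and site bookkeeping.
#
# Sites are indexed 1..n_sites row-major on an "odd-r" offset grid:
# site = (row - 1) * n_cols + col, with Cartesian embedding
# x = (col - 1) + 0.5 * (row odd), y = (sqrt(3)/2) * (row - 1) and lattice
# constant 1.  The cyclic neighbor order is E, NE, NW, W, SW, SE.

#' Build a hexagonal lattice
#'
#' Constructs a honeycomb lattice with `n_cols * n_rows` sites, optionally
#' periodic in either direction, with precomputed neighbor tables and
#' Cartesian site coordinates.
#'
#' @param n_cols,n_rows Positive integer lattice dimensions.
#' @param boundary_x,boundary_y `"periodic"` or `"open"`.  Periodic `y`
#'   requires an even `n_rows` (offset-row parity must match across the
#'   seam).
#' @return An object of class `hex_lattice`: a list with `n_cols`, `n_rows`,
#'   `n_sites`, `periodic_x`, `periodic_y`, `nbr` (an `n_sites x 6` integer
#'   matrix of neighbor site indices, `NA` where a neighbor is absent under
#'   open boundaries) and `coords` (an `n_sites x 2` matrix of Cartesian
#'   `x`, `y`).
#' @examples
#' lat <- build_lattice(10, 10, "periodic", "periodic")
#' lat$n_sites            # 100
#' neighbors(lat, 1)      # 6 sites
#' @export
build_lattice <- function(n_cols, n_rows,
                          boundary_x = c("periodic", "open"),
                          boundary_y = c("periodic", "open")) {
  boundary_x <- match.arg(boundary_x)
  boundary_y <- match.arg(boundary_y)
  if (length(n_cols) != 1L || length(n_rows) != 1L ||
      is.na(n_cols) || is.na(n_rows) || n_cols < 1 || n_rows < 1)
    stop("lattice dimensions must be positive integers")
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)
  px <- boundary_x == "periodic"
  py <- boundary_y == "periodic"
  nbr <- hex_neighbors_cpp(n_cols, n_rows, px, py)
  coords <- hex_coords_cpp(n_cols, n_rows)
  colnames(coords) <- c("x", "y")
  structure(list(n_cols = n_cols, n_rows = n_rows,
                 n_sites = n_cols * n_rows,
                 periodic_x = px, periodic_y = py,
                 nbr = nbr, coords = coords),
            class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("<hex_lattice %d x %d (%d sites), x: %s, y: %s>\n",
              x$n_cols, x$n_rows, x$n_sites,
              if (x$periodic_x) "periodic" else "open",
              if (x$periodic_y) "periodic" else "open"))
  invisible(x)
}

#' Neighbors of a lattice site
#'
#' Returns the neighboring site indices of `site` in the fixed cyclic order
#' E, NE, NW, W, SW, SE; absent neighbors (open boundaries) are dropped.
#'
#' @param lattice A [build_lattice()] object.
#' @param site Site index in `1..n_sites`.
#' @return Integer vector of up to 6 site indices.
#' @export
neighbors <- function(lattice, site) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (length(site) != 1L || is.na(site) || site < 1 || site > lattice$n_sites)
    stop("site off lattice")
  v <- lattice$nbr[site, ]
  v[!is.na(v)]
}

#' Hex-distance disk neighborhood
#'
#' All sites within hex graph distance `R` of `site`.  On an unbounded
#' lattice the disk contains `1 + 3 * R * (R + 1)` sites.
#'
#' @inheritParams neighbors
#' @param R Non-negative integer radius (hex graph distance).
#' @return Sorted integer vector of site indices.
#' @examples
#' lat <- build_lattice(20, 20)
#' length(disk_neighborhood(lat, 105, 5))  # 91
#' @export
disk_neighborhood <- function(lattice, site, R) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (length(R) != 1L || is.na(R) || R < 0)
    stop("disk radius must be a non-negative integer")
  hex_disk_cpp(lattice$n_cols, lattice$n_rows,
               lattice$periodic_x, lattice$periodic_y,
               as.integer(site), as.integer(R))
}

#' Would removing a site keep its cell connected?
#'
#' Tests whether the cell owning `site` remains a single 6-connected
#' component after `site` is removed.  Uses a local ring check on the cyclic
#' neighbor order, falling back to a flood fill when the local check is
#' ambiguous.
#'
#' @param lattice A [build_lattice()] object.
#' @param owner Integer vector of length `n_sites`: owning cell id per site
#'   (0 = empty).
#' @param site Site index; must be owned by a cell.
#' @return `TRUE` if the owning cell stays connected (or the site is its
#'   last one), `FALSE` if removal would fragment it.
#' @examples
#' lat <- build_lattice(10, 10)
#' owner <- integer(100); owner[c(34, 35, 36)] <- 1L   # 3-site line
#' move_preserves_connectivity(lat, owner, 35)  # FALSE (middle site)
#' move_preserves_connectivity(lat, owner, 36)  # TRUE  (tip site)
#' @export
move_preserves_connectivity <- function(lattice, owner, site) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (length(owner) != lattice$n_sites)
    stop("owner vector length must equal the number of lattice sites")
  conn_check_cpp(as.integer(owner), lattice$n_cols, lattice$n_rows,
                 lattice$periodic_x, lattice$periodic_y, as.integer(site))
}

#' Center of mass of a site set
#'
#' Mean Cartesian coordinate of a connected set of sites, unwrapped across
#' periodic images (coordinates are propagated along lattice steps through
#' the set, so sets spanning a periodic seam give a continuous result).
#'
#' @param lattice A [build_lattice()] object.
#' @param sites Non-empty integer vector of site indices forming a
#'   connected set.
#' @return Numeric length-2 vector `c(x, y)`.
#' @export
center_of_mass <- function(lattice, sites) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (length(sites) == 0L) stop("empty site set has no center of mass")
  if (length(sites) == 1L) return(unname(lattice$coords[sites, ]))
  uv <- unwrap_sites(lattice, as.integer(sites))
  c(mean(uv$x), mean(uv$y))
}

# Unwrapped Cartesian coordinates of a connected site set, propagated by
# breadth-first search along lattice direction steps from the first site.
unwrap_sites <- function(lattice, sites) {
  dxs <- c(1, 0.5, -0.5, -1, -0.5, 0.5)
  dys <- c(0, -1, -1, 0, 1, 1) * sqrt(3) / 2
  n <- length(sites)
  idx <- setNames(seq_len(n), sites)
  ux <- rep(NA_real_, n); uy <- rep(NA_real_, n)
  ux[1] <- lattice$coords[sites[1], 1]
  uy[1] <- lattice$coords[sites[1], 2]
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- lattice$nbr[sites[i], ]
    for (d in 1:6) {
      v <- nb[d]
      if (is.na(v)) next
      j <- idx[as.character(v)]
      if (!is.na(j) && is.na(ux[j])) {
        ux[j] <- ux[i] + dxs[d]
        uy[j] <- uy[i] + dys[d]
        queue <- c(queue, j)
      }
    }
  }
  if (anyNA(ux)) stop("site set is not connected")
  list(x = ux, y = uy)
}

#' Split a connected site set across its short axis
#'
#' Partitions a connected site set into two connected halves by the line
#' through the center of mass perpendicular to the gyration-tensor major
#' axis, as used for cell division.  Ties are broken toward balancing the
#' two areas; stray fragments are reassigned so both halves stay connected.
#'
#' @param lattice A [build_lattice()] object.
#' @param sites Connected integer site set with at least 2 sites.
#' @return List with sorted integer vectors `first` and `second`; disjoint,
#'   with union equal to `sites`.
#' @export
split_site_set <- function(lattice, sites) {
  stopifnot(inherits(lattice, "hex_lattice"))
  hex_split_cpp(lattice$n_cols, lattice$n_rows,
                lattice$periodic_x, lattice$periodic_y, as.integer(sites))
}
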