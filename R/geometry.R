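#' Generate parcel geometry on the unit sphere
#'
#' Draws `n_parcels` points approximately uniformly on the unit sphere and
#' computes the full great-circle (geodesic) distance matrix. The geometry
#' stands in for the cortical surface when generating spatially autocorrelated
#' maps and variogram-matched surrogate maps: all that downstream machinery
#' needs is a plausible inter-parcel distance structure.
#'
#' @param n_parcels Number of parcels (at least 3).
#' @param seed Integer seed; results are bit-reproducible for a fixed seed.
#' @return An object of class `parcel_geometry`: a list with `coordinates`
#'   (`n_parcels x 3`, unit rows) and `distance_matrix` (symmetric,
#'   zero-diagonal great-circle distances in radians, so the maximum possible
#'   distance is `pi`).
#' @examples
#' geom <- generate_geometry(50, seed = 1)
#' max(geom$distance_matrix) <= pi
#' @export
generate_geometry <- function(n_parcels, seed) {
  n_parcels <- check_scalar_int(n_parcels, "n_parcels", min = 3)
  seed <- check_scalar_int(seed, "seed")
  coords <- withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n_parcels * 3L), ncol = 3L)
    z / sqrt(rowSums(z^2))
  })
  # Great-circle distance from the chordal dot product; clamp for acos domain.
  ip <- tcrossprod(coords)
  ip[ip > 1] <- 1
  ip[ip < -1] <- -1
  d <- acos(ip)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(
    list(coordinates = coords, distance_matrix = d, n_parcels = n_parcels,
         seed = seed),
    class = "parcel_geometry"
  )
}

#' @export
print.parcel_geometry <- function(x, ...) {
  cat(sprintf("<parcel_geometry> %d parcels on the unit sphere (seed %d)\n",
              x$n_parcels, x$seed))
  cat(sprintf("  distance range: [0, %.3f] rad\n", max(x$distance_matrix)))
  invisible(x)
}

# Validate + extract the distance matrix from either a parcel_geometry or a
# bare symmetric matrix (user-supplied geometry).
geometry_distances <- function(geometry) {
  d <- if (inherits(geometry, "parcel_geometry")) geometry$distance_matrix
       else geometry
  d <- check_matrix(d, "geometry")
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0))
    stop_invalid("geometry distance matrix must be symmetric with zero diagonal")
  d
}
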