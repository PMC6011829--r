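#' Shrake-Rupley SASA sampling specification
#'
#' @param probe_radius Solvent probe radius, Angstrom (water: 1.4).
#' @param points_per_atom Size of the deterministic spherical point set used
#'   per atom (>= 12).
#' @return A list of class `sasa_spec`.
#' @export
sasa_spec <- function(probe_radius = 1.4, points_per_atom = 960L) {
  if (probe_radius < 0) stop("probe_radius must be >= 0", call. = FALSE)
  if (points_per_atom < 12) stop("points_per_atom must be >= 12", call. = FALSE)
  structure(list(probe_radius = probe_radius,
                 points_per_atom = as.integer(points_per_atom)),
            class = "sasa_spec")
}

# Deterministic quasi-uniform unit sphere point set (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's probe-inflated sphere (radius `r_i + probe`) is sampled with a
#' deterministic Fibonacci point set; a point is exposed when it lies outside
#' every other atom's inflated sphere.  Per-atom area is the exposed fraction
#' times the sphere area.
#'
#' @param system A [molecular_system()].
#' @param radii Per-atom radii, Angstrom (commonly the PB cavity radii).
#' @param spec A [sasa_spec()].
#' @return A list with `total` (A^2) and `per_atom` (tibble: `index`,
#'   `area`).
#' @export
sasa <- function(system, radii, spec = sasa_spec()) {
  stopifnot(inherits(system, "molecular_system"))
  sasa_xyz(coords(system), radii, spec,
           index = system$atoms$index)
}

sasa_xyz <- function(xyz, radii, spec = sasa_spec(), index = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  radii <- rep_len(as.numeric(radii), n)
  if (any(radii <= 0)) stop("radii must be > 0", call. = FALSE)
  pts <- fibonacci_sphere(spec$points_per_atom)
  inflated <- radii + spec$probe_radius
  # neighbor lists from pairwise distances (desk-scale systems)
  d <- cross_distances(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < inflated[i] + inflated & seq_len(n) != i)
    surf <- sweep(pts * inflated[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(surf))
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(surf[exposed, , drop = FALSE], 2, xyz[j, ])^2)
      # strictly inside sphere j buries a point; a point exactly on the
      # shared boundary of two spheres is owned by the lower-index atom so
      # coincident surfaces are counted once
      tol <- 1e-9 * inflated[j]^2
      keep <- dj2 > inflated[j]^2 - tol
      if (j < i) keep <- keep & dj2 > inflated[j]^2 + tol
      exposed[exposed] <- keep
    }
    area[i] <- 4 * pi * inflated[i]^2 * mean(exposed)
  }
  list(total = sum(area),
       per_atom = tibble::tibble(index = index %||% (seq_len(n) - 1L),
                                 area = area))
}

hostguest_sasa_spec_default <- function() sasa_spec()
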