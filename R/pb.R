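#' Poisson-Boltzmann grid specification
#'
#' Controls the finite-difference grid and dielectric model for
#' [pb_solvation_energy()]: a regular cubic-lattice grid padded around the
#' solute, a sharp two-valued dielectric map from the union of atom spheres
#' at their PB radii, and an optional linearized salt term.
#'
#' @param spacing Grid spacing h, Angstrom.
#' @param padding Minimum distance from any atom to the grid boundary,
#'   Angstrom.
#' @param eps_solute Solute (interior) dielectric constant.
#' @param eps_solvent Solvent (exterior) dielectric constant.
#' @param ionic_strength Monovalent ionic strength, mol/L (0 = pure Poisson).
#' @param tolerance Relative residual for solver convergence.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A list of class `pb_grid_spec`.
#' @export
pb_grid_spec <- function(spacing = 0.5, padding = 8, eps_solute = 1,
                         eps_solvent = 80, ionic_strength = 0,
                         tolerance = 1e-6, max_iter = 20000L) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (!(eps_solvent >= eps_solute && eps_solute >= 1)) {
    stop("need eps_solvent >= eps_solute >= 1", call. = FALSE)
  }
  if (ionic_strength < 0) stop("ionic_strength must be >= 0", call. = FALSE)
  structure(list(spacing = spacing, padding = padding,
                 eps_solute = eps_solute, eps_solvent = eps_solvent,
                 ionic_strength = ionic_strength, tolerance = tolerance,
                 max_iter = as.integer(max_iter)),
            class = "pb_grid_spec")
}

#' Polar solvation energy by finite-difference linearized Poisson-Boltzmann
#'
#' Solves `div(eps grad phi) - eps_s kappa^2 phi = -4 pi k_e rho` on a
#' regular grid with trilinear charge spreading, face dielectrics sampled at
#' face midpoints of a sharp two-valued map (union of atom spheres at their
#' PB radii), and Dirichlet boundary values from Debye-Hueckel monopole
#' sums.  The polar solvation energy is `1/2 sum q_i phi(x_i)` in the
#' solvated dielectric minus the same quantity with the solute dielectric
#' everywhere, computed on the identical grid so the discrete self-energy
#' cancels.
#'
#' @param system A [molecular_system()].
#' @param params An [ff_parameters()] table supplying `charge` and
#'   `pb_radius`.
#' @param grid A [pb_grid_spec()].
#' @return Polar solvation energy, kcal/mol.
#' @export
pb_solvation_energy <- function(system, params, grid = pb_grid_spec()) {
  stopifnot(inherits(system, "molecular_system"))
  params <- ff_parameters(params, n_atoms = n_atoms(system))
  pb_solvation_energy_xyz(coords(system), params$charge, params$pb_radius,
                          grid)
}

pb_solvation_energy_xyz <- function(xyz, charges, radii, grid) {
  xyz <- as.matrix(xyz)
  if (all(charges == 0)) return(0)
  if (grid$eps_solvent == grid$eps_solute) return(0)

  h <- grid$spacing
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  center <- (lo + hi) / 2
  half <- (hi - lo) / 2 + grid$padding
  m <- pmax(ceiling(half / h), 4)            # nodes per half-axis
  dims <- 2L * as.integer(m) + 1L
  origin <- center - m * h
  ax <- lapply(1:3, function(d) origin[d] + h * (seq_len(dims[d]) - 1))

  # Debye screening: kappa_bar^2 in e^2-units so that the solvent-region
  # diagonal term is kappa_bar^2 * h^2 (the eps is folded in here)
  kT <- .const$R_kcal * 298.15
  kap2 <- 8 * pi * .const$coulomb_k *
    (grid$ionic_strength * .const$avogadro / 1e27) / kT

  phi_solv <- pb_solve_grid(xyz, charges, radii, grid, ax, dims, h,
                            eps_out = grid$eps_solvent, kap2 = kap2)
  phi_ref <- pb_solve_grid(xyz, charges, radii, grid, ax, dims, h,
                           eps_out = grid$eps_solute, kap2 = 0)
  0.5 * sum(charges * (interp_phi(phi_solv, ax, dims, xyz) -
                       interp_phi(phi_ref, ax, dims, xyz)))
}

# Solve one dielectric configuration; returns flattened phi.
pb_solve_grid <- function(xyz, charges, radii, grid, ax, dims, h,
                          eps_out, kap2) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ntot <- nx * ny * nz
  eps_in <- grid$eps_solute

  inside_union <- function(px, py, pz) {
    ins <- rep(FALSE, length(px))
    for (a in seq_len(nrow(xyz))) {
      r2 <- (px - xyz[a, 1])^2 + (py - xyz[a, 2])^2 + (pz - xyz[a, 3])^2
      ins <- ins | r2 < radii[a]^2
    }
    ins
  }

  face_eps <- function(dir, n_samples = 5L) {
    # Harmonic average of the two-valued dielectric along each grid edge:
    # the edge is sampled at n_samples interior points, the inside-solute
    # fraction f gives eps = 1 / (f/eps_in + (1-f)/eps_out).  This is the
    # usual boundary smoothing that restores smooth grid convergence for a
    # sharp union-of-spheres cavity.  Full-size array; last slab unused.
    if (eps_out == eps_in) return(rep(eps_in, ntot))
    gx <- rep(ax[[1]], times = ny * nz)
    gy <- rep(rep(ax[[2]], each = nx), times = nz)
    gz <- rep(ax[[3]], each = nx * ny)
    frac <- rep(0, ntot)
    for (s in seq_len(n_samples)) {
      t <- (s - 0.5) / n_samples * h
      frac <- frac + inside_union(gx + if (dir == 1) t else 0,
                                  gy + if (dir == 2) t else 0,
                                  gz + if (dir == 3) t else 0)
    }
    frac <- frac / n_samples
    1 / (frac / eps_in + (1 - frac) / eps_out)
  }
  epsx <- face_eps(1); epsy <- face_eps(2); epsz <- face_eps(3)

  # solvent-region salt term on nodes
  kap2h2 <- rep(0, ntot)
  if (kap2 > 0) {
    gx <- rep(ax[[1]], times = ny * nz)
    gy <- rep(rep(ax[[2]], each = nx), times = nz)
    gz <- rep(ax[[3]], each = nx * ny)
    kap2h2 <- ifelse(inside_union(gx, gy, gz), 0, kap2 * h^2)
  }

  # trilinear charge spreading -> rhs = 4 pi k_e q_node / h
  qgrid <- rep(0, ntot)
  for (a in seq_len(nrow(xyz))) {
    fx <- (xyz[a, 1] - ax[[1]][1]) / h
    fy <- (xyz[a, 2] - ax[[2]][1]) / h
    fz <- (xyz[a, 3] - ax[[3]][1]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
           (if (dk) wz else 1 - wz)
      if (w == 0) next
      n <- (i0 + di) + nx * ((j0 + dj) + ny * (k0 + dk)) + 1
      qgrid[n] <- qgrid[n] + w * charges[a]
    }
  }
  rhs <- 4 * pi * .const$coulomb_k * qgrid / h

  # Dirichlet boundary: screened monopole sum in the exterior dielectric
  phi <- rep(0, ntot)
  kap_eff <- if (kap2 > 0) sqrt(kap2 / eps_out) else 0
  bidx <- boundary_indices(nx, ny, nz)
  bx <- ((bidx - 1) %% nx) + 1
  by <- (((bidx - 1) %/% nx) %% ny) + 1
  bz <- ((bidx - 1) %/% (nx * ny)) + 1
  px <- ax[[1]][bx]; py <- ax[[2]][by]; pz <- ax[[3]][bz]
  vb <- rep(0, length(bidx))
  for (a in seq_len(nrow(xyz))) {
    r <- sqrt((px - xyz[a, 1])^2 + (py - xyz[a, 2])^2 + (pz - xyz[a, 3])^2)
    r <- pmax(r, 1e-6)
    scr <- if (kap_eff > 0) exp(-kap_eff * r) else 1
    vb <- vb + .const$coulomb_k * charges[a] * scr / (eps_out * r)
  }
  phi[bidx] <- vb

  omega <- 2 / (1 + pi / max(nx, ny, nz))   # near-optimal SOR factor
  out <- pb_sor_solve(phi, epsx, epsy, epsz, kap2h2, rhs,
                      nx, ny, nz, omega, grid$tolerance, grid$max_iter, 25L)
  if (!out$converged) {
    stop(sprintf(
      "PB solver did not converge in %d iterations (relative residual %.3g)",
      grid$max_iter, out$residual), call. = FALSE)
  }
  phi
}

boundary_indices <- function(nx, ny, nz) {
  i <- rep(seq_len(nx), times = ny * nz)
  j <- rep(rep(seq_len(ny), each = nx), times = nz)
  k <- rep(seq_len(nz), each = nx * ny)
  which(i == 1 | i == nx | j == 1 | j == ny | k == 1 | k == nz)
}

interp_phi <- function(phi, ax, dims, xyz) {
  nx <- dims[1]; ny <- dims[2]
  h <- ax[[1]][2] - ax[[1]][1]
  vapply(seq_len(nrow(xyz)), function(a) {
    fx <- (xyz[a, 1] - ax[[1]][1]) / h
    fy <- (xyz[a, 2] - ax[[2]][1]) / h
    fz <- (xyz[a, 3] - ax[[3]][1]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
    v <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
           (if (dk) wz else 1 - wz)
      if (w == 0) next
      n <- (i0 + di) + nx * ((j0 + dj) + ny * (k0 + dk)) + 1
      v <- v + w * phi[n]
    }
    v
  }, numeric(1))
}
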