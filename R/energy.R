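# Pairwise molecular-mechanics interaction terms and the MM-PBSA style
# interaction-enthalpy decomposition.

cross_distances <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Inter-set Coulomb energy
#'
#' Sum over all pairs (one atom from each set) of `k q_i q_j / r_ij` with the
#' Amber electrostatic constant k = 332.0637 kcal A / (mol e^2).
#'
#' @param coords_a,coords_b `n x 3` coordinate matrices, Angstrom (disjoint
#'   atom sets).
#' @param charges_a,charges_b Partial charges, e.
#' @return Energy in kcal/mol.
#' @examples
#' coulomb_energy(rbind(c(0, 0, 0)), 1, rbind(c(1, 0, 0)), 1)  # 332.0637
#' @export
coulomb_energy <- function(coords_a, charges_a, coords_b, charges_b) {
  r <- cross_distances(coords_a, coords_b)
  if (any(r < 1e-12)) {
    stop("coincident atoms across the two sets (r = 0)", call. = FALSE)
  }
  .const$coulomb_k * sum(outer(charges_a, charges_b) / r)
}

#' Inter-set Lennard-Jones energy
#'
#' 12-6 form `eps [ (rmin/r)^12 - 2 (rmin/r)^6 ]` per pair, with
#' Lorentz-Berthelot combination `rmin = rmin_half_i + rmin_half_j`,
#' `eps = sqrt(eps_i eps_j)`.  No cutoff: systems here are finite.
#'
#' @param coords_a,coords_b `n x 3` coordinate matrices, Angstrom.
#' @param params_a,params_b Data frames with columns `epsilon` (kcal/mol) and
#'   `rmin_half` (Angstrom), one row per atom of the corresponding set.
#' @return Energy in kcal/mol.
#' @export
lennard_jones_energy <- function(coords_a, params_a, coords_b, params_b) {
  r <- cross_distances(coords_a, coords_b)
  if (any(r < 1e-12)) {
    stop("coincident atoms across the two sets (r = 0)", call. = FALSE)
  }
  eps <- sqrt(outer(params_a$epsilon, params_b$epsilon))
  rmin <- outer(params_a$rmin_half, params_b$rmin_half, "+")
  sr6 <- (rmin / r)^6
  sum(eps * (sr6^2 - 2 * sr6))
}

#' Nonpolar (cavity) solvation energy from a SASA change
#'
#' Linear surface-area model `gamma * delta_sasa + b`, the SA half of PB/SA.
#'
#' @param delta_sasa Change in solvent-accessible surface area, A^2.
#' @param gamma Surface tension coefficient, kcal/(mol A^2).
#' @param b Offset, kcal/mol.
#' @return Energy in kcal/mol.
#' @export
nonpolar_energy <- function(delta_sasa, gamma = 0.0072, b = 0) {
  gamma * delta_sasa + b
}

#' Construct an interaction-energy decomposition
#'
#' Container for the MM-PBSA style components: molecular-mechanics Coulomb
#' and van der Waals terms, polar (PB) and nonpolar (SA) solvation, plus an
#' optional valence term.  The total enthalpy is their sum by construction.
#'
#' @param e_coulomb,e_pb,e_np,e_vdw,e_valence Components, kcal/mol.
#' @param label Optional complex label.
#' @return An object of class `energy_decomposition`.
#' @export
energy_decomposition <- function(e_coulomb, e_pb, e_np, e_vdw, e_valence = 0,
                                 label = "") {
  structure(list(
    label = label,
    e_valence = e_valence, e_coulomb = e_coulomb, e_pb = e_pb,
    e_np = e_np, e_vdw = e_vdw,
    total_enthalpy = e_valence + e_coulomb + e_pb + e_np + e_vdw
  ), class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat("<energy_decomposition>", x$label, "\n")
  print(tidy.energy_decomposition(x))
  invisible(x)
}

#' @rdname energy_decomposition
#' @param x An `energy_decomposition`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per component (term, energy).
#' @export
tidy.energy_decomposition <- function(x, ...) {
  tibble::tibble(
    term = c("e_valence", "e_coulomb", "e_pb", "e_np", "e_vdw",
             "total_enthalpy"),
    energy = c(x$e_valence, x$e_coulomb, x$e_pb, x$e_np, x$e_vdw,
               x$total_enthalpy)
  )
}

#' @rdname energy_decomposition
#' @return `glance()`: a one-row tibble of all components.
#' @export
glance.energy_decomposition <- function(x, ...) {
  tibble::tibble(label = x$label, e_valence = x$e_valence,
                 e_coulomb = x$e_coulomb, e_pb = x$e_pb, e_np = x$e_np,
                 e_vdw = x$e_vdw, total_enthalpy = x$total_enthalpy)
}

#' MM-PBSA interaction-enthalpy decomposition of a complex
#'
#' Single-trajectory convention: receptor and ligand geometries are cut from
#' the complex frame without relaxation.  The interaction enthalpy is
#' `dE_Coulomb + dE_PB + dE_NP + dE_VDW` where the MM terms are inter-set
#' pairwise sums, `dE_PB = PB(complex) - PB(receptor) - PB(ligand)` on
#' identical grid spacing, and `dE_NP = gamma * [SASA(complex) -
#' SASA(receptor) - SASA(ligand)]`.
#'
#' @param complex_system A [molecular_system()] holding the whole complex.
#' @param receptor_selection,ligand_selection Disjoint atom index sets that
#'   together cover the complex.
#' @param params An [ff_parameters()] table for the complex.
#' @param grid A [pb_grid_spec()].
#' @param sasa_spec A [sasa_spec()]; default settings when `NULL`.
#' @param gamma,b Nonpolar model coefficients (kcal/(mol A^2), kcal/mol).
#' @param frame Optional coordinate matrix overriding the system coordinates.
#' @return An [energy_decomposition()].
#' @export
mmpbsa_decompose <- function(complex_system, receptor_selection,
                             ligand_selection, params,
                             grid = pb_grid_spec(), sasa_spec = NULL,
                             gamma = 0.0072, b = 0, frame = NULL) {
  if (is.null(sasa_spec)) sasa_spec <- hostguest_sasa_spec_default()
  stopifnot(inherits(complex_system, "molecular_system"))
  n <- n_atoms(complex_system)
  params <- ff_parameters(params, n_atoms = n)
  rr <- sel_rows(n, receptor_selection, "receptor_selection")
  lr <- sel_rows(n, ligand_selection, "ligand_selection")
  if (length(intersect(rr, lr))) {
    stop("receptor and ligand selections overlap", call. = FALSE)
  }
  if (length(rr) + length(lr) != n) {
    stop("selections must partition the complex (", n, " atoms; got ",
         length(rr), " + ", length(lr), ")", call. = FALSE)
  }
  xyz <- if (is.null(frame)) coords(complex_system) else as.matrix(frame)
  pr <- params[rr, ]; pl <- params[lr, ]
  xr <- xyz[rr, , drop = FALSE]; xl <- xyz[lr, , drop = FALSE]

  e_coul <- coulomb_energy(xr, pr$charge, xl, pl$charge)
  e_vdw <- lennard_jones_energy(xr, pr, xl, pl)

  pb_part <- function(x, p) {
    pb_solvation_energy_xyz(x, p$charge, p$pb_radius, grid)
  }
  e_pb <- pb_part(xyz, params) - pb_part(xr, pr) - pb_part(xl, pl)

  sasa_part <- function(x, p) sasa_xyz(x, p$pb_radius, sasa_spec)$total
  d_sasa <- sasa_part(xyz, params) - sasa_part(xr, pr) - sasa_part(xl, pl)
  e_np <- nonpolar_energy(d_sasa, gamma = gamma, b = b)

  energy_decomposition(e_coulomb = e_coul, e_pb = e_pb, e_np = e_np,
                       e_vdw = e_vdw, label = complex_system$title)
}

#' Trajectory-averaged MM-PBSA decomposition
#'
#' Runs [mmpbsa_decompose()] on every frame (or a stride of frames) and
#' averages each component.
#'
#' @inheritParams mmpbsa_decompose
#' @param traj A [trajectory()].
#' @param stride Analyze every `stride`-th frame.
#' @return A tibble with per-component `mean` and `sd` over analyzed frames.
#' @export
mmpbsa_profile <- function(traj, receptor_selection, ligand_selection, params,
                           grid = pb_grid_spec(), sasa_spec = NULL,
                           gamma = 0.0072, b = 0, stride = 1L) {
  if (is.null(sasa_spec)) sasa_spec <- hostguest_sasa_spec_default()
  stopifnot(inherits(traj, "trajectory"))
  idx <- seq(1L, n_frames(traj), by = stride)
  purrr::map_dfr(idx, function(i) {
    dec <- mmpbsa_decompose(traj$topology, receptor_selection,
                            ligand_selection, params, grid, sasa_spec,
                            gamma, b, frame = traj$frames[[i]])
    dplyr::mutate(glance.energy_decomposition(dec), frame = i)
  }) |>
    tidyr::pivot_longer(c("e_valence", "e_coulomb", "e_pb", "e_np", "e_vdw",
                          "total_enthalpy"),
                        names_to = "term", values_to = "energy") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(mean = mean(.data$energy), sd = stats::sd(.data$energy),
                     n_frames = dplyr::n(), .groups = "drop")
}
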