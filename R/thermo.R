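#' Thermodynamic conditions
#'
#' @param temperature Temperature, K.
#' @param pressure Pressure, atm (ideal-gas standard state).
#' @return A list of class `thermo_conditions`.
#' @export
thermo_conditions <- function(temperature = 298.15, pressure = 1) {
  if (temperature <= 0 || pressure <= 0) {
    stop("temperature and pressure must be > 0", call. = FALSE)
  }
  structure(list(temperature = temperature, pressure = pressure),
            class = "thermo_conditions")
}

# Principal moments of inertia in amu A^2, sorted ascending.
principal_moments <- function(masses, coords) {
  com <- colSums(coords * masses) / sum(masses)
  x <- sweep(coords, 2, com)
  Ixx <- sum(masses * (x[, 2]^2 + x[, 3]^2))
  Iyy <- sum(masses * (x[, 1]^2 + x[, 3]^2))
  Izz <- sum(masses * (x[, 1]^2 + x[, 2]^2))
  Ixy <- -sum(masses * x[, 1] * x[, 2])
  Ixz <- -sum(masses * x[, 1] * x[, 3])
  Iyz <- -sum(masses * x[, 2] * x[, 3])
  Imat <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
  sort(eigen(Imat, symmetric = TRUE, only.values = TRUE)$values)
}

#' Rigid-rotor/harmonic-oscillator thermochemistry of one structure
#'
#' Ideal-gas statistical thermodynamics from a frequency dataset:
#' translational partition function at the stated pressure (Sackur-Tetrode
#' entropy), classical rigid-rotor rotation with the external symmetry
#' number (linear or nonlinear detected from the principal moments of
#' inertia), harmonic vibrations over the real positive modes with the
#' zero-point energy kept separate (bottom-of-well reference), and an
#' electronic term equal to the spin multiplicity.  The imaginary mode of a
#' transition state is excluded from all thermal functions.  The enthalpy is
#' `E_elec + ZPE + E_thermal + RT` and `G = H - T S` by construction.
#'
#' @param state A [frequency_dataset()].
#' @param cond A [thermo_conditions()].
#' @return A list of class `thermo_result` with partition functions
#'   (`q_trans`, `q_rot`, `q_vib`, `q_elec`), `zpe` (kcal/mol), entropy
#'   components and `s_total` (cal/(mol K)), `h_total` and `g_total`
#'   (kcal/mol), and the conditions.
#' @examples
#' ar <- frequency_dataset(0, 39.948, matrix(0, 1, 3), numeric())
#' thermo_result(ar)$s_total  # Sackur-Tetrode: 36.98 cal/(mol K)
#' @export
thermo_result <- function(state, cond = thermo_conditions()) {
  stopifnot(inherits(state, "frequency_dataset"),
            inherits(cond, "thermo_conditions"))
  T <- cond$temperature
  P <- cond$pressure * .const$atm_pa
  kB <- .const$boltzmann; h <- .const$planck
  R_cal <- .const$R_cal; R_kcal <- .const$R_kcal
  n <- length(state$masses)

  # translation (Sackur-Tetrode at stated P)
  M <- sum(state$masses) * .const$amu_kg
  q_trans <- (2 * pi * M * kB * T / h^2)^1.5 * (kB * T / P)
  s_trans <- R_cal * (log(q_trans) + 1 + 1.5)
  e_trans <- 1.5 * R_kcal * T

  # rotation
  mom <- principal_moments(state$masses, state$coords)  # amu A^2
  mom_si <- mom * .const$amu_kg * 1e-20                 # kg m^2
  linear <- n > 1 && mom[1] < 1e-6 * max(mom, 1e-12)
  sigma <- state$symmetry_number
  if (n == 1) {
    q_rot <- 1; s_rot <- 0; e_rot <- 0
  } else if (linear) {
    theta <- h^2 / (8 * pi^2 * mom_si[3] * kB)
    q_rot <- T / (sigma * theta)
    s_rot <- R_cal * (log(q_rot) + 1)
    e_rot <- R_kcal * T
  } else {
    theta <- h^2 / (8 * pi^2 * mom_si * kB)
    q_rot <- sqrt(pi) / sigma * sqrt(T^3 / prod(theta))
    s_rot <- R_cal * (log(q_rot) + 1.5)
    e_rot <- 1.5 * R_kcal * T
  }

  # vibrations: real positive modes only (TS imaginary mode dropped)
  freqs <- state$frequencies[state$frequencies > 0]
  n_expected <- if (n == 1) 0L else if (linear) 3L * n - 5L else 3L * n - 6L
  n_real_expected <- n_expected - as.integer(state$is_transition_state)
  if (length(freqs) < n_real_expected) {
    stop("expected ", n_real_expected, " real modes for this ",
         if (state$is_transition_state) "transition state" else "minimum",
         "; found ", length(freqs), call. = FALSE)
  }
  x <- h * .const$c_cm * freqs / (kB * T)
  q_vib <- prod(1 / (1 - exp(-x)))
  s_vib <- R_cal * sum(x / (exp(x) - 1) - log(1 - exp(-x)))
  e_vib <- R_kcal * T * sum(x / (exp(x) - 1))
  zpe <- sum(h * .const$c_cm * freqs / 2) * .const$avogadro /
    (.const$cal_joule * 1000)

  # electronic
  q_elec <- state$multiplicity
  s_elec <- R_cal * log(q_elec)

  s_total <- s_trans + s_rot + s_vib + s_elec
  h_total <- state$electronic_energy + zpe + e_trans + e_rot + e_vib +
    R_kcal * T
  g_total <- h_total - T * s_total / 1000

  structure(list(
    title = state$title,
    q_trans = q_trans, q_rot = q_rot, q_vib = q_vib, q_elec = q_elec,
    zpe = zpe,
    s_trans = s_trans, s_rot = s_rot, s_vib = s_vib, s_elec = s_elec,
    s_total = s_total,
    e_thermal = e_trans + e_rot + e_vib,
    h_total = h_total, g_total = g_total,
    temperature = T, pressure = cond$pressure,
    n_modes = length(freqs), linear = linear,
    is_transition_state = state$is_transition_state
  ), class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("<thermo_result>", x$title,
      if (x$is_transition_state) "(transition state)", "\n")
  cat(sprintf("  T = %.2f K, P = %g atm, %d modes%s\n", x$temperature,
              x$pressure, x$n_modes, if (x$linear) " (linear)" else ""))
  cat(sprintf("  S = %.2f cal/(mol K), H = %.2f kcal/mol, G = %.2f kcal/mol\n",
              x$s_total, x$h_total, x$g_total))
  invisible(x)
}

#' @rdname thermo_result
#' @param x A `thermo_result`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per entropy/partition component.
#' @export
tidy.thermo_result <- function(x, ...) {
  tibble::tibble(
    component = c("translational", "rotational", "vibrational", "electronic"),
    q = c(x$q_trans, x$q_rot, x$q_vib, x$q_elec),
    entropy = c(x$s_trans, x$s_rot, x$s_vib, x$s_elec)
  )
}

#' @rdname thermo_result
#' @return `glance()`: a one-row tibble with S, H, G, ZPE and conditions.
#' @export
glance.thermo_result <- function(x, ...) {
  tibble::tibble(title = x$title, s_total = x$s_total, zpe = x$zpe,
                 h_total = x$h_total, g_total = x$g_total,
                 temperature = x$temperature, pressure = x$pressure)
}

#' Activation free-energy decomposition
#'
#' Differences transition-state minus reactant reference:
#' `dG = G(TS) - sum G(reactants)`, likewise for H, with the entropic part
#' reported as `-T dS = dG - dH`.  The reactant reference may be one bound
#' supermolecule (pre-reactive complex) or several separated species; which
#' one was used is recorded in the result.
#'
#' @param reactants A [thermo_result()] or list of them (summed).
#' @param ts The transition-state [thermo_result()].
#' @return A list of class `activation_decomposition` with `delta_g`,
#'   `delta_h`, `minus_t_delta_s` (kcal/mol) and `reference`
#'   (`"supermolecule"` or `"separated"`).
#' @export
activation_decomposition <- function(reactants, ts) {
  stopifnot(inherits(ts, "thermo_result"))
  if (inherits(reactants, "thermo_result")) reactants <- list(reactants)
  stopifnot(all(vapply(reactants, inherits, TRUE, "thermo_result")))
  temps <- vapply(reactants, `[[`, 1, "temperature")
  if (any(abs(temps - ts$temperature) > 1e-9)) {
    stop("reactants and transition state evaluated at different temperatures",
         call. = FALSE)
  }
  delta_g <- ts$g_total - sum(vapply(reactants, `[[`, 1, "g_total"))
  delta_h <- ts$h_total - sum(vapply(reactants, `[[`, 1, "h_total"))
  structure(list(
    delta_g = delta_g, delta_h = delta_h,
    minus_t_delta_s = delta_g - delta_h,
    temperature = ts$temperature,
    reference = if (length(reactants) == 1L) "supermolecule" else "separated"
  ), class = "activation_decomposition")
}

#' @export
print.activation_decomposition <- function(x, ...) {
  cat(sprintf(
    "<activation_decomposition> dG = %.2f, dH = %.2f, -TdS = %.2f kcal/mol (%s reference)\n",
    x$delta_g, x$delta_h, x$minus_t_delta_s, x$reference))
  invisible(x)
}

#' @rdname activation_decomposition
#' @param x An `activation_decomposition`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble of the three components.
#' @export
glance.activation_decomposition <- function(x, ...) {
  tibble::tibble(delta_g = x$delta_g, delta_h = x$delta_h,
                 minus_t_delta_s = x$minus_t_delta_s,
                 temperature = x$temperature, reference = x$reference)
}

#' Check the free-energy identity dG = dH + (-T dS) on a table
#'
#' Computes the per-row residual `delta_g - (delta_h + minus_t_delta_s)` and
#' flags rows exceeding the tolerance (default 0.015 kcal/mol, the allowance
#' for values printed to 0.01).
#'
#' @param table Data frame with columns `delta_g`, `delta_h`,
#'   `minus_t_delta_s` (kcal/mol).
#' @param tolerance Flagging threshold, kcal/mol.
#' @return The input tibble with `residual` and `flagged` columns appended.
#' @export
check_free_energy_identity <- function(table, tolerance = 0.015) {
  table <- tibble::as_tibble(table)
  need <- c("delta_g", "delta_h", "minus_t_delta_s")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(
    table,
    residual = .data$delta_g - (.data$delta_h + .data$minus_t_delta_s),
    flagged = abs(.data$residual) > tolerance
  )
}
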