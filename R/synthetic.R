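# Synthetic-data generators: a toy truncated-cone host, guest templates,
# stochastic binding trajectories with known ground truth, and fixtures with
# closed-form thermodynamics/electrostatics for oracle tests.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a toy truncated-cone host
#'
#' Two stacked rings of pseudo-atoms mimic the macrocycle: a narrow rim of
#' `n_units` carbons at `-height/2` and a wide rim of `n_units` hydroxyl
#' oxygens at `+height/2`, each oxygen carrying one donor hydrogen pointing
#' outward.  Deterministic geometry; by construction the host frame has its
#' center at the origin and its axis along +z.
#'
#' @param n_units Ring size (>= 3; default 7, mirroring the heptameric
#'   macrocycle).
#' @param narrow_radius,wide_radius Rim radii, Angstrom.
#' @param height Rim-to-rim distance, Angstrom.
#' @return A list with `system` ([molecular_system()]), and selections
#'   `host`, `rim_narrow`, `rim_wide` (atom indices), `donors` (two-column
#'   matrix of O,H indices).
#' @export
build_toy_host <- function(n_units = 7L, narrow_radius = 3.0,
                           wide_radius = 4.5, height = 6.0) {
  if (n_units < 3L) stop("n_units must be >= 3", call. = FALSE)
  if (narrow_radius <= 0 || wide_radius <= 0 || height <= 0) {
    stop("radii and height must be positive", call. = FALSE)
  }
  ang <- 2 * pi * (seq_len(n_units) - 1) / n_units
  narrow <- cbind(narrow_radius * cos(ang), narrow_radius * sin(ang),
                  -height / 2)
  wide <- cbind(wide_radius * cos(ang), wide_radius * sin(ang), height / 2)
  hyd <- cbind((wide_radius + 0.96) * cos(ang),
               (wide_radius + 0.96) * sin(ang), height / 2)
  atoms <- tibble::tibble(
    element = c(rep("C", n_units), rep("O", n_units), rep("H", n_units)),
    name = c(sprintf("C%d", seq_len(n_units)),
             sprintf("O%d", seq_len(n_units)),
             sprintf("HO%d", seq_len(n_units))),
    residue_id = 1L,
    x = c(narrow[, 1], wide[, 1], hyd[, 1]),
    y = c(narrow[, 2], wide[, 2], hyd[, 2]),
    z = c(narrow[, 3], wide[, 3], hyd[, 3])
  )
  list(
    system = molecular_system(atoms, title = "toy truncated-cone host"),
    host = 0:(3L * n_units - 1L),
    rim_narrow = 0:(n_units - 1L),
    rim_wide = n_units:(2L * n_units - 1L),
    donors = cbind(n_units:(2L * n_units - 1L),
                   (2L * n_units):(3L * n_units - 1L))
  )
}

#' Parameters of a synthetic trajectory
#'
#' Defaults mirror one coherent study arm (the plain beta-cyclodextrin
#' system): 3000 frames spanning 300 ns (100 ps spacing), an H-bond
#' formation probability of 0.041 per frame, a whole-guest depth of
#' 1.44 +/- 0.70 Angstrom along the cavity axis, and two-state ternary
#' kinetics with stationary occupancy k_on/(k_on + k_off) = 0.081 and a
#' 5-ns mean bound dwell (complexes shorter-lived than 10 ns).  The
#' methylated-host arm is the same generator at p_hbond = 0.0067,
#' depth 2.05 +/- 0.73, k_on = 0.0268, k_off = 0.05 (occupancy 0.349,
#' dwells up to tens of ns).
#'
#' @param n_frames Number of frames.
#' @param frame_interval Frame spacing, ps.
#' @param p_hbond Per-frame probability that the guest acceptor is placed in
#'   H-bond geometry.
#' @param depth_mean,depth_sd Normal law of the imposed whole-guest depth,
#'   Angstrom.
#' @param k_on,k_off Two-state binding rates of the second guest, 1/ns.
#' @param noise_sd Coordinate jitter applied to host and bound second-guest
#'   atoms, Angstrom.
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   trajectories.
#' @return A list of class `synthetic_trajectory_params`.
#' @export
synthetic_trajectory_params <- function(n_frames = 3000L,
                                        frame_interval = 100,
                                        p_hbond = 0.041,
                                        depth_mean = 1.44, depth_sd = 0.70,
                                        k_on = 0.0176, k_off = 0.2,
                                        noise_sd = 0.1, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0 ps", call. = FALSE)
  if (p_hbond < 0 || p_hbond > 1) stop("p_hbond must be in [0,1]", call. = FALSE)
  if (k_on < 0 || k_off < 0) stop("rates must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, p_hbond = p_hbond,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 k_on = k_on, k_off = k_off, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_trajectory_params")
}

# Guest templates: offsets from the guest centroid, Angstrom.
# Primary guest (maleimide-like): two "cyclohexyl" carbons 1.47 below the
# centroid, a linker carbon, and an "imide" N plus carbonyl-O acceptor whose
# centroid sits 1.91 above -- so that with the whole-guest depth at its
# imposed value d1, the moiety depths fall at d1 - 1.47 and d1 + 1.91,
# mirroring the published MD averages (1.44, -0.03, 3.35).
# Second guest (anthracene-like): a rigid 3-atom triangle.
guest_templates <- function() {
  list(
    guest_a = list(
      elements = c("C", "C", "C", "N", "O"),
      offsets = rbind(c(0.4, 0, -1.47), c(-0.4, 0, -1.47),
                      c(0, 0.3, -0.88),
                      c(0, 0, 1.71), c(0, 0, 2.11)),
      cyclohexyl = 1:2, imide = 4:5, acceptor = 5L
    ),
    guest_b = list(
      elements = c("C", "C", "C"),
      offsets = rbind(c(0.7, 0, 0), c(-0.7, 0, 0), c(0, 0.9, 0))
    )
  )
}

#' Simulate a stochastic host-guest binding trajectory with ground truth
#'
#' Emulates the statistical structure of a long explicit-solvent run at desk
#' scale.  Per frame: the primary guest's whole-body depth along the host
#' axis is drawn from `Normal(depth_mean, depth_sd)`; with probability
#' `p_hbond` its carbonyl acceptor is placed exactly in H-bond geometry
#' (1.9 Angstrom from a donor hydrogen, 10 degrees from linearity),
#' otherwise it stays on axis, out of reach of every donor; the second guest
#' hops between bound (in-cavity) and unbound (>= 10 Angstrom displaced)
#' states as a two-state Markov chain with per-frame transition
#' probabilities `1 - exp(-k dt)`, started from the chain's stationary
#' distribution `k_on / (k_on + k_off)`.  Host and bound
#' second-guest atoms get Gaussian jitter of `noise_sd`; the primary guest
#' is placed exactly so detection tests decouple from jitter.
#'
#' @param host A host bundle from [build_toy_host()].
#' @param params A [synthetic_trajectory_params()].
#' @param guests Guest templates (see `hostguest:::guest_templates`).
#' @return A list with `trajectory` ([trajectory()]), `ground_truth` (tibble:
#'   `frame`, `hbond`, `bound`, `depth`), `reference` (frame-1-like bound
#'   reference coordinates), and `selections` (host/rims/donors/acceptors,
#'   guest index sets for depth and RMSD analyses).
#' @export
simulate_binding_trajectory <- function(host = build_toy_host(),
                                        params = synthetic_trajectory_params(),
                                        guests = guest_templates()) {
  stopifnot(inherits(params, "synthetic_trajectory_params"))
  sys <- host$system
  n_host <- n_atoms(sys)
  ga <- guests$guest_a
  gb <- guests$guest_b
  na_ <- nrow(ga$offsets)
  nb_ <- nrow(gb$offsets)

  atoms <- dplyr::bind_rows(
    sys$atoms[, c("element", "name", "residue_id", "x", "y", "z")],
    tibble::tibble(element = ga$elements,
                   name = paste0("A", seq_len(na_)), residue_id = 2L,
                   x = ga$offsets[, 1], y = ga$offsets[, 2],
                   z = ga$offsets[, 3]),
    tibble::tibble(element = gb$elements,
                   name = paste0("B", seq_len(nb_)), residue_id = 3L,
                   x = gb$offsets[, 1], y = gb$offsets[, 2],
                   z = gb$offsets[, 3])
  )
  topo <- molecular_system(atoms, title = "synthetic host-guest complex")

  ax0 <- host_frame(sys, host$host, host$rim_narrow, host$rim_wide)
  center <- ax0$center; axis <- ax0$axis
  host_xyz <- coords(sys)
  donor_o <- host$donors[1, 1] + 1L   # rows in host coordinates
  donor_h <- host$donors[1, 2] + 1L

  ga_rows <- n_host + seq_len(na_)
  gb_rows <- n_host + na_ + seq_len(nb_)
  bound_centroid <- center + 0.5 * axis            # in-cavity second guest
  unbound_centroid <- center + 15 * axis           # >= 10 A displaced

  p_off <- 1 - exp(-params$k_off * params$frame_interval / 1000)
  p_on <- 1 - exp(-params$k_on * params$frame_interval / 1000)

  nfr <- params$n_frames
  gt_hbond <- logical(nfr); gt_bound <- logical(nfr); gt_depth <- numeric(nfr)
  frames <- vector("list", nfr)

  # initial residence state drawn from the chain's stationary distribution
  # (k_off = 0 gives P(bound) = 1, so an absorbing bound state starts bound)
  p_stationary <- if (params$k_on + params$k_off > 0) {
    params$k_on / (params$k_on + params$k_off)
  } else 1

  with_seed(params$seed, {
    bound <- stats::runif(1) < p_stationary
    for (f in seq_len(nfr)) {
      fr <- matrix(0.0, n_host + na_ + nb_, 3)
      # host with jitter
      hx <- host_xyz +
        matrix(stats::rnorm(3 * n_host, 0, params$noise_sd), n_host, 3)
      fr[seq_len(n_host), ] <- hx

      # primary guest: imposed depth, optional exact H-bond geometry
      depth <- stats::rnorm(1, params$depth_mean, params$depth_sd)
      hbond <- stats::runif(1) < params$p_hbond
      gxyz <- sweep(ga$offsets, 2, center + depth * axis, "+")
      if (hbond) {
        xh <- hx[donor_h, ] - hx[donor_o, ]          # O -> H direction
        xh <- xh / sqrt(sum(xh^2))
        # in-plane perpendicular for the 10-degree linearity deviation
        perp <- c(-xh[2], xh[1], 0)
        if (sum(perp^2) < 1e-12) perp <- c(1, 0, 0)
        perp <- perp / sqrt(sum(perp^2))
        dev <- 10 * pi / 180
        gxyz[ga$acceptor, ] <- hx[donor_h, ] +
          1.9 * (cos(dev) * xh + sin(dev) * perp)
      }
      # re-center the non-acceptor atoms along the axis so the whole-guest
      # axis projection equals the imposed depth exactly
      proj <- as.numeric(sweep(gxyz, 2, center) %*% axis)
      shift <- (depth * na_ - sum(proj)) / (na_ - 1)
      rest <- setdiff(seq_len(na_), ga$acceptor)
      gxyz[rest, ] <- gxyz[rest, ] +
        matrix(axis * shift, length(rest), 3, byrow = TRUE)
      fr[ga_rows, ] <- gxyz

      # second guest: two-state residence kinetics
      if (bound) {
        if (stats::runif(1) < p_off) bound <- FALSE
      } else {
        if (stats::runif(1) < p_on) bound <- TRUE
      }
      cen_b <- if (bound) bound_centroid else unbound_centroid
      bxyz <- sweep(gb$offsets, 2, cen_b, "+")
      if (bound) {
        bxyz <- bxyz + matrix(stats::rnorm(3 * nb_, 0, params$noise_sd),
                              nb_, 3)
      }
      fr[gb_rows, ] <- bxyz

      frames[[f]] <- fr
      gt_hbond[f] <- hbond; gt_bound[f] <- bound; gt_depth[f] <- depth
    }
  })

  reference <- frames[[1]]
  reference[seq_len(n_host), ] <- host_xyz
  reference[gb_rows, ] <- sweep(gb$offsets, 2, bound_centroid, "+")

  list(
    trajectory = trajectory(frames, topo, params$frame_interval),
    ground_truth = tibble::tibble(frame = seq_len(nfr), hbond = gt_hbond,
                                  bound = gt_bound, depth = gt_depth),
    reference = reference,
    selections = list(
      host = host$host, rim_narrow = host$rim_narrow,
      rim_wide = host$rim_wide, donors = host$donors,
      acceptors = n_host + ga$acceptor - 1L,
      guest_whole = (n_host):(n_host + na_ - 1L),
      guest_cyclohexyl = n_host + ga$cyclohexyl - 1L,
      guest_imide = n_host + ga$imide - 1L,
      guest_second = (n_host + na_):(n_host + na_ + nb_ - 1L)
    ),
    params = params
  )
}

#' Uniform per-atom parameters for synthetic systems
#'
#' @param system A [molecular_system()].
#' @param charge,epsilon,rmin_half,pb_radius Per-atom values, recycled.
#' @return An [ff_parameters()] tibble.
#' @export
toy_parameters <- function(system, charge = 0, epsilon = 0.1,
                           rmin_half = 1.7, pb_radius = 1.8) {
  n <- n_atoms(system)
  ff_parameters(tibble::tibble(
    index = seq_len(n) - 1L,
    charge = rep_len(charge, n),
    epsilon = rep_len(epsilon, n),
    rmin_half = rep_len(rmin_half, n),
    pb_radius = rep_len(pb_radius, n)
  ), n_atoms = n)
}

#' Thermochemistry fixtures with closed-form answers
#'
#' Builds small frequency datasets whose thermodynamics are known
#' analytically, for use as oracles:
#' `"monatomic"` (Sackur-Tetrode), `"diatomic"` (rigid rotor plus one
#' harmonic mode), and `"ts_pair"` (a nonlinear minimum and a transition
#' state identical except that one low-frequency mode is deleted and an
#' imaginary mode added, so the activation entropy gap is that mode's
#' closed-form entropy).
#'
#' @param kind `"monatomic"`, `"diatomic"` or `"ts_pair"`.
#' @param mass,masses Atomic masses, amu.
#' @param bond_length Diatomic bond length, Angstrom.
#' @param frequency Diatomic mode, cm^-1.
#' @param symmetry_number External symmetry number.
#' @param removed_mode Low-frequency mode removed at the TS, cm^-1.
#' @param cond A [thermo_conditions()] at which the closed forms are
#'   evaluated.
#' @return A list with the dataset(s) and an `expected` list of closed-form
#'   values (entropies in cal/(mol K), energies in kcal/mol).
#' @export
make_thermo_fixture <- function(kind = c("monatomic", "diatomic", "ts_pair"),
                                mass = 39.948, masses = c(14.003, 15.995),
                                bond_length = 1.15, frequency = 1904,
                                symmetry_number = 1L, removed_mode = 50,
                                cond = thermo_conditions()) {
  kind <- match.arg(kind)
  T <- cond$temperature; P <- cond$pressure * .const$atm_pa
  kB <- .const$boltzmann; h <- .const$planck
  R_cal <- .const$R_cal; R_kcal <- .const$R_kcal

  st_entropy <- function(m_amu) {
    q <- (2 * pi * m_amu * .const$amu_kg * kB * T / h^2)^1.5 * kB * T / P
    R_cal * (log(q) + 2.5)
  }
  vib_closed <- function(nu) {
    x <- h * .const$c_cm * nu / (kB * T)
    list(s = R_cal * (x / (exp(x) - 1) - log(1 - exp(-x))),
         e_thermal = R_kcal * T * x / (exp(x) - 1),
         zpe = h * .const$c_cm * nu / 2 * .const$avogadro /
           (.const$cal_joule * 1000))
  }

  if (kind == "monatomic") {
    ds <- frequency_dataset(0, mass, matrix(0, 1, 3), numeric(),
                            title = "monatomic fixture")
    s <- st_entropy(mass)
    hh <- 2.5 * R_kcal * T
    return(list(dataset = ds,
                expected = list(s_total = s, h_total = hh,
                                g_total = hh - T * s / 1000)))
  }
  if (kind == "diatomic") {
    co <- matrix(c(0, 0, 0, 0, 0, bond_length), 2, 3, byrow = TRUE)
    ds <- frequency_dataset(0, masses, co, frequency,
                            symmetry_number = symmetry_number,
                            title = "diatomic fixture")
    mu <- prod(masses) / sum(masses) * .const$amu_kg
    inertia <- mu * (bond_length * 1e-10)^2
    theta_r <- h^2 / (8 * pi^2 * inertia * kB)
    s_rot <- R_cal * (log(T / (symmetry_number * theta_r)) + 1)
    vb <- vib_closed(frequency)
    s <- st_entropy(sum(masses)) + s_rot + vb$s
    hh <- vb$zpe + 1.5 * R_kcal * T + R_kcal * T + vb$e_thermal + R_kcal * T
    return(list(dataset = ds,
                expected = list(s_total = s, s_rot = s_rot, s_vib = vb$s,
                                h_total = hh, g_total = hh - T * s / 1000)))
  }
  # ts_pair: nonlinear 3-atom minimum with three modes; TS drops the low
  # mode and gains an imaginary one, same geometry/energy otherwise
  co <- matrix(c(0, 0, 0.117, 0, 0.757, -0.469, 0, -0.757, -0.469), 3, 3,
               byrow = TRUE)
  ms <- c(15.999, 1.008, 1.008)
  modes_min <- c(removed_mode, 1650, 3700)
  reactant <- frequency_dataset(0, ms, co, modes_min,
                                title = "ts_pair reactant")
  ts <- frequency_dataset(0, ms, co, c(-500, 1650, 3700),
                          is_transition_state = TRUE, title = "ts_pair ts")
  vb <- vib_closed(removed_mode)
  minus_t_ds <- T * vb$s / 1000
  delta_h <- -(vb$zpe + vb$e_thermal)
  list(reactant = reactant, ts = ts,
       expected = list(minus_t_delta_s = minus_t_ds, delta_h = delta_h,
                       delta_g = delta_h + minus_t_ds,
                       removed_mode_entropy = vb$s))
}

#' Born-ion fixture with the analytic solvation energy
#'
#' One charged sphere, whose polar solvation energy has the closed form
#' `-(k q^2 / 2a)(1 - 1/eps_out)` -- the standard oracle for a
#' Poisson-Boltzmann solver.
#'
#' @param charge Ion charge, e.
#' @param radius Cavity radius a, Angstrom.
#' @param eps_out Solvent dielectric.
#' @return A list with `system`, `params` ([ff_parameters()]), and `energy`
#'   (kcal/mol, analytic).
#' @export
make_born_fixture <- function(charge = 1, radius = 2, eps_out = 80) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  sys <- molecular_system(
    tibble::tibble(element = "X", x = 0, y = 0, z = 0),
    title = "Born ion")
  params <- ff_parameters(tibble::tibble(
    index = 0L, charge = charge, epsilon = 0, rmin_half = radius,
    pb_radius = radius))
  list(system = sys, params = params,
       energy = -(.const$coulomb_k * charge^2 / (2 * radius)) *
         (1 - 1 / eps_out))
}
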