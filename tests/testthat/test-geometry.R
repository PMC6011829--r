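test_that("host frame: symmetric construction, equivariance, antisymmetry", {
  host <- build_toy_host()
  ax <- host_frame(host$system, host$host, host$rim_narrow, host$rim_wide)
  expect_equal(ax$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ax$axis, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(sqrt(sum(ax$axis^2)), 1, tolerance = 1e-9)

  R <- random_rotation(4); t <- c(3, -2, 7)
  moved <- set_coords(host$system, rigid_transform(coords(host$system), R, t))
  ax2 <- host_frame(moved, host$host, host$rim_narrow, host$rim_wide)
  expect_equal(ax2$axis, as.numeric(R %*% ax$axis), tolerance = 1e-9)
  expect_equal(ax2$center, as.numeric(R %*% ax$center + t), tolerance = 1e-9)

  ax3 <- host_frame(host$system, host$host, host$rim_wide, host$rim_narrow)
  expect_equal(ax3$axis, -ax$axis, tolerance = 1e-12)

  expect_error(host_frame(host$system, host$host, integer(), host$rim_wide),
               "empty")
})

test_that("H-bond detection applies strict distance and linearity rules", {
  crit <- hbond_criterion()
  donors <- rbind(c(0L, 1L)); acceptors <- 2L

  hit <- detect_hbonds(hbond_geometry(2.0, 170), donors, acceptors, crit)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 2.0, tolerance = 1e-9)
  expect_equal(hit$linearity_deviation, 10, tolerance = 1e-6)

  # boundary cases are excluded (strict <)
  expect_equal(nrow(detect_hbonds(hbond_geometry(2.2, 170), donors,
                                  acceptors, crit)), 0L)
  expect_equal(nrow(detect_hbonds(hbond_geometry(1.8, 85), donors,
                                  acceptors, crit)), 0L)

  # coincident X,H is an undefined angle
  bad <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(detect_hbonds(bad, donors, acceptors, crit), "coincident")
})

test_that("occurrence percentage is the H-bonded frame fraction", {
  # frames built directly: formed geometry vs far-away acceptor
  make_frame <- function(bonded) {
    if (bonded) hbond_geometry(1.9, 175) else hbond_geometry(8, 175)
  }
  topo <- molecular_system(tibble::tibble(element = c("O", "H", "N"),
                                          x = 0, y = 0, z = 0))
  donors <- rbind(c(0L, 1L)); acceptors <- 2L

  for (case in list(c(20, 3000, 0.67), c(123, 3000, 4.10))) {
    flags <- rep(FALSE, case[2]); flags[seq_len(case[1])] <- TRUE
    traj <- trajectory(lapply(flags, make_frame), topo, 100)
    occ <- hbond_occupancy(traj, donors, acceptors)
    expect_equal(round(occ$occupancy_percent, 2), case[3])
  }

  all_on <- trajectory(lapply(rep(TRUE, 10), make_frame), topo, 100)
  expect_equal(hbond_occupancy(all_on, donors, acceptors)$occupancy_percent,
               100)
  expect_error(hbond_occupancy(trajectory(list(), topo, 100), donors,
                               acceptors))
})

test_that("occupancy equals a brute-force recount on small trajectories", {
  sim <- simulate_binding_trajectory(
    params = synthetic_trajectory_params(n_frames = 50, p_hbond = 0.3,
                                         seed = 9))
  sel <- sim$selections
  occ <- hbond_occupancy(sim$trajectory, sel$donors, sel$acceptors)
  brute <- hbond_frames_brute(sim$trajectory, sel$donors, sel$acceptors)
  expect_equal(occ$occupancy_percent, 100 * brute / 50, tolerance = 1e-12)
  expect_equal(sum(occ$per_frame), brute)
})

test_that("depth metrics are signed axis projections, rigid-motion invariant", {
  host <- build_toy_host()
  sys <- host$system
  n <- n_atoms(sys)
  # append a one-atom guest at a known depth
  at <- dplyr::bind_rows(sys$atoms[, c("element", "x", "y", "z")],
                         tibble::tibble(element = "C", x = 0, y = 0, z = 0))
  sys2 <- molecular_system(at)
  ax <- host_frame(sys2, host$host, host$rim_narrow, host$rim_wide)

  d0 <- depth_metrics(coords(sys2), ax, list(guest = n))
  expect_equal(d0$depth, 0, tolerance = 1e-12)

  xyz <- coords(sys2); xyz[n + 1, 3] <- 2
  expect_equal(depth_metrics(xyz, ax, list(guest = n))$depth, 2,
               tolerance = 1e-12)
  xyz[n + 1, 3] <- -1.5   # toward the narrow rim: negative
  expect_equal(depth_metrics(xyz, ax, list(guest = n))$depth, -1.5,
               tolerance = 1e-12)

  # invariance of the full statistic under rigid motion of everything
  for (s in 1:5) {
    R <- random_rotation(s); t <- stats::rnorm(3, sd = 5)
    moved <- rigid_transform(xyz, R, t)
    ax2 <- host_frame(sys2, host$host, host$rim_narrow, host$rim_wide,
                      frame = moved)
    expect_equal(depth_metrics(moved, ax2, list(guest = n))$depth, -1.5,
                 tolerance = 1e-9)
  }
  expect_error(depth_metrics(xyz, ax, list(guest = integer())), "empty")
})

test_that("guest RMSD removes global motion and reports true displacement", {
  sim <- simulate_binding_trajectory(
    params = synthetic_trajectory_params(n_frames = 3, noise_sd = 0,
                                         seed = 5))
  ref <- sim$trajectory$frames[[1]]
  sel <- sim$selections
  host_idx <- sel$host; guest_idx <- sel$guest_second

  # frame identical to reference
  tr1 <- trajectory(list(ref), sim$trajectory$topology, 100)
  expect_equal(guest_rmsd(tr1, ref, host_idx, guest_idx)$rmsd, 0,
               tolerance = 1e-9)

  # whole-system translation is removed by superposition
  tr2 <- trajectory(list(sweep(ref, 2, c(3, 4, 0), "+")),
                    sim$trajectory$topology, 100)
  expect_equal(guest_rmsd(tr2, ref, host_idx, guest_idx)$rmsd, 0,
               tolerance = 1e-9)

  # guest-only 3-4-5 displacement
  f3 <- ref
  f3[guest_idx + 1, 1] <- f3[guest_idx + 1, 1] + 3
  f3[guest_idx + 1, 2] <- f3[guest_idx + 1, 2] + 4
  tr3 <- trajectory(list(f3), sim$trajectory$topology, 100)
  expect_equal(guest_rmsd(tr3, ref, host_idx, guest_idx)$rmsd, 5,
               tolerance = 1e-9)

  expect_error(guest_rmsd(tr3, ref, host_idx[1:2], guest_idx),
               "at least 3")
})

test_that("Kabsch superposition matches the bio3d least-squares oracle", {
  skip_if_not_installed("bio3d")
  set.seed(42)
  for (s in 1:3) {
    ref <- matrix(stats::rnorm(30), 10, 3)
    R <- random_rotation(s)
    mobile <- rigid_transform(ref, R, c(1, 2, 3)) +
      matrix(stats::rnorm(30, sd = 0.1), 10, 3)
    fit <- hostguest:::kabsch(mobile, ref)
    ours <- hostguest:::apply_kabsch(fit, mobile)
    theirs <- matrix(bio3d::fit.xyz(as.vector(t(ref)),
                                    as.vector(t(mobile)),
                                    fixed.inds = 1:30,
                                    mobile.inds = 1:30),
                     10, 3, byrow = TRUE)
    expect_equal(ours, theirs, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})
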