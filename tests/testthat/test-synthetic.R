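test_that("toy host geometry is deterministic with the stated counts", {
  host <- build_toy_host(n_units = 3)
  expect_equal(n_atoms(host$system), 9L)          # 6 ring atoms + 3 hydrogens
  expect_equal(nrow(host$donors), 3L)
  expect_equal(length(host$rim_narrow), 3L)

  # default host frame: axis +z, center origin (checked in geometry tests);
  # inverted cone flips the axis under the same rim-selection convention
  inv <- build_toy_host(narrow_radius = 4.5, wide_radius = 3.0)
  ax <- host_frame(inv$system, inv$host, inv$rim_narrow, inv$rim_wide)
  expect_equal(ax$axis, c(0, 0, 1), tolerance = 1e-12)  # still narrow->wide

  expect_error(build_toy_host(narrow_radius = -1), "positive")
  expect_error(build_toy_host(n_units = 2), "n_units")
})

test_that("identical parameters and seed give bit-identical trajectories", {
  p <- synthetic_trajectory_params(n_frames = 40, seed = 123)
  a <- simulate_binding_trajectory(params = p)
  b <- simulate_binding_trajectory(params = p)
  expect_identical(a$trajectory$frames, b$trajectory$frames)
  expect_identical(a$ground_truth, b$ground_truth)

  c_ <- simulate_binding_trajectory(
    params = synthetic_trajectory_params(n_frames = 40, seed = 124))
  expect_false(identical(a$trajectory$frames, c_$trajectory$frames))
})

test_that("degenerate rates and probabilities give the promised extremes", {
  p0 <- synthetic_trajectory_params(n_frames = 60, p_hbond = 0, seed = 5)
  sim <- simulate_binding_trajectory(params = p0)
  occ <- hbond_occupancy(sim$trajectory, sim$selections$donors,
                         sim$selections$acceptors)
  expect_equal(occ$occupancy_percent, 0)

  pa <- synthetic_trajectory_params(n_frames = 60, k_off = 0, seed = 5)
  sim2 <- simulate_binding_trajectory(params = pa)
  rmsd <- guest_rmsd(sim2$trajectory, sim2$reference, sim2$selections$host,
                     sim2$selections$guest_second)
  out <- residence_summary(classify_bound(rmsd, 5))
  expect_equal(out$occupancy_percent, 100)
  expect_equal(length(out$dwell_times_ns), 1L)   # one dwell spanning the run
})

test_that("H-bond occupancy recovers the imposed probability (binomial bound)", {
  p <- synthetic_trajectory_params(n_frames = 3000, p_hbond = 0.041,
                                   seed = 17)
  sim <- simulate_binding_trajectory(params = p)
  sel <- sim$selections
  occ <- hbond_occupancy(sim$trajectory, sel$donors, sel$acceptors)
  # detection must agree with the generator's ground truth frame by frame
  expect_identical(occ$per_frame, sim$ground_truth$hbond)
  bound3 <- 3 * sqrt(0.041 * 0.959 / 3000) * 100
  expect_lt(abs(occ$occupancy_percent - 4.1), bound3)
})

test_that("depth and residence statistics recover ground truth per frame", {
  p <- synthetic_trajectory_params(n_frames = 250, seed = 31)
  sim <- simulate_binding_trajectory(params = p)
  sel <- sim$selections

  dp <- depth_profile(sim$trajectory, sel$host, sel$rim_narrow, sel$rim_wide,
                      list(whole = sel$guest_whole))
  expect_equal(dp$mean, mean(sim$ground_truth$depth), tolerance = 0.02)
  expect_equal(dp$sd, stats::sd(sim$ground_truth$depth), tolerance = 0.05)

  rmsd <- guest_rmsd(sim$trajectory, sim$reference, sel$host,
                     sel$guest_second)
  rs <- classify_bound(rmsd, 5)
  expect_identical(rs$bound, sim$ground_truth$bound)
})

test_that("generated trajectories round-trip through the io layer", {
  sim <- simulate_binding_trajectory(
    params = synthetic_trajectory_params(n_frames = 4, seed = 2))
  f <- tempfile(fileext = ".xyz")
  write_trajectory(sim$trajectory, f)
  back <- read_trajectory(f, frame_interval = 100)
  expect_equal(n_frames(back), 4L)
  expect_equal(back$topology$atoms$element,
               sim$trajectory$topology$atoms$element)
  for (i in 1:4) {
    expect_lt(max(abs(back$frames[[i]] - sim$trajectory$frames[[i]])), 1e-5)
  }
})

test_that("thermo and Born fixtures carry correct closed-form answers", {
  born <- make_born_fixture(charge = 1, radius = 2, eps_out = 80)
  expect_equal(born$energy, -(332.0637 / 4) * (1 - 1 / 80),
               tolerance = 1e-9)
  expect_error(make_born_fixture(radius = -2), "radius")
  expect_error(make_thermo_fixture("unknown"))

  # symmetry-number contrast is R ln 2 by closed form too
  f1 <- make_thermo_fixture("diatomic", masses = c(16, 16),
                            symmetry_number = 1)
  f2 <- make_thermo_fixture("diatomic", masses = c(16, 16),
                            symmetry_number = 2)
  R_cal <- 8.31446261815324 / 4.184
  expect_equal(f1$expected$s_total - f2$expected$s_total, R_cal * log(2),
               tolerance = 1e-9)
})
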