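test_that("PDB structures read faithfully and round-trip at format precision", {
  f <- write_water_pdb()
  sys <- read_structure(f)
  expect_equal(n_atoms(sys), 3L)
  expect_equal(sys$atoms$element, c("O", "H", "H"))
  expect_equal(coords(sys)[1, ], c(0, 0, 0.117), tolerance = 1e-9)

  host <- build_toy_host()$system
  out <- tempfile(fileext = ".pdb")
  write_structure(host, out)
  back <- read_structure(out)
  expect_equal(n_atoms(back), n_atoms(host))
  expect_equal(back$atoms$element, host$atoms$element)
  expect_lt(max(abs(coords(back) - coords(host))), 1e-3)
})

test_that("XYZ structures round-trip and malformed/empty files error", {
  host <- build_toy_host(n_units = 5)$system
  f <- tempfile(fileext = ".xyz")
  write_structure(host, f)
  back <- read_structure(f)
  expect_lt(max(abs(coords(back) - coords(host))), 1e-5)

  empty <- tempfile(fileext = ".xyz")
  writeLines(character(), empty)
  expect_error(read_structure(empty), "empty")

  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  O   HOH A   1       0.000   xx0.00   0.117"),
             bad)
  expect_error(read_structure(bad), "line 1")
})

test_that("multi-model XYZ trajectories parse with the declared frame count", {
  sim <- simulate_binding_trajectory(
    params = synthetic_trajectory_params(n_frames = 5, seed = 2))
  f <- tempfile(fileext = ".xyz")
  write_trajectory(sim$trajectory, f)
  tr <- read_trajectory(f, frame_interval = 100)
  expect_equal(n_frames(tr), 5L)
  expect_equal(tr$frame_interval, 100)
  for (i in 1:5) {
    expect_lt(max(abs(tr$frames[[i]] - sim$trajectory$frames[[i]])), 1e-5)
  }

  # single frame
  one <- tempfile(fileext = ".xyz")
  writeLines(c("2", "pair", "C 0 0 0", "C 1 0 0"), one)
  expect_equal(n_frames(read_trajectory(one)), 1L)

  # frame 3 missing one atom
  lines <- c("2", "f1", "C 0 0 0", "C 1 0 0",
             "2", "f2", "C 0 0 0", "C 1 0 0",
             "1", "f3", "C 0 0 0",
             "2", "f4", "C 0 0 0", "C 1 0 0")
  bad <- tempfile(fileext = ".xyz")
  writeLines(lines, bad)
  expect_error(read_trajectory(bad), "frame 3")
})

test_that("trajectory construction rejects inconsistent frames and intervals", {
  topo <- build_toy_host(n_units = 3)$system
  ok <- matrix(0, n_atoms(topo), 3)
  expect_error(trajectory(list(ok, ok[-1, ]), topo), "frame 2")
  expect_error(trajectory(list(ok), topo, frame_interval = 0),
               "frame_interval")
})

test_that("parameter tables validate indices, signs and completeness", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("index,charge,epsilon,rmin_half,pb_radius",
               "0,1,0.1,1.7,1.8", "1,-1,0.1,1.7,1.8"), f)
  p <- read_parameter_table(f, n_atoms = 2)
  expect_equal(sum(p$charge), 0)

  writeLines(c("index,charge,epsilon,rmin_half,pb_radius",
               "0,1,0.1,1.7,-1.8"), f)
  expect_error(read_parameter_table(f), "pb_radius")

  writeLines(c("index,charge,epsilon,rmin_half,pb_radius",
               "0,1,0.1,1.7,1.8", "0,-1,0.1,1.7,1.8"), f)
  expect_error(read_parameter_table(f), "duplicated")

  writeLines(c("index,charge,epsilon,rmin_half,pb_radius",
               "0,1,0.1,1.7,1.8", "2,-1,0.1,1.7,1.8"), f)
  expect_error(read_parameter_table(f, n_atoms = 3), "missing atom indices: 1")
})

test_that("frequency datasets enforce the transition-state mode contract", {
  co <- matrix(c(0, 0, 0.117, 0, 0.757, -0.469, 0, -0.757, -0.469),
               3, 3, byrow = TRUE)
  ms <- c(15.999, 1.008, 1.008)
  expect_s3_class(frequency_dataset(0, ms, co, c(1600, 3650, 3750)),
                  "frequency_dataset")
  ts <- frequency_dataset(0, ms, co, c(-500, 1600, 3650),
                          is_transition_state = TRUE)
  expect_true(ts$is_transition_state)
  expect_error(frequency_dataset(0, ms, co, c(-10, 1600, 3650)),
               "minimum")
  expect_error(frequency_dataset(0, ms, co, c(1600, 3650, 3750),
                                 is_transition_state = TRUE),
               "exactly one negative")
  expect_error(frequency_dataset(0, ms, co, c(-10, -500, 3650),
                                 is_transition_state = TRUE),
               "exactly one negative")
})

test_that("frequency files round-trip through the key-value dialect", {
  fx <- make_thermo_fixture("ts_pair")
  f <- tempfile()
  write_frequency_dataset(fx$ts, f)
  back <- read_frequency_dataset(f)
  expect_true(back$is_transition_state)
  expect_equal(back$frequencies, fx$ts$frequencies, tolerance = 1e-6)
  expect_equal(back$masses, fx$ts$masses, tolerance = 1e-8)
  expect_equal(back$coords, fx$ts$coords, tolerance = 1e-8)

  write_frequency_dataset(fx$reactant, f)
  r <- read_frequency_dataset(f)
  expect_false(r$is_transition_state)
  expect_equal(thermo_result(r)$s_total, thermo_result(fx$reactant)$s_total,
               tolerance = 1e-6)
})
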