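test_that("Coulomb term reproduces the analytic law and is symmetric", {
  a <- rbind(c(0, 0, 0)); b <- rbind(c(1, 0, 0))
  expect_equal(coulomb_energy(a, 1, b, 1), 332.0637, tolerance = 1e-9)
  expect_equal(coulomb_energy(a, 1, rbind(c(3.320637, 0, 0)), -1), -100,
               tolerance = 1e-6)
  expect_equal(coulomb_energy(a, 0, b, 1), 0)
  expect_equal(coulomb_energy(a, 0.7, b, -0.3),
               coulomb_energy(b, -0.3, a, 0.7))
  expect_error(coulomb_energy(a, 1, a, 1), "r = 0")
})

test_that("Lennard-Jones term has the right minimum, zero and decay", {
  p <- data.frame(epsilon = 0.25, rmin_half = 1.7)
  rmin <- 3.4
  at <- function(r) lennard_jones_energy(rbind(c(0, 0, 0)), p,
                                         rbind(c(r, 0, 0)), p)
  expect_equal(at(rmin), -0.25, tolerance = 1e-12)
  expect_equal(at(rmin / 2^(1 / 6)), 0, tolerance = 1e-12)
  expect_lt(abs(at(10 * rmin)), 1e-5 * 0.25)
})

test_that("pairwise sums equal brute-force double loops on 100-atom systems", {
  set.seed(7)
  na <- 60; nb <- 40
  xa <- matrix(stats::runif(3 * na, -8, 8), na, 3)
  xb <- matrix(stats::runif(3 * nb, 12, 25), nb, 3)  # disjoint regions
  qa <- stats::rnorm(na); qb <- stats::rnorm(nb)
  pa <- data.frame(epsilon = stats::runif(na, 0.05, 0.3),
                   rmin_half = stats::runif(na, 1.2, 2.2))
  pb <- data.frame(epsilon = stats::runif(nb, 0.05, 0.3),
                   rmin_half = stats::runif(nb, 1.2, 2.2))
  expect_equal(coulomb_energy(xa, qa, xb, qb), coulomb_brute(xa, qa, xb, qb),
               tolerance = 1e-10)
  expect_equal(lennard_jones_energy(xa, pa, xb, pb),
               lj_brute(xa, pa, xb, pb), tolerance = 1e-10)
})

test_that("nonpolar term is the linear surface-area model", {
  expect_equal(nonpolar_energy(0), 0)
  expect_equal(nonpolar_energy(-300), -2.16, tolerance = 1e-12)
  expect_equal(nonpolar_energy(500, gamma = 0), 0)
  expect_equal(nonpolar_energy(100, gamma = 0.005, b = 0.92), 1.42,
               tolerance = 1e-12)
})

test_that("decomposition total is the component sum by construction", {
  dec <- energy_decomposition(e_coulomb = -7.24, e_pb = 17.23, e_np = -2.19,
                              e_vdw = -23.07)
  expect_equal(dec$total_enthalpy,
               dec$e_valence + dec$e_coulomb + dec$e_pb + dec$e_np +
                 dec$e_vdw, tolerance = 1e-9)
  td <- tidy(dec)
  expect_equal(td$energy[td$term == "total_enthalpy"], dec$total_enthalpy)
})

test_that("vdW-only toy dimer decomposes with zero electrostatics", {
  host <- build_toy_host(n_units = 3)
  at <- dplyr::bind_rows(
    host$system$atoms[, c("element", "x", "y", "z")],
    tibble::tibble(element = "C", x = 0, y = 0, z = 0))
  sys <- molecular_system(at, title = "toy dimer")
  n <- n_atoms(sys)
  params <- toy_parameters(sys, charge = 0)
  dec <- mmpbsa_decompose(sys, 0:(n - 2), n - 1, params,
                          grid = pb_grid_spec(spacing = 1, padding = 5))
  expect_equal(dec$e_coulomb, 0)
  expect_equal(dec$e_pb, 0)
  expect_equal(dec$total_enthalpy, dec$e_vdw + dec$e_np, tolerance = 1e-9)

  expect_error(mmpbsa_decompose(sys, 0:(n - 1), n - 1, params), "overlap")
  expect_error(mmpbsa_decompose(sys, 0:(n - 3), n - 1, params), "partition")
})

test_that("bundled decomposition tables satisfy their printed sums", {
  mm <- cd_reference_tables("mmpbsa")
  for (i in seq_len(nrow(mm))) {
    dec <- energy_decomposition(mm$e_coulomb[i], mm$e_pb[i], mm$e_np[i],
                                mm$e_vdw[i])
    expect_lt(abs(dec$total_enthalpy - mm$total_enthalpy[i]), 0.01 + 1e-9)
  }
  vm <- cd_reference_tables("vm2")
  for (i in seq_len(nrow(vm))) {
    dec <- energy_decomposition(vm$e_coulomb[i], vm$e_pb[i], vm$e_np[i],
                                vm$e_vdw[i], e_valence = vm$e_valence[i])
    expect_lt(abs(dec$total_enthalpy - vm$delta_h[i]), 0.015 + 1e-9)
  }
})
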