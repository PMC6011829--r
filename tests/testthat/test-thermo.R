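test_that("monatomic entropy matches Sackur-Tetrode for random masses", {
  ar <- make_thermo_fixture("monatomic", mass = 39.948)
  tr <- thermo_result(ar$dataset)
  expect_equal(tr$s_total, 36.98, tolerance = 0.01 / 36.98)
  expect_equal(tr$s_total, ar$expected$s_total, tolerance = 1e-9)

  set.seed(11)
  for (m in stats::runif(5, 1, 250)) {
    fx <- make_thermo_fixture("monatomic", mass = m)
    expect_equal(thermo_result(fx$dataset)$s_total, fx$expected$s_total,
                 tolerance = 0.01 / fx$expected$s_total)
  }
})

test_that("vibrational entropy matches the harmonic closed form", {
  # single 100 cm^-1 mode at 298.15 K: R[x/(e^x-1) - ln(1-e^-x)] = 3.45
  fx <- make_thermo_fixture("diatomic", frequency = 100)
  tr <- thermo_result(fx$dataset)
  expect_equal(tr$s_vib, 3.45, tolerance = 0.01 / 3.45)
  expect_equal(tr$s_total, fx$expected$s_total, tolerance = 1e-9)

  # positive, decreasing in frequency, vanishing at high frequency
  s_at <- function(nu) {
    thermo_result(make_thermo_fixture("diatomic", frequency = nu)$dataset)$s_vib
  }
  freqs <- c(50, 200, 800, 2000, 4000)
  s <- vapply(freqs, s_at, numeric(1))
  expect_true(all(s > 0))
  expect_true(all(diff(s) < 0))
  expect_lt(s_at(12000), 1e-6)
})

test_that("symmetry number enters rotational entropy as -R ln sigma", {
  s1 <- thermo_result(make_thermo_fixture("diatomic", masses = c(16, 16),
                                          symmetry_number = 1)$dataset)
  s2 <- thermo_result(make_thermo_fixture("diatomic", masses = c(16, 16),
                                          symmetry_number = 2)$dataset)
  R_cal <- 8.31446261815324 / 4.184
  expect_equal(s1$s_rot - s2$s_rot, R_cal * log(2), tolerance = 1e-9)
})

test_that("G = H - TS and S-component additivity hold to numerical identity", {
  states <- list(
    make_thermo_fixture("monatomic")$dataset,
    make_thermo_fixture("diatomic")$dataset,
    make_thermo_fixture("ts_pair")$reactant,
    make_thermo_fixture("ts_pair")$ts)
  for (ds in states) {
    for (T in c(250, 298.15, 350)) {
      tr <- thermo_result(ds, thermo_conditions(temperature = T))
      expect_lt(abs(tr$g_total - (tr$h_total - T * tr$s_total / 1000)), 1e-9)
      expect_lt(abs(tr$s_total -
                      (tr$s_trans + tr$s_rot + tr$s_vib + tr$s_elec)), 1e-9)
    }
  }
})

test_that("mode-count contract and TS imaginary-mode exclusion", {
  co <- matrix(c(0, 0, 0.117, 0, 0.757, -0.469, 0, -0.757, -0.469),
               3, 3, byrow = TRUE)
  ms <- c(15.999, 1.008, 1.008)
  short <- frequency_dataset(0, ms, co, c(1600, 3650))
  expect_error(thermo_result(short), "expected 3 real modes")

  fx <- make_thermo_fixture("ts_pair")
  ts <- thermo_result(fx$ts)
  expect_equal(ts$n_modes, 2L)   # imaginary mode dropped
})

test_that("activation decomposition recovers a constructed entropy gap", {
  fx <- make_thermo_fixture("ts_pair", removed_mode = 50)
  act <- activation_decomposition(thermo_result(fx$reactant),
                                  thermo_result(fx$ts))
  expect_equal(act$minus_t_delta_s, fx$expected$minus_t_delta_s,
               tolerance = 1e-9)
  expect_equal(act$delta_h, fx$expected$delta_h, tolerance = 1e-9)
  expect_equal(act$delta_g, act$delta_h + act$minus_t_delta_s,
               tolerance = 1e-9)
  expect_equal(act$reference, "supermolecule")

  # identical states give a null decomposition
  r <- thermo_result(fx$reactant)
  null_act <- activation_decomposition(r, r)
  expect_equal(null_act$delta_g, 0, tolerance = 1e-12)
  expect_equal(null_act$delta_h, 0, tolerance = 1e-12)

  # separated-species reference is labeled and summed
  sep <- activation_decomposition(list(r, r), thermo_result(fx$ts))
  expect_equal(sep$reference, "separated")
  expect_equal(sep$delta_g, thermo_result(fx$ts)$g_total - 2 * r$g_total,
               tolerance = 1e-9)

  cold <- thermo_result(fx$reactant, thermo_conditions(temperature = 250))
  expect_error(activation_decomposition(cold, thermo_result(fx$ts)),
               "different temperatures")
})

test_that("free-energy identity check passes the bundled tables, flags breaks", {
  act <- cd_reference_tables("activation")
  out <- check_free_energy_identity(act)
  expect_true(all(abs(out$residual) <= 0.01 + 1e-9))
  expect_false(any(out$flagged))

  vm <- cd_reference_tables("vm2")
  out2 <- check_free_energy_identity(vm)
  expect_false(any(out2$flagged))
  # the specific row: dG = -18.52 + 15.81 = -2.71 exactly
  expect_equal(out2$residual[vm$complex == "beta-CD and 1"], 0,
               tolerance = 1e-9)

  broken <- tibble::tibble(delta_g = 10, delta_h = 5, minus_t_delta_s = 4)
  expect_true(check_free_energy_identity(broken)$flagged)
})
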