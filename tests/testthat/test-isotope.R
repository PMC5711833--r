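# Delta conversions, headspace accounting, and the 13C mass balance.

test_that("delta-13C and atom fraction convert exactly and round-trip", {
  expect_equal(delta_to_atom_fraction(0), 0.0111802 / 1.0111802,
               tolerance = 1e-12)
  expect_equal(round(delta_to_atom_fraction(0), 6), 0.011057)
  # doubling the isotope ratio at delta = +1000 per mil
  expect_equal(delta_to_atom_fraction(1000),
               (2 * 0.0111802) / (1 + 2 * 0.0111802), tolerance = 1e-12)
  x <- c(0.0108, 0.011, 0.05, 0.195, 0.5)
  expect_equal(delta_to_atom_fraction(atom_fraction_to_delta(x)), x,
               tolerance = 1e-12)
  expect_error(delta_to_atom_fraction(-1000), "-1000")
})

test_that("headspace concentration converts by ideal-gas accounting", {
  # 1000 uL/L net, 1 L headspace, 20 g soil at standard conditions:
  # 1e-3 * 101325 * 1e-3 / (8.314 * 298.15) mol * 12.011e6 ug / 20 g
  expect_equal(headspace_to_co2c_mass(1000, 1, 20), 24.548,
               tolerance = 1e-3)
  expect_equal(headspace_to_co2c_mass(400, 1, 20, blank_concentration = 400),
               0)
  expect_equal(headspace_to_co2c_mass(1000, 1, 40),
               headspace_to_co2c_mass(1000, 1, 20) / 2)
  expect_warning(out <- headspace_to_co2c_mass(300, 1, 20,
                                               blank_concentration = 400),
                 "negative")
  expect_equal(out, 0)
  expect_error(headspace_to_co2c_mass(1000, 0, 20), "headspace_volume")
})

test_that("interval accumulation sums windows and refuses gaps", {
  t5 <- c(4, 12, 24, 36, 48)
  m5 <- c(10, 20, 30, 20, 20)
  expect_equal(accumulate_intervals(t5, m5), 100)
  expect_equal(accumulate_intervals(t5, m5, window = c(0, 24)), 60)
  expect_error(accumulate_intervals(c(4, 12, 36, 48), c(1, 1, 1, 1),
                                    schedule = t5), "missing")
})

test_that("two-source mixing partition matches hand calculations", {
  expect_equal(partition_glucose(100, 0.100, 0.0108, 0.195),
               100 * 0.0892 / 0.1842, tolerance = 1e-12)
  expect_equal(partition_glucose(50, 0.0108, 0.0108, 0.195), 0)
  expect_equal(partition_glucose(50, 0.195, 0.0108, 0.195), 50)
  expect_error(partition_glucose(10, 0.1, 0.2, 0.2), "collapse")
  # strictly increasing in the sample abundance
  xs <- seq(0.02, 0.18, by = 0.02)
  expect_true(all(diff(partition_glucose(100, xs, 0.0108, 0.195)) > 0))
  # bounded by [0, Rt] whenever x_soil <= x_sample <= x_glucose
  rg <- partition_glucose(100, xs, 0.0108, 0.195)
  expect_true(all(rg >= 0 & rg <= 100))
})

test_that("SOM and primed pools obey the printed mass-balance identities", {
  sp <- som_and_primed(248.1, 172.5, 37.4)
  expect_equal(sp$rsom, 75.6, tolerance = 1e-9)
  expect_equal(sp$rprimed, 38.2, tolerance = 1e-9)
  sp2 <- som_and_primed(100, 100, 0)
  expect_equal(sp2$rsom, 0)
  expect_equal(sp2$rprimed, 0)
  # negative priming preserved
  expect_lt(som_and_primed(100, 80, 30)$rprimed, 0)
  pp <- partition_proportions(100, 34.7 / 60.8 * 100, 34.7, 60.8)
  expect_equal(pp$p_primed_of_som, 57.07, tolerance = 0.005)
  expect_equal(partition_proportions(100, 100, 0, 50)$p_primed_of_som, 0)
  expect_equal(partition_proportions(100, 100, 10, 50)$p_glucose_of_total,
               100)
  expect_error(partition_proportions(0, 1, 1, 1), "nonzero")
})

test_that("fumigation-extraction MBC follows the kec convention", {
  expect_equal(microbial_biomass_c(155, 65), 200)
  expect_equal(microbial_biomass_c(65, 65), 0)
  expect_equal(microbial_biomass_c(100, 60, kec = 1), 40)
  expect_warning(out <- microbial_biomass_c(50, 65), "negative")
  expect_equal(out, 0)
  expect_error(microbial_biomass_c(100, 50, kec = 0), "kec")
})

test_that("partition_jars recovers a noise-free synthetic experiment", {
  d <- small_design(seed = 21)
  tr <- noiseless_truth(d)
  gas <- simulate_gas_series(d, tr)
  part <- partition_jars(gas, x_glucose = tr$x_glucose)
  expect_equal(nrow(part), 2 * 2 * d$n_replicates)  # glucose jars only
  for (t in design_treatments(d)) {
    p <- part[part$treatment == t, ]
    true_rg <- tr$frac_glucose_respired[[t]] * d$glucose_c_rate
    expect_equal(mean(p$rglucose), true_rg, tolerance = 5e-3)
    expect_equal(mean(p$rbasal), tr$basal_co2c[[t]], tolerance = 1e-8)
    expect_equal(mean(p$priming_coefficient), tr$priming_coef[[t]],
                 tolerance = 0.02)
    # conservation identity holds row by row at machine precision
    expect_equal(p$rglucose + p$rsom, p$rt, tolerance = 1e-12)
    expect_equal(p$rprimed + p$rbasal, p$rsom, tolerance = 1e-12)
  }
})

test_that("partition_jars returns zero priming when truth has none", {
  d <- small_design(seed = 22)
  tr <- noiseless_truth(d, priming_coef = 0)
  part <- partition_jars(simulate_gas_series(d, tr))
  expect_equal(part$rprimed, rep(0, nrow(part)), tolerance = 1e-6)
})

test_that("interval and cumulative partition granularity agree when the
           soil endmember is constant in time", {
  d <- small_design(seed = 23)
  tr <- noiseless_truth(d)
  gas <- simulate_gas_series(d, tr)
  pi_ <- partition_jars(gas, granularity = "interval")
  pc <- partition_jars(gas, granularity = "cumulative")
  expect_equal(pi_$rglucose, pc$rglucose, tolerance = 1e-6)
})
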