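# The synthetic-data generator: integral constraints, mass balance,
# determinism, and schema.

test_that("heat curves integrate to the target cumulative heats", {
  d <- small_design(seed = 31)
  tr <- noiseless_truth(d, q_control = 1.20, q_glucose = 6.93)
  heat <- simulate_heat_curves(d, tr, dt_min = 1)
  for (u in split(heat, heat$unit_id)) {
    q <- as.numeric(cumulative_heat(u$time_h, u$power_uW_per_g))
    target <- if (u$amendment[1] == "glucose") 6.93 else 1.20
    expect_equal(q, target, tolerance = 1e-3)
  }
  # downstream efficiency pipeline then recovers the closed form
  qg <- mean(sapply(split(heat[heat$amendment == "glucose", ],
                          heat$unit_id[heat$amendment == "glucose"]),
                    function(u) cumulative_heat(u$time_h, u$power_uW_per_g)))
  qw <- mean(sapply(split(heat[heat$amendment == "water", ],
                          heat$unit_id[heat$amendment == "water"]),
                    function(u) cumulative_heat(u$time_h, u$power_uW_per_g)))
  expect_equal(thermodynamic_efficiency(qg, qw),
               1 - (6.93 - 1.20) / 18.05, tolerance = 1e-3)
})

test_that("heat simulation is reproducible and rejects bad pulses", {
  d <- small_design(seed = 32)
  tr <- synthetic_truth(d)
  h1 <- simulate_heat_curves(d, tr, dt_min = 5)
  h2 <- simulate_heat_curves(d, tr, dt_min = 5)
  expect_identical(h1, h2)
  # mode-12h default-shape pulse leaks > 1% of its mass past 48 h
  expect_error(simulate_heat_curves(d, tr, pulse_scale_h = 6), "1%")
  bad <- synthetic_truth(d, q_glucose = 1.0, q_control = 1.2)
  expect_error(simulate_heat_curves(d, bad), "exceed")
})

test_that("gas series conserve mass exactly before noise", {
  d <- small_design(seed = 33)
  tr <- noiseless_truth(d)
  gas <- simulate_gas_series(d, tr)
  for (j in split(gas[gas$amendment == "glucose", ],
                  gas$jar_id[gas$amendment == "glucose"])) {
    t <- j$treatment[1]
    total <- sum(j$co2c_ug_per_g_interval)
    expected <- tr$frac_glucose_respired[[t]] * d$glucose_c_rate +
      (1 + tr$priming_coef[[t]]) * tr$basal_co2c[[t]]
    expect_equal(total, expected, tolerance = 1e-10)
  }
  for (j in split(gas[gas$amendment == "water", ],
                  gas$jar_id[gas$amendment == "water"])) {
    expect_equal(sum(j$co2c_ug_per_g_interval),
                 tr$basal_co2c[[j$treatment[1]]], tolerance = 1e-10)
    expect_equal(j$atom_fraction_13c, rep(tr$x_soil, nrow(j)))
  }
  expect_equal(gas$co2c_ug_per_g_interval[gas$amendment == "blank"],
               rep(0, sum(gas$amendment == "blank")))
})

test_that("interval atom fraction is the mass-weighted endmember mixture", {
  # equal glucose and SOM contributions give the arithmetic mean abundance
  x <- (0.195 + 0.0108) / 2
  expect_equal(round(x, 4), 0.1029)
  d <- small_design(seed = 34)
  tr <- noiseless_truth(d)
  gas <- simulate_gas_series(d, tr)
  g <- gas[gas$amendment == "glucose", ]
  # back out the implied glucose share and check it lies in (0, 1)
  share <- (g$atom_fraction_13c - tr$x_soil) / (0.195 - tr$x_soil)
  expect_true(all(share > 0 & share < 1))
})

test_that("OTU tables honour depth, overdispersion contract, and planting", {
  d <- small_design(seed = 35)
  tr <- synthetic_truth(d, n_enriched = 15, enriched_log2fc = 3)
  o <- simulate_otu_table(d, tr, n_taxa = 60, depth = 2000)
  expect_true(all(colSums(o$counts) == 2000))
  expect_equal(length(o$enriched_taxa), 15)
  expect_equal(nrow(o$samples), 3 * 2 * 2 * d$n_replicates)
  expect_setequal(unique(o$samples$fraction),
                  c("12C-light", "13C-light", "13C-heavy"))
  # planted fold-change shows up in the heavy fraction of the target system
  heavy <- o$samples$fraction == "13C-heavy" & o$samples$management == "ORG"
  light <- o$samples$fraction == "13C-light" & o$samples$management == "ORG"
  rel <- sweep(o$counts, 2, colSums(o$counts), "/")
  lfc <- log2(rowMeans(rel[, heavy]) + 1e-6) -
    log2(rowMeans(rel[, light]) + 1e-6)
  expect_gt(mean(lfc[o$enriched_taxa]) - mean(lfc[setdiff(rownames(o$counts),
                                                          o$enriched_taxa)]),
            1.5)
  expect_error(simulate_otu_table(d, synthetic_truth(d, n_enriched = 100),
                                  n_taxa = 50), "larger")
  expect_error(simulate_otu_table(d, tr, n_taxa = 5), "n_taxa")
})

test_that("chemistry draws reproduce configured treatment means at sd zero", {
  d <- small_design(seed = 36, n_replicates = 4)
  chem <- simulate_soil_chemistry(d, sds = 0)
  # all replicates identical within treatment
  expect_true(all(tapply(chem$po4_p, chem$treatment, sd) == 0))
  means <- default_chemistry_means()
  pooled <- tapply(chem$po4_p, chem$management, mean)
  expect_equal(unname(pooled["CON"] / pooled["ORG"]), 59.6 / 15.5,
               tolerance = 1e-12)
  # fumigation-extraction columns invert to the drawn MBC exactly
  expect_equal(microbial_biomass_c(chem$ec_fumigated, chem$ec_unfumigated),
               chem$mbc, tolerance = 1e-12)
  # seeded draws reproducible
  expect_identical(simulate_soil_chemistry(d), simulate_soil_chemistry(d))
})

test_that("experiment bundles are complete, reproducible, and readable", {
  d <- small_design(seed = 37)
  tr <- synthetic_truth(d)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  dir3 <- withr::local_tempdir()
  simulate_experiment(d, tr, dir1, dt_min = 20, n_taxa = 30, depth = 500)
  simulate_experiment(d, tr, dir2, dt_min = 20, n_taxa = 30, depth = 500)
  files <- c("heat_curves.tsv", "gas_samples.tsv", "chemistry.tsv",
             "otu_counts.tsv", "samples.tsv", "truth.json")
  expect_true(all(file.exists(file.path(dir1, files))))
  # byte-identical regeneration from the same seed
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  # different seed: same schema, different data
  d2 <- small_design(seed = 38)
  simulate_experiment(d2, synthetic_truth(d2), dir3, dt_min = 20,
                      n_taxa = 30, depth = 500)
  b1 <- read_bundle(dir1)
  b3 <- read_bundle(dir3)
  expect_identical(dim(b1$otu), dim(b3$otu))
  expect_identical(names(b1$gas), names(b3$gas))
  expect_false(identical(b1$otu, b3$otu))
  expect_equal(b1$truth$truth$x_glucose, 0.195)
})
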