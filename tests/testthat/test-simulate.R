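test_that("noise-free trajectories match their closed forms", {
  m <- trajectory_model(n0 = 3e5, mu = log(2), carrying_capacity = 1e12,
                        lag_days = 0, noise_sigma = 0)
  s <- simulate_growth_series(m, days = 0:4, seed = 1)
  # doubling per day, up to the tiny logistic bend at K = 1e12
  expect_equal(s$observations$cells_per_ml, c(3, 6, 12, 24, 48) * 1e5,
               tolerance = 1e-4)
  # and exactly equal to the logistic closed form
  e <- exp(log(2) * (0:4))
  expect_equal(s$observations$cells_per_ml,
               1e12 * 3e5 * e / (1e12 + 3e5 * (e - 1)), tolerance = 1e-9)

  lagm <- trajectory_model(n0 = 3e5, mu = 1, carrying_capacity = 1e9,
                           lag_days = 3, noise_sigma = 0)
  flat <- simulate_growth_series(lagm, days = 0:3, seed = 1)
  expect_equal(flat$observations$cells_per_ml, rep(3e5, 4))

  # frozen from the logistic closed form K*n0*e^{mu t}/(K + n0*(e^{mu t}-1)),
  # cross-checked against K/(1 + ((K-n0)/n0) e^{-mu t})
  lg <- trajectory_model(n0 = 1e5, mu = 1, carrying_capacity = 1e6,
                         lag_days = 0, noise_sigma = 0)
  s10 <- simulate_growth_series(lg, days = c(0, 10), seed = 1)
  expect_equal(s10$observations$cells_per_ml[2], 999591.6,
               tolerance = 1e-6)

  expect_error(trajectory_model(n0 = -1, mu = 1, carrying_capacity = 1e6),
               class = "invalid_parameter")
  expect_error(trajectory_model(n0 = 1e6, mu = 1, carrying_capacity = 1e5),
               class = "invalid_parameter")
})

test_that("noisy trajectories are positive, seeded and reproducible", {
  m <- trajectory_model(n0 = 3e5, mu = 0.9, carrying_capacity = 1e8,
                        lag_days = 2, noise_sigma = 0.2)
  s1 <- simulate_growth_series(m, days = 0:10, seed = 99)
  s2 <- simulate_growth_series(m, days = 0:10, seed = 99)
  s3 <- simulate_growth_series(m, days = 0:10, seed = 100)
  expect_identical(s1$observations, s2$observations)
  expect_false(identical(s1$observations, s3$observations))
  expect_true(all(s1$observations$cells_per_ml > 0))
})

test_that("thermal observations sit on the curve at noise_sd = 0", {
  p <- do.call(norberg_params, table1_rows$bacteria_ambient$params)
  tab <- simulate_thermal_observations(p, n_reps = 2, noise_sd = 0, seed = 1)
  expect_equal(nrow(tab), 18L)
  expect_equal(tab$growth_rate_per_day,
               norberg_growth(tab$temperature_c, p))
  t16 <- simulate_thermal_observations(p, temps = 16, n_reps = 1,
                                       noise_sd = 0, seed = 1)
  expect_equal(t16$growth_rate_per_day, 0.379002, tolerance = 1e-6)
  expect_error(simulate_thermal_observations(p, temps = numeric()),
               class = "invalid_parameter")
})

test_that("thermal observations honour the seed contract", {
  p <- do.call(norberg_params, table1_rows$diatom_ambient$params)
  a <- simulate_thermal_observations(p, noise_sd = 0.1, seed = 5)
  b <- simulate_thermal_observations(p, noise_sd = 0.1, seed = 5)
  c <- simulate_thermal_observations(p, noise_sd = 0.1, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
  resid <- a$growth_rate_per_day - norberg_growth(a$temperature_c, p)
  expect_lt(max(abs(resid)), 0.5)   # Gaussian(0, 0.1) residuals
})

test_that("simulated ASV tables have exact depths and bounded richness", {
  profiles <- list(LA = community_profile(n_asvs = 13, depth = 10000),
                   LW = community_profile(n_asvs = 17, depth = 10000))
  tab <- simulate_asv_table(profiles, seed = 2)
  expect_s3_class(tab, "asv_table")
  expect_true(all(rowSums(tab$counts) == 10000L))
  rich <- apply(tab$counts, 1, function(x) sum(x > 0))
  expect_true(all(rich[1:3] <= 13))
  expect_true(all(rich[4:6] <= 17))
  expect_identical(simulate_asv_table(profiles, seed = 2)$counts,
                   tab$counts)
})

test_that("dominant fraction concentrates at large depth (law of large numbers)", {
  pr <- list(G = community_profile(n_asvs = 17, dominant_fraction = 0.5,
                                   depth = 1e6, n_replicates = 1))
  tab <- simulate_asv_table(pr, seed = 4)
  top <- max(tab$counts) / sum(tab$counts)
  expect_lt(abs(top - 0.5), 0.01)
})

test_that("infeasible community profiles error", {
  expect_error(community_profile(n_asvs = 1, dominant_fraction = 0.5),
               class = "invalid_parameter")
  expect_error(community_profile(n_asvs = 10, dominant_fraction = 1.2),
               class = "invalid_parameter")
})

test_that("metabolite simulation enforces class folds exactly at cv = 0", {
  cm <- c(ala = "amino_acid", glu = "amino_acid", gluc = "carbohydrate",
          form = "other")
  bl <- c(ala = 1, glu = 0.5, gluc = 2, form = 0)
  spec0 <- metabolite_effect_spec(cm, bl, c(amino_acid = 1,
                                            carbohydrate = 1, other = 1),
                                  cv = 0)
  tab0 <- simulate_metabolite_table(spec0, n_per_group = 2, seed = 1)
  g <- tab0$sample_map$group
  expect_equal(unname(tab0$concentrations[g == "A", ]),
               unname(tab0$concentrations[g == "B", ]))

  spec <- metabolite_effect_spec(cm, bl, c(amino_acid = 5.21,
                                           carbohydrate = 0.4, other = 1),
                                 cv = 0)
  tab <- simulate_metabolite_table(spec, n_per_group = 3, seed = 1)
  fc <- fold_change(tab, "B", "A")
  expect_equal(fc$fc[fc$class == "amino_acid"], c(5.21, 5.21))
  expect_equal(fc$fc[fc$class == "carbohydrate"], 0.4)
  expect_true(all(tab$concentrations > 0))
})

test_that("metabolite simulation is seeded and rejects unknown classes", {
  cm <- c(m1 = "amino_acid", m2 = "mystery")
  expect_error(metabolite_effect_spec(cm, c(m1 = 0, m2 = 0),
                                      c(amino_acid = 1), cv = 0.1),
               class = "unknown_class")
  cm2 <- c(m1 = "amino_acid", m2 = "other")
  spec <- metabolite_effect_spec(cm2, c(m1 = 0, m2 = 0),
                                 c(amino_acid = 2, other = 1), cv = 0.3)
  a <- simulate_metabolite_table(spec, n_per_group = 3, seed = 8)
  b <- simulate_metabolite_table(spec, n_per_group = 3, seed = 8)
  expect_identical(a$concentrations, b$concentrations)
})

test_that("derived stream seeds are deterministic and distinct", {
  expect_identical(derive_stream_seed(1, "thermal"),
                   derive_stream_seed(1, "thermal"))
  expect_false(derive_stream_seed(1, "thermal") ==
                 derive_stream_seed(1, "community"))
  expect_false(derive_stream_seed(1, "thermal") ==
                 derive_stream_seed(2, "thermal"))
})
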