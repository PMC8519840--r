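test_that("identical seeds give identical trials", {
  cfg <- sim_config(n_cages_per_diet = 2)
  a <- simulate_trial(cfg, seed = 5)
  b <- simulate_trial(cfg, seed = 5)
  expect_identical(a$feeding_records, b$feeding_records)
  expect_identical(a$controls, b$controls)
  expect_identical(a$truth, b$truth)
  c <- simulate_trial(cfg, seed = 6)
  expect_false(identical(a$feeding_records, c$feeding_records))
})

test_that("noiseless, death-free trials are inverted exactly by the pipeline", {
  for (rule in c("equal_distance", "no_interaction_c", "closest_distance")) {
    sim <- simulate_trial(noiseless_config(rule, n_cages_per_diet = 2),
                          seed = 1)
    intake <- compute_intake(sim$feeding_records, sim$controls, sim$panel)
    merged <- merge(intake, sim$truth, by = c("cage_id", "diet_id"),
                    suffixes = c("", ".true"))
    expect_equal(nrow(merged), nrow(sim$truth))
    expect_true(all(abs(merged$aa_mmol_per_bee -
                        merged$aa_mmol_per_bee.true) < 1e-12))
    expect_true(all(abs(merged$c_mmol_per_bee -
                        merged$c_mmol_per_bee.true) < 1e-12))
  }
})

test_that("an undefined rule on the sucrose-only rail is substituted or excluded", {
  cfg <- noiseless_config("no_interaction_aa", n_cages_per_diet = 1)
  expect_message(sim <- simulate_trial(cfg, seed = 1), "closest_distance")
  expect_true("0:1" %in% sim$truth$diet_id)

  cfg2 <- noiseless_config("no_interaction_aa", n_cages_per_diet = 1,
                           undefined_rail = "exclude")
  expect_message(sim2 <- simulate_trial(cfg2, seed = 1), "excluded")
  expect_false("0:1" %in% sim2$truth$diet_id)
  # the defined rails all regulate amino acid exactly
  tgt <- cfg2$target[["aa"]]
  expect_true(all(abs(sim2$truth$aa_mmol_per_bee - tgt) < 1e-12))
})

test_that("per-diet mean intake stays within 3 SE of the rule projection under noise", {
  cfg <- sim_config("closest_distance", n_cages_per_diet = 30,
                    mass_noise_sd = 0.02, daily_death_prob = 0)
  sim <- simulate_trial(cfg, seed = 21)
  intake <- compute_intake(sim$feeding_records, sim$controls, sim$panel)
  means <- intake_means(intake, sim$panel)
  z <- numeric(0)
  for (i in seq_len(nrow(means))) {
    truth <- sim$truth[sim$truth$diet_id == means$diet_id[i], ][1, ]
    z <- c(z, abs(means$mean_c_mmol[i] - truth$c_mmol_per_bee) /
             means$se_c[i])
    if (means$se_aa[i] > 0) {
      z <- c(z, abs(means$mean_aa_mmol[i] - truth$aa_mmol_per_bee) /
               means$se_aa[i])
    } else {
      expect_equal(means$mean_aa_mmol[i], truth$aa_mmol_per_bee)
    }
  }
  # 14 simultaneous 3-SE checks: allow a single marginal exceedance
  expect_true(all(z < 4))
  expect_gte(sum(z < 3), length(z) - 1L)
})

test_that("the death process matches its expected bee-days within 3 SE", {
  p <- 0.1
  cfg <- sim_config(ratios = list(c(1, 50)), n_cages_per_diet = 100,
                    daily_death_prob = p, mass_noise_sd = 0)
  sim <- simulate_trial(cfg, seed = 13)
  per_cage <- tapply(sim$feeding_records$n_alive,
                     sim$feeding_records$cage_id, sum)
  expected <- cfg$n_bees * sum((1 - p)^(seq_len(cfg$n_days) - 1))
  se <- stats::sd(per_cage) / sqrt(length(per_cage))
  expect_lt(abs(mean(per_cage) - expected), 3 * se)
  # n_alive never increases within a cage
  drops <- tapply(sim$feeding_records$n_alive,
                  sim$feeding_records$cage_id,
                  function(v) all(diff(v) <= 0))
  expect_true(all(drops))
})

test_that("slope-estimate RMSE grows with measurement noise", {
  noise_levels <- c(0.005, 0.05, 0.5)
  rmse <- vapply(noise_levels, function(ns) {
    errs <- vapply(1:25, function(s) {
      cfg <- sim_config("equal_distance", n_cages_per_diet = 3,
                        mass_noise_sd = ns, evap_sd = 0,
                        daily_death_prob = 0)
      sim <- simulate_trial(cfg, seed = 1000 + s)
      rep <- recovery_report(sim, classify = FALSE)
      rep$array$slope - (-1)
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("recovery_report recovers rule diagnostics on noiseless trials", {
  sim <- simulate_trial(noiseless_config("equal_distance",
                                         n_cages_per_diet = 1), seed = 2)
  rep <- suppressMessages(recovery_report(sim, grid_n = 60))
  expect_equal(rep$array$slope, -1, tolerance = 1e-9)
  expect_equal(rep$rule_fit$best_rule, "equal_distance")
  expect_true(rep$rule_recovered)
  # under equal distance only T_aa + T_c is identifiable
  est_sum <- rep$rule_fit$ranking$target_aa[1] + rep$rule_fit$ranking$target_c[1]
  expect_equal(est_sum, sum(sim$config$target), tolerance = 1e-4)

  sim0 <- simulate_trial(noiseless_config("no_interaction_c",
                                          n_cages_per_diet = 1), seed = 2)
  rep0 <- suppressMessages(recovery_report(sim0, grid_n = 60))
  expect_equal(rep0$array$slope, 0, tolerance = 1e-9)
  expect_equal(rep0$rule_fit$best_rule, "no_interaction_c")
})

test_that("simulated trials round-trip through the CSV writers", {
  sim <- simulate_trial(noiseless_config("closest_distance",
                                         n_cages_per_diet = 1), seed = 4)
  dir <- tempfile("trial")
  paths <- write_trial_csv(sim, dir)
  expect_true(all(file.exists(paths)))
  feeding <- utils::read.csv(paths[["feeding_records"]])
  controls <- utils::read.csv(paths[["controls"]])
  intake <- compute_intake(feeding, controls, sim$panel)
  truth <- utils::read.csv(paths[["truth"]])
  expect_equal(intake$c_mmol_per_bee[order(intake$cage_id)],
               truth$c_mmol_per_bee[order(truth$cage_id)],
               tolerance = 1e-9)
})
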