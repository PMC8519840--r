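test_that("array slope and its standard error match a hand OLS oracle", {
  arr <- fit_intake_array(data.frame(aa = c(0, 1, 2), c = c(1, 3, 2)))
  expect_equal(unname(coef(arr)), c(1.5, 0.5))
  expect_equal(arr$slope_se, sqrt(1.5 / 2), tolerance = 1e-10)
  expect_equal(arr$n_diets, 3)

  collinear <- fit_intake_array(data.frame(aa = 0:2, c = 2:0))
  expect_equal(collinear$slope, -1)
  expect_equal(collinear$slope_se, 0, tolerance = 1e-12)

  rising <- fit_intake_array(data.frame(aa = 0:2, c = 0:2))
  expect_equal(rising$slope, 1)

  expect_error(fit_intake_array(data.frame(aa = c(1, 1, 1), c = 1:3)),
               "undefined slope")
  expect_error(fit_intake_array(data.frame(aa = 0:1, c = 0:1)), ">= 3 diets")
})

test_that("array methods expose the fit like a standard model object", {
  arr <- fit_intake_array(data.frame(aa = c(0, 1, 2), c = c(1, 3, 2)))
  expect_equal(predict(arr, newdata = c(0, 2)), c("1" = 1.5, "2" = 2.5))
  expect_equal(unname(fitted(arr)), c(1.5, 2.0, 2.5))
  expect_equal(sum(residuals(arr)), 0, tolerance = 1e-12)
  expect_output(print(arr), "slope")
  expect_output(print(summary(arr)), "Slope tests")
})

test_that("per-cage intake feeds the array via per-diet means", {
  sim <- simulate_trial(noiseless_config("equal_distance",
                                         n_cages_per_diet = 2), seed = 3)
  intake <- compute_intake(sim$feeding_records, sim$controls, sim$panel)
  arr <- fit_intake_array(intake, panel = sim$panel)
  expect_equal(arr$n_diets, 7)
  expect_equal(arr$slope, -1, tolerance = 1e-9)
  cage_fit <- fit_intake_array(intake, panel = sim$panel, use = "cages")
  expect_equal(cage_fit$n_points, 14)
  expect_equal(cage_fit$slope, -1, tolerance = 1e-9)
})

test_that("slope test reproduces the t formula with n - 2 degrees of freedom", {
  # printed slope/SE pairs of the reference trial
  st <- slope_test(-0.127, beta_h = 0, se = 1.05, n_diets = 7)
  expect_equal(st$df, 5)
  expect_equal(st$t_stat, -0.127 / 1.05, tolerance = 1e-12)
  expect_equal(st$t_stat, -0.121, tolerance = 1e-3)

  st2 <- slope_test(-1.68, beta_h = -1, se = 1.05, n_diets = 7)
  expect_equal(st2$t_stat, (-1.68 + 1) / 1.05, tolerance = 1e-12)
  expect_equal(st2$t_stat, -0.648, tolerance = 1e-3)
  expect_equal(st2$p_two_tailed,
               2 * stats::pt(-abs(st2$t_stat), 5), tolerance = 1e-12)

  # slope equal to the hypothesis
  eq <- slope_test(-1, beta_h = -1, se = 0.5, n_diets = 7)
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p_two_tailed, 1)
})

test_that("slope test handles exact fits and is antisymmetric in (beta_a, beta_h)", {
  exact <- slope_test(-1, beta_h = 0, se = 0, n_diets = 7)
  expect_true(exact$exact_fit)
  expect_equal(exact$p_two_tailed, 0)
  same <- slope_test(-1, beta_h = -1, se = 0, n_diets = 7)
  expect_equal(same$p_two_tailed, 1)

  a <- slope_test(-1.3, beta_h = -0.2, se = 0.4, n_diets = 7)
  b <- slope_test(-0.2, beta_h = -1.3, se = 0.4, n_diets = 7)
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$p_two_tailed, b$p_two_tailed)

  expect_error(slope_test(-1, beta_h = 0, se = 1, n_diets = 2), ">= 3")
})

test_that("classify_rule recovers the generating rule from noiseless arrays", {
  panel <- build_diet_panel()
  as_means <- function(pts) data.frame(diet_id = pts$diet_id,
                                       mean_aa_mmol = pts$aa_mmol,
                                       mean_c_mmol = pts$c_mmol)

  truth <- predict_rule_points("equal_distance", c(aa = 1, c = 4), panel)
  fit <- suppressMessages(classify_rule(as_means(truth), panel, grid_n = 60))
  expect_equal(fit$best_rule, "equal_distance")
  expect_lt(fit$ranking$sse[1], 1e-12)
  # the equal-distance projection depends on the target only through
  # T_aa + T_c, so only that sum is identifiable
  expect_equal(fit$ranking$target_aa[1] + fit$ranking$target_c[1], 5,
               tolerance = 1e-4)

  truth <- predict_rule_points("no_interaction_c", c(aa = 1, c = 4), panel)
  fit <- suppressMessages(classify_rule(as_means(truth), panel, grid_n = 60))
  expect_equal(fit$best_rule, "no_interaction_c")
  # a carbohydrate-only array is flat
  arr <- fit_intake_array(data.frame(aa = truth$aa_mmol, c = truth$c_mmol))
  expect_equal(arr$slope, 0, tolerance = 1e-12)

  truth <- predict_rule_points("closest_distance", c(aa = 0.08, c = 3), panel)
  fit <- suppressMessages(classify_rule(as_means(truth), panel, grid_n = 60))
  expect_equal(fit$best_rule, "closest_distance")
})

test_that("classify_rule validates its inputs", {
  panel <- build_diet_panel()
  obs <- data.frame(diet_id = c("1:10", "1:10", "1:10"),
                    mean_aa_mmol = c(1, 1, 1), mean_c_mmol = c(1, 2, 3))
  expect_error(suppressMessages(classify_rule(obs, panel, grid_n = 20)),
               "duplicated rail")
  good <- data.frame(diet_id = c("0:1", "1:25"), mean_aa_mmol = c(0, 1),
                     mean_c_mmol = c(3, 2))
  expect_error(classify_rule(good, panel), ">= 3 diets")
  obs3 <- data.frame(diet_id = c("0:1", "1:25", "1:10"),
                     mean_aa_mmol = c(0, 0.5, 1), mean_c_mmol = c(3, 2.5, 2))
  expect_error(classify_rule(obs3, panel, grid_n = 1), "grid")
})
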