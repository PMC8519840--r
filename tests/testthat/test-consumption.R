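test_that("evaporation correction uses the per-diet control mean", {
  ctl <- make_controls(losses = c(0.1, 0.1, 0.1))
  expect_equal(evaporation_mean(ctl, "1:10"), 0.1)
  expect_equal(evaporation_mean(make_controls(losses = c(0.05, 0.15)), "1:10"),
               0.10)
  expect_error(evaporation_mean(ctl, "1:25"), "missing control")

  both <- rbind(make_controls("1:10", c(0.1, 0.2)),
                make_controls("0:1", c(0.3, 0.3)))
  expect_equal(evaporation_mean(both),
               c("0:1" = 0.3, "1:10" = 0.15))
})

test_that("daily consumed mass is tube change minus evaporation, negatives retained", {
  rec <- list(tube1_pre_g = 5, tube1_post_g = 4.5,
              tube2_pre_g = 5, tube2_post_g = 4.7)
  expect_equal(daily_consumption_mass(rec, 0.10), 0.70)

  flat <- list(tube1_pre_g = 5, tube1_post_g = 5,
               tube2_pre_g = 5, tube2_post_g = 5)
  expect_equal(daily_consumption_mass(flat, 0), 0)
  expect_warning(m <- daily_consumption_mass(flat, 0.05), "exceeds")
  expect_equal(m, -0.05)
})

test_that("per-individual volume divides by survivors then density", {
  expect_equal(per_bee_volume(1.06, 1, 1.06), 1)
  expect_equal(per_bee_volume(5.30, 5, 1.06), 1)
  expect_equal(per_bee_volume(0, 5, 1.06), 0)
  expect_error(per_bee_volume(1, 0, 1.06), "n_alive")
})

test_that("volume times molarity gives millimoles on the diet rail", {
  sucrose_only <- diet(0, 1, 0.5)
  expect_equal(nutrient_intake(1, sucrose_only),
               c(aa_mmol = 0, c_mmol = 0.5))
  d10 <- diet(1, 10, 0.5)
  expect_equal(nutrient_intake(1, d10), c(aa_mmol = 0.05, c_mmol = 0.5))
  expect_equal(nutrient_intake(0, d10), c(aa_mmol = 0, c_mmol = 0))
  # linearity and the rail ratio invariant
  v <- c(0.3, 1.7)
  ni <- vapply(v, nutrient_intake, numeric(2), diet = d10)
  expect_equal(ni[, 2], ni[, 1] * (v[2] / v[1]))
  expect_equal(unname(ni["c_mmol", ] / ni["aa_mmol", ]), c(10, 10))
})

test_that("cumulative intake matches a day-by-day hand oracle, deaths included", {
  d10 <- diet(1, 10, 0.5)
  ctl <- make_controls(losses = rep(0.1, 7))

  # 7 identical days each yielding 1.0 ml per bee: drops sum to 5.40 g,
  # minus 0.10 g evap = 5.30 g over 5 bees at 1.06 g/ml
  recs <- make_feeding(tube1_drop = 2.7, tube2_drop = 2.7, n_alive = 5)
  pt <- cumulative_intake(recs, ctl, d10)
  expect_equal(pt$volume_ml_per_bee, 7)
  expect_equal(pt$aa_mmol_per_bee, 0.35)
  expect_equal(pt$c_mmol_per_bee, 3.5)

  # all-zero days with zero evaporation
  zero <- cumulative_intake(make_feeding(tube1_drop = 0, tube2_drop = 0),
                            make_controls(losses = rep(0, 7)), d10)
  expect_equal(zero$aa_mmol_per_bee, 0)
  expect_equal(zero$c_mmol_per_bee, 0)

  # one death mid-trial: independent loop oracle
  recs <- make_feeding(tube1_drop = 2.7, tube2_drop = 2.7, n_alive = 5)
  recs$n_alive[4:7] <- 4
  pt <- cumulative_intake(recs, ctl, d10)
  oracle_vol <- sum(vapply(seq_len(7), function(day) {
    mass <- (2.7 + 2.7) - 0.1
    (mass / recs$n_alive[day]) / 1.06
  }, numeric(1)))
  expect_equal(pt$volume_ml_per_bee, oracle_vol)
  expect_equal(pt$aa_mmol_per_bee, oracle_vol * 0.05)
})

test_that("accounting conserves mass through the volume round trip", {
  d <- diet(1, 25, 0.5)
  ctl <- make_controls("1:25", rep(0.08, 7))
  recs <- make_feeding(diet_id = "1:25", tube1_drop = 1.3, tube2_drop = 0.9,
                       n_alive = 5)
  pt <- cumulative_intake(recs, ctl, d)
  corrected_total <- 7 * ((1.3 + 0.9) - 0.08)  # per-day corrected mass x 7 days
  expect_lt(abs(pt$volume_ml_per_bee * 1.06 * 5 - corrected_total), 1e-9)
  # mass -> volume -> mmol -> volume closes
  expect_lt(abs(pt$c_mmol_per_bee / 0.5 - pt$volume_ml_per_bee), 1e-9)
})

test_that("degenerate cage-days are skipped or flagged, not silently dropped", {
  d <- diet(1, 10, 0.5)
  ctl <- make_controls(losses = rep(0, 7))

  recs <- make_feeding(tube1_drop = 0.5, tube2_drop = 0.5)
  recs$n_alive[7] <- 0
  expect_message(pt <- cumulative_intake(recs, ctl, d), "no survivors")
  expect_equal(pt$volume_ml_per_bee, 6 * (1 / 5) / 1.06)

  gap <- make_feeding(days = 7)[-3, ]
  expect_warning(cumulative_intake(gap, ctl, d), "gap")

  # floor-at-zero switch clamps negative corrected days
  neg <- make_feeding(tube1_drop = 0, tube2_drop = 0, days = 2)
  ctl2 <- make_controls(losses = rep(0.2, 2))
  w <- capture_warnings(kept <- cumulative_intake(neg, ctl2, d))
  expect_true(any(grepl("exceeds measured", w)))
  expect_true(any(grepl("negative cumulative", w)))
  expect_lt(kept$volume_ml_per_bee, 0)
  floored <- suppressWarnings(
    cumulative_intake(neg, ctl2, d, floor_negative = TRUE))
  expect_equal(floored$volume_ml_per_bee, 0)
})

test_that("compute_intake processes every cage and validates its inputs", {
  feeding <- rbind(make_feeding("c1", "1:10", tube1_drop = 1, tube2_drop = 1),
                   make_feeding("c2", "0:1", tube1_drop = 0.6,
                                tube2_drop = 0.4))
  controls <- rbind(make_controls("1:10", rep(0.1, 7)),
                    make_controls("0:1", rep(0.1, 7)))
  panel <- build_diet_panel()
  out <- compute_intake(feeding, controls, panel)
  expect_equal(nrow(out), 2)
  expect_equal(out$aa_mmol_per_bee[out$diet_id == "0:1"], 0)

  expect_error(compute_intake(feeding[, -3], controls, panel), "lack columns")
  bad <- feeding
  bad$diet_id <- "9:9"
  expect_error(compute_intake(bad, controls, panel), "absent from the panel")
})
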