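make_cells <- function(...) {
  tibble::tibble(...)
}

test_that("aggregation applies the ceiling rule and conserves trial counts", {
  trials <- simulate_experiment(observer_params(), both_specs(2L),
                                n_subjects = 2, seed = 21)
  cells <- aggregate_cells(trials, c("subject", "cue_type", "validity"))
  expect_equal(sum(cells$n_trials), nrow(trials))
  expect_true(all(cells$pc_corrected > 0 & cells$pc_corrected < 1))
  expect_equal(cells$dprime, dprime_from_pc(cells$pc_corrected))

  # explicit ceiling cell: 10/10 correct becomes pc 0.95
  toy <- tibble::tibble(
    subject_id = "S01", cue_type = "exogenous", validity = "valid",
    ctoa_ms = 50, post_cue_pos = 1L, correct = rep(TRUE, 10))
  cell <- aggregate_cells(toy, c("subject", "validity"))
  expect_equal(cell$pc_corrected, 0.95)
  expect_equal(cell$dprime, dprime_from_pc(0.95))

  toy$correct <- rep(c(TRUE, FALSE), 5)
  expect_equal(aggregate_cells(toy, "subject")$pc_corrected, 0.5)

  # empty grouping: one cell holding the table totals
  total <- aggregate_cells(trials, character(0))
  expect_equal(total$n_trials, nrow(trials))
  expect_equal(total$n_correct, sum(trials$correct))

  expect_error(aggregate_cells(trials, "condition"), "unknown grouping")
})

test_that("benefit, cost and total effect follow their definitions", {
  cells <- make_cells(
    subject_id = "S01", cue_type = "exogenous", ctoa_ms = 50,
    validity = c("valid", "neutral", "invalid"),
    dprime = c(2.55, 2.33, 2.03)
  )
  eff <- cue_effects(cells)
  expect_equal(eff$benefit, 0.22)
  expect_equal(eff$cost, 0.30)
  expect_equal(eff$total_effect, eff$benefit + eff$cost)

  flat <- cells
  flat$dprime <- 2
  eff0 <- cue_effects(flat)
  expect_equal(c(eff0$benefit, eff0$cost, eff0$total_effect), c(0, 0, 0))
})

test_that("missing validity levels yield NA statistics, and endogenous has no cost", {
  endo <- make_cells(
    subject_id = "S01", cue_type = "endogenous", ctoa_ms = 600,
    validity = c("valid", "neutral"), dprime = c(2.6, 2.3)
  )
  eff <- cue_effects(endo)
  expect_equal(eff$benefit, 0.3)
  expect_true(is.na(eff$cost))
  expect_true(is.na(eff$total_effect))

  no_neutral <- make_cells(
    subject_id = "S01", cue_type = "exogenous", ctoa_ms = 50,
    validity = c("valid", "invalid"), dprime = c(2.6, 2.0)
  )
  eff2 <- cue_effects(no_neutral)
  expect_true(is.na(eff2$benefit))
  expect_true(is.na(eff2$cost))
  expect_equal(eff2$total_effect, 0.6)
})

test_that("total effect equals benefit plus cost to machine precision", {
  trials <- simulate_experiment(observer_params(),
                                design_spec("exogenous", trials_per_cell = 3L),
                                n_subjects = 3, seed = 22)
  eff <- cue_effects(aggregate_cells(trials,
                                     c("subject", "cue_type", "validity",
                                       "ctoa")))
  ok <- complete.cases(eff$benefit, eff$cost)
  expect_true(any(ok))
  expect_equal(eff$total_effect[ok], eff$benefit[ok] + eff$cost[ok],
               tolerance = 1e-12)
})

test_that("the benefit function aggregates positions with equal weights", {
  records <- expand.grid(subject_id = sprintf("S%02d", 1:4),
                         post_cue_pos = 1:6, stringsAsFactors = FALSE)
  records$cue_type <- "exogenous"
  records$ctoa_ms <- 50
  b <- 0.4
  records$benefit <- c(0, b, b, 0, b, 0)[records$post_cue_pos]

  summ <- benefit_function(records)
  expect_equal(summ$benefit_by_position$mean_benefit,
               c(0, b, b, 0, b, 0))
  crowd <- summ$crowding_benefit
  expect_equal(crowd$mean_benefit[crowd$crowding == "crowded"], b)
  expect_equal(crowd$mean_benefit[crowd$crowding == "uncrowded"], 0)
  hemi <- summ$hemifield_benefit
  expect_equal(hemi$mean_benefit[hemi$hemifield == "left"], 2 * b / 3)
  expect_equal(hemi$mean_benefit[hemi$hemifield == "right"], b / 3)

  # flat benefits: every aggregate equals the common value
  records$benefit <- 0.25
  summ2 <- benefit_function(records)
  expect_true(all(abs(summ2$hemifield_benefit$mean_benefit - 0.25) < 1e-12))
  expect_true(all(abs(summ2$crowding_benefit$mean_benefit - 0.25) < 1e-12))
})

test_that("hemifield means equal the equal-weight mean of member positions", {
  trials <- simulate_experiment(observer_params(), both_specs(3L),
                                n_subjects = 4, seed = 23)
  eff <- cue_effects(aggregate_cells(
    trials, c("subject", "cue_type", "validity", "ctoa", "position")))
  summ <- benefit_function(eff)
  by_pos <- summ$benefit_by_position
  for (ct in unique(by_pos$cue_type)) {
    left <- mean(by_pos$mean_benefit[by_pos$cue_type == ct &
                                       by_pos$post_cue_pos <= 3])
    got <- summ$hemifield_benefit$mean_benefit[
      summ$hemifield_benefit$cue_type == ct &
        summ$hemifield_benefit$hemifield == "left"]
    expect_equal(got, left)
  }
})

test_that("the mixed-model formula emits the canonical string", {
  expect_equal(
    mixed_model_formula(c("cue_validity", "CTOA"),
                        "cue_validity + CTOA | subject"),
    "d\u2019 = cue_validity + CTOA + (cue_validity + CTOA | subject)"
  )
  expect_equal(mixed_model_formula("position", response = "d\u2019"),
               "d\u2019 = position")
  expect_equal(
    mixed_model_formula(c("CTOA", "CTOA", "cue_validity")),
    "d\u2019 = CTOA + cue_validity"
  )
  expect_error(mixed_model_formula("reading_score"), "unknown model term")
  expect_error(mixed_model_formula("CTOA", "CTOA | session"),
               "unknown model term")
})
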