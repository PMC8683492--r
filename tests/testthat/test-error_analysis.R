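worked_example <- function(responses) {
  tibble::tibble(letters = "KNBTYP", post_cue_pos = 5L,
                 response = responses)
}

test_that("the KNBTYP worked example classifies exactly as defined", {
  cls <- classify_response(worked_example(c("Y", "T", "P", "V", "K")))
  expect_equal(cls$error_class,
               c("correct", "transposition", "transposition",
                 "misidentification", "other_intrusion"))
})

test_that("classification is a total four-way partition with edge positions", {
  # at position 1 only position 2 is adjacent; 3 and 4 are neighbours
  tr <- tibble::tibble(letters = "KNBTYP",
                       post_cue_pos = c(1L, 1L, 3L, 4L),
                       response = c("N", "B", "T", "B"))
  expect_equal(classify_response(tr)$error_class,
               c("transposition", "other_intrusion", "transposition",
                 "transposition"))

  trials <- simulate_experiment(observer_params(), both_specs(2L),
                                n_subjects = 2, seed = 31)
  cls <- classify_response(trials)
  expect_false(any(is.na(cls$error_class)))
  expect_setequal(unique(cls$error_class[cls$correct]), "correct")
  counts <- table(cls$error_class)
  expect_equal(sum(counts), nrow(trials))
})

test_that("classification is invariant to left-right mirroring", {
  trials <- simulate_experiment(observer_params(), both_specs(1L),
                                n_subjects = 2, seed = 32)
  cls <- classify_response(trials)$error_class
  mirrored <- trials
  mirrored$letters <- vapply(strsplit(trials$letters, ""),
                             function(l) paste(rev(l), collapse = ""),
                             character(1))
  mirrored$post_cue_pos <- 7L - trials$post_cue_pos
  expect_equal(classify_response(mirrored)$error_class, cls)
})

test_that("responses outside the response set are a data error", {
  expect_error(classify_response(worked_example("Q")),
               "outside the 12-letter response set")
})

test_that("error profiles are proportions of total trials summing to one", {
  trials <- tibble::tibble(
    cue_type = "exogenous", validity = "neutral", ctoa_ms = 100,
    post_cue_pos = 5L, letters = "KNBTYP",
    response = c(rep("Y", 8), "T", "P")
  )
  prof <- error_profile(trials, c("cue_type", "validity", "position"))
  expect_equal(prof$p_correct, 0.8)
  expect_equal(prof$p_transposition, 0.2)
  expect_equal(prof$p_misidentification, 0)
  expect_equal(prof$p_other_intrusion, 0)

  sim <- classify_response(simulate_experiment(observer_params(),
                                               both_specs(2L),
                                               n_subjects = 2, seed = 33))
  prof2 <- error_profile(sim)
  sums <- prof2$p_correct + prof2$p_transposition +
    prof2$p_misidentification + prof2$p_other_intrusion
  expect_equal(sums, rep(1, nrow(prof2)), tolerance = 1e-12)

  # all-correct cell
  allc <- trials
  allc$response <- "Y"
  prof3 <- error_profile(allc, c("cue_type", "validity"))
  expect_equal(prof3$p_transposition + prof3$p_misidentification +
                 prof3$p_other_intrusion, 0)
})

test_that("delta error linearises with the probit and the 1/(2n) floor rule", {
  prof_n <- tibble::tibble(cue_type = "endogenous", post_cue_pos = 2L,
                           n_trials = 1000,
                           p_transposition = 0.5,
                           p_misidentification = 0.3)
  prof_v <- tibble::tibble(cue_type = "endogenous", post_cue_pos = 2L,
                           n_trials = 1000,
                           p_transposition = pnorm(-1),
                           p_misidentification = 0.3)
  d <- delta_error(prof_n, prof_v)
  expect_equal(d$delta[d$error_type == "transposition"], 1)
  expect_equal(d$delta[d$error_type == "misidentification"], 0)

  # a zero error proportion is floored at 1/(2n) before the transform
  prof_v0 <- prof_v
  prof_v0$n_trials <- 30
  prof_v0$p_transposition <- 0
  d0 <- delta_error(prof_n, prof_v0)
  expect_equal(d0$delta[d0$error_type == "transposition"],
               qnorm(0.5) - qnorm(1 / 60))
})

test_that("delta error is antisymmetric in its two profiles", {
  trials <- classify_response(simulate_experiment(observer_params(),
                                                  design_spec("endogenous",
                                                              trials_per_cell = 3L),
                                                  n_subjects = 4, seed = 34))
  prof <- error_profile(trials)
  pn <- prof[prof$validity == "neutral", setdiff(names(prof), "validity")]
  pv <- prof[prof$validity == "valid", setdiff(names(prof), "validity")]
  fwd <- delta_error(pn, pv)
  rev <- delta_error(pv, pn)
  expect_equal(fwd$delta, -rev$delta)
})

test_that("endogenous valid cues shrink transposition errors most at crowded positions", {
  hits <- 0
  for (seed in 41:50) {
    trials <- simulate_experiment(observer_params(),
                                  design_spec("endogenous"),
                                  n_subjects = 28, seed = seed)
    prof <- error_profile(trials, c("cue_type", "validity", "position"),
                          ctoa_restrict = c(endogenous = 600))
    pn <- prof[prof$validity == "neutral", setdiff(names(prof), "validity")]
    pv <- prof[prof$validity == "valid", setdiff(names(prof), "validity")]
    d <- delta_error(pn, pv)
    dt <- d[d$error_type == "transposition", ]
    contrast <- mean(dt$delta[dt$post_cue_pos %in% c(2, 5)]) -
      mean(dt$delta[dt$post_cue_pos %in% c(1, 6)])
    hits <- hits + (contrast > 0)
  }
  expect_gte(hits, 9)
})
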