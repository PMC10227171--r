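# Trial scoring: validity, the correct/incorrect truth table, response
# times, TTC prediction error, aggregation and participant exclusion.

test_that("correctness reproduces the response definition on all four cases", {
  p <- noiseless_params()
  # perturbation + saccade to the cross -> correct
  tlp <- ref_timeline(speed = 3, occlusion = 1.0)
  s1 <- simulate_trial(tlp, p, "saccade", seed = 1)
  sc1 <- score_trial(s1$gaze, tlp, buttons = s1$events, mode = "saccade")
  expect_true(sc1$valid); expect_true(sc1$correct)
  # perturbation + pursuit only (missed) -> incorrect
  s2 <- simulate_trial(tlp, noiseless_params(miss_rate = 1), "saccade", seed = 2)
  sc2 <- score_trial(s2$gaze, tlp, buttons = s2$events, mode = "saccade")
  expect_true(sc2$valid); expect_false(sc2$correct)
  # no perturbation + pursuit only -> correct
  tlc <- ref_timeline(speed = 4, occlusion = 1.0)
  s3 <- simulate_trial(tlc, p, "saccade", seed = 3)
  sc3 <- score_trial(s3$gaze, tlc, buttons = s3$events, mode = "saccade")
  expect_true(sc3$correct)
  # no perturbation + saccade to the cross (false alarm) -> incorrect
  s4 <- simulate_trial(tlc, noiseless_params(false_alarm_rate = 1), "saccade",
                       seed = 4)
  sc4 <- score_trial(s4$gaze, tlc, buttons = s4$events, mode = "saccade")
  expect_false(sc4$correct)
})

test_that("relative TTC is 0% at change onset and 100% at the true TTC", {
  tl <- ref_timeline(speed = 3, occlusion = 1.0)
  sim <- simulate_trial(tl, noiseless_params(), seed = 1)
  press_at <- function(time) tibble::tibble(time = time, kind = "ttc_response")
  sc_onset <- score_trial(sim$gaze, tl, buttons = press_at(tl$change_onset),
                          mode = "saccade")
  expect_equal(sc_onset$relative_ttc, 0)
  sc_ttc <- score_trial(sim$gaze, tl, buttons = press_at(tl$ttc),
                        mode = "saccade")
  expect_equal(sc_ttc$relative_ttc, 100)
  expect_equal(sc_ttc$ttc_error, 0)
})

test_that("TTC error follows timeline arithmetic (press 0.25 s after occlusion)", {
  # speed 5, occlusion 1.5 s: 0.50 s remain between occlusion and TTC
  tl <- ref_timeline(speed = 5, occlusion = 1.5)
  sim <- simulate_trial(tl, noiseless_params(), seed = 1)
  b <- tibble::tibble(time = tl$occlusion_time + 0.25, kind = "ttc_response")
  sc <- score_trial(sim$gaze, tl, buttons = b, mode = "saccade")
  expect_equal(sc$ttc_error, 0.25 - 0.50)
})

test_that("relative TTC is affine in press time and origin-invariant", {
  tl <- ref_timeline(speed = 4, occlusion = 1.0)
  sim <- simulate_trial(tl, noiseless_params(), seed = 2)
  rel <- vapply(c(0, 0.5, 1, 1.7, 2.5), function(dt) {
    b <- tibble::tibble(time = tl$change_onset + dt, kind = "ttc_response")
    score_trial(sim$gaze, tl, buttons = b, mode = "saccade")$relative_ttc
  }, numeric(1))
  span <- tl$ttc - tl$change_onset
  expect_equal(rel, 100 * c(0, 0.5, 1, 1.7, 2.5) / span)
})

test_that("validity uses a strict 3-degree threshold on the phase distance", {
  # gaze tracking the target with a constant 2.9 deg offset stays valid;
  # with a 3.1 deg offset it does not
  tl <- ref_timeline(speed = 4, occlusion = 1.0)
  t <- seq(0, tl$ttc + 0.5, by = 0.005)
  for (off in c(2.9, 3.1)) {
    g <- tibble::tibble(t = t, x = target_position(tl, t) + off, y = 0)
    sc <- score_trial(g, tl, buttons = NULL, mode = "pursuit")
    expect_identical(sc$valid, off < 3)
  }
})

test_that("generator-labelled drift trials are scored invalid", {
  design <- generate_design(1, seed = 6)[1:10, ]
  run <- run_experiment(1, n_participants = 1,
                        params = oculomotor_params(invalid_trial_rate = 1),
                        seed = 7, design = design)
  expect_true(all(!run$scores$intended_valid))
  expect_true(all(!run$scores$valid))
})

test_that("anticipatory cross-directed saccades make the trial incorrect", {
  tl <- ref_timeline(speed = 3, occlusion = 1.0)
  fs <- 200; t <- seq(0, tl$ttc + 0.5, by = 1 / fs)
  # gaze pursues, then jumps to the cross 0.5 s BEFORE the change onset
  jump <- tl$change_onset - 0.5
  x <- ifelse(t < jump, target_position(tl, t),
              target_position(tl, jump) +
                gazepred:::saccade_displacement(t - jump,
                                                -target_position(tl, jump), 30))
  sc <- score_trial(tibble::tibble(t = t, x = x, y = 0), tl,
                    buttons = NULL, mode = "saccade")
  expect_false(sc$correct)
  expect_true(is.na(sc$saccadic_rt))
})

test_that("response time recovers a fixed detection latency", {
  tl <- ref_timeline(speed = 5, occlusion = 0.9)
  sim <- simulate_trial(tl, noiseless_params(), "saccade", seed = 1)
  sc <- score_trial(sim$gaze, tl, buttons = sim$events, mode = "saccade")
  expect_lt(abs(sc$saccadic_rt - 0.300), 0.015)
  # pursuit mode: the button press carries the same latency exactly
  simb <- simulate_trial(tl, noiseless_params(), "pursuit", seed = 1)
  scb <- score_trial(simb$gaze, tl, buttons = simb$events, mode = "pursuit")
  expect_equal(scb$perturbation_rt, 0.300)
})

test_that("button-mode scoring mirrors saccade-mode scoring under zero noise", {
  p <- noiseless_params()
  for (v in c(3, 5)) {
    tl <- ref_timeline(speed = v, occlusion = 0.7)
    ssac <- simulate_trial(tl, p, "saccade", seed = 10 + v)
    spur <- simulate_trial(tl, p, "pursuit", seed = 10 + v)
    a <- score_trial(ssac$gaze, tl, buttons = ssac$events, mode = "saccade")
    b <- score_trial(spur$gaze, tl, buttons = spur$events, mode = "pursuit")
    expect_equal(a$valid, b$valid)
    expect_equal(a$correct, b$correct)
    expect_equal(a$ttc_error, b$ttc_error, tolerance = 1e-9)
  }
})

test_that("aggregation summarises cells and applies the <10-valid exclusion", {
  scores <- tidyr::expand_grid(
    participant = c("P1", "P2"), speed = c(3, 4), occlusion = 1,
    trial = 1:12
  )
  scores$valid <- TRUE
  scores$correct <- TRUE
  scores$saccadic_rt <- 0.3
  scores$ttc_error <- 0
  scores$relative_ttc <- 100
  # P2 has only 9 valid trials in the speed-3 cell
  scores$valid[scores$participant == "P2" & scores$speed == 3 &
                 scores$trial <= 3] <- FALSE
  agg <- aggregate_scores(scores, min_valid = 10)
  expect_equal(excluded_participants(agg), "P2")
  expect_equal(unique(agg$participant), "P1")
  expect_true(all(agg$percent_correct == 100))
  expect_true(all(agg$n_correct <= agg$n_valid))
  expect_error(aggregate_scores(scores[0, ]), "empty")
})

test_that("expected percent correct tracks the miss rate in perturbation cells", {
  design <- dplyr::bind_rows(purrr::map(1:40, function(i) {
    d <- trial_design(speed = 3, occlusion = 1.0)
    d$trial_id <- i
    d
  }))
  m <- 0.3
  run <- run_experiment(1, n_participants = 3,
                        params = noiseless_params(miss_rate = m),
                        seed = 11, design = design)
  agg <- aggregate_scores(run$scores, min_valid = 1)
  # binomial error around 100*(1-m) with 120 trials total
  expect_lt(abs(mean(agg$percent_correct) - 100 * (1 - m)),
            3 * 100 * sqrt(m * (1 - m) / 120))
})
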