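# Within-subject statistics: rm_anova decomposition, GG epsilon, Holm
# adjustment, contrasts, exploratory regression.

rand_table <- function(n = 6, a = 3, b = 2, seed = 1, effect = 0) {
  withr::with_seed(seed, {
    d <- tidyr::expand_grid(id = paste0("s", seq_len(n)),
                            A = paste0("a", seq_len(a)),
                            B = paste0("b", seq_len(b)))
    d$y <- rnorm(nrow(d)) + effect * as.integer(factor(d$A))
    d
  })
}

test_that("a 2-level within factor reproduces the squared paired t statistic", {
  for (seed in 1:5) {
    d <- withr::with_seed(seed, {
      tibble::tibble(id = rep(paste0("s", 1:9), each = 2),
                     A = rep(c("x", "y"), 9), y = rnorm(18))
    })
    fit <- tidy(rm_anova(d, "y", "id", "A"))
    w <- tidyr::pivot_wider(d, names_from = "A", values_from = "y")
    tt <- t.test(w$x, w$y, paired = TRUE)
    expect_lt(abs(fit$F - tt$statistic^2), 1e-10)
    expect_lt(abs(fit$p_uncorrected - tt$p.value), 1e-10)
    expect_equal(fit$epsilon, 1) # 2 levels cannot violate sphericity
  }
})

test_that("two-way decomposition matches the aov error-strata oracle", {
  for (seed in 1:4) {
    d <- rand_table(n = 5 + seed, seed = seed, effect = 0.5)
    fit <- tidy(rm_anova(d, "y", "id", c("A", "B")))
    ref <- summary(stats::aov(y ~ A * B + Error(factor(id) / (A * B)),
                              data = d))
    get_f <- function(stratum, term) {
      tab <- ref[[stratum]][[1]]
      tab[trimws(rownames(tab)) == term, "F value"]
    }
    expect_lt(abs(fit$F[fit$effect == "A"] - get_f("Error: factor(id):A", "A")),
              1e-10)
    expect_lt(abs(fit$F[fit$effect == "B"] - get_f("Error: factor(id):B", "B")),
              1e-10)
    expect_lt(abs(fit$F[fit$effect == "A:B"] -
                    get_f("Error: factor(id):A:B", "A:B")), 1e-10)
  }
})

test_that("degenerate and invalid tables are handled", {
  d <- rand_table(seed = 3)
  d$y <- 5 # zero between-condition variance
  fit <- tidy(rm_anova(d, "y", "id", c("A", "B")))
  expect_equal(fit$F, c(0, 0, 0))
  expect_equal(fit$partial_eta_sq, c(0, 0, 0))
  # missing cell names the participant and the cell
  d2 <- rand_table(seed = 4)
  d2 <- d2[!(d2$id == "s2" & d2$A == "a3" & d2$B == "b1"), ]
  expect_error(rm_anova(d2, "y", "id", c("A", "B")), "s2.*a3")
})

test_that("statistics are invariant under participant relabelling", {
  d <- rand_table(n = 7, seed = 5, effect = 0.3)
  fit1 <- tidy(rm_anova(d, "y", "id", c("A", "B")))
  relabel <- setNames(sample(paste0("t", 1:7)), paste0("s", 1:7))
  d2 <- d
  d2$id <- unname(relabel[d2$id])
  fit2 <- tidy(rm_anova(d2, "y", "id", c("A", "B")))
  expect_equal(fit1[, -1], fit2[, -1], tolerance = 1e-12)
})

test_that("partial eta squared and epsilon respect their ranges", {
  for (seed in 6:9) {
    fit <- tidy(rm_anova(rand_table(n = 8, a = 4, seed = seed), "y", "id",
                         c("A", "B")))
    expect_true(all(fit$partial_eta_sq >= 0 & fit$partial_eta_sq <= 1))
    k <- c(4, 2, 8) # levels per effect (a, b, a*b)
    lower <- 1 / fit$df_num
    expect_true(all(fit$epsilon <= 1 + 1e-12))
    expect_true(all(fit$epsilon >= lower - 1e-12))
    expect_true(all(fit$F >= 0))
  }
})

test_that("Holm adjustment matches the hand-computed step-down oracle", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  # adjusted >= raw, monotone in raw order, capped at 1
  p <- withr::with_seed(2, runif(10))
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj <= 1))
})

test_that("pairwise contrasts are paired t tests with Holm adjustment", {
  d <- rand_table(n = 10, seed = 12, effect = 0.8)
  ct <- pairwise_contrasts(d, "y", "id", "A")
  expect_equal(nrow(ct), 3)
  expect_true(all(ct$p_adjusted >= ct$p_raw))
  # reproduce one contrast by hand
  m <- dplyr::summarise(dplyr::group_by(d, id, A), y = mean(y), .groups = "drop")
  w <- tidyr::pivot_wider(m, names_from = "A", values_from = "y")
  tt <- t.test(w$a1, w$a2, paired = TRUE)
  expect_equal(ct$t[ct$contrast == "a1 - a2"], unname(tt$statistic))
  expect_equal(holm_adjust(ct$p_raw), ct$p_adjusted)
})

test_that("regression recovers toy lines and the generator's RT-TTC coupling", {
  toy <- tibble::tibble(speed = 1, valid = TRUE, correct = TRUE,
                        saccadic_rt = c(0, 1, 2), perturbation_rt = NA_real_,
                        relative_ttc = c(0, 1, 2))
  fit <- suppressWarnings(rt_ttc_regression(toy))
  expect_equal(fit$slope, 1)
  expect_equal(fit$r, 1)
  # degenerate x variance errors
  toy2 <- toy; toy2$saccadic_rt <- 1
  expect_error(rt_ttc_regression(toy2), "constant")
  # null coupling: slope compatible with zero
  design <- generate_design(1, seed = 20)
  run0 <- run_experiment(1, n_participants = 2,
                         params = oculomotor_params(invalid_trial_rate = 0,
                                                    miss_rate = 0),
                         seed = 21, design = design[design$speed == 3, ][1:30, ])
  f0 <- rt_ttc_regression(run0$scores)
  expect_gt(f0$p, 0.01)
  # with slow speed updating, early responses extrapolate the old 4 deg/s:
  # 3 deg/s trials are pressed too early (slope > 0 in RT), 5 deg/s too
  # late (slope < 0), signs given by the generator's closed-form coupling
  pc <- oculomotor_params(invalid_trial_rate = 0, miss_rate = 0,
                          ttc_response_sd = 0.05, speed_update_time = 0.6)
  d35 <- design[design$speed != 4, ]
  d35 <- dplyr::bind_rows(d35[d35$speed == 3, ][1:40, ], d35[d35$speed == 5, ][1:40, ])
  d35$trial_id <- seq_len(nrow(d35))
  runc <- run_experiment(1, n_participants = 2, params = pc, seed = 22,
                         design = d35)
  fc <- rt_ttc_regression(runc$scores)
  expect_gt(fc$slope[fc$speed == 3], 0)
  expect_lt(fc$slope[fc$speed == 5], 0)
})
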