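test_that("community simulation partitions children into households", {
  cfg <- sim_config(n_children = 4, n_households = 2, K = 4, n_events = 10,
                    household_size_mean = 2, seed = 1)
  roster <- simulate_community(cfg)
  expect_equal(nrow(roster), 4)
  expect_equal(length(unique(roster$household_id)), 2)
  expect_equal(sum(table(roster$household_id)), 4)
  # determinism
  expect_identical(simulate_community(cfg), roster)
  # infeasible constraints rejected at construction
  expect_error(sim_config(n_children = 100, n_households = 2))
})

test_that("household sizes respect bounds and the configured mean", {
  sizes <- unlist(lapply(1:60, function(s) {
    cfg <- sim_config(seed = s)
    as.integer(table(simulate_community(cfg)$household_id))
  }))
  expect_true(all(sizes >= 1 & sizes <= 9))
  # the sum constraint fixes the mean exactly at n_children / n_households
  expect_equal(mean(sizes), 213 / 70, tolerance = 1e-12)
  # dispersion is in the right regime for the emulated community
  expect_gt(sd(sizes), 1)
  expect_lt(sd(sizes), 2.6)
})

test_that("truth recipes produce valid bundles", {
  cfg <- sim_config(n_children = 10, n_households = 4, K = 4, n_events = 10,
                    household_size_mean = 2.5, seed = 2)
  tz <- draw_truth(cfg, recipe = "zero")
  expect_equal(tz$alpha, numeric(3))
  expect_equal(tz$scale_I, numeric(3))
  expect_equal(tz$corr_I, diag(3))
  tp <- draw_truth(cfg)
  ev <- eigen(tp$corr_I, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_true(all(abs(diag(tp$corr_I) - 1) < 1e-12))
  expect_true(all(tp$scale_I >= 0))
  # non-PSD user matrix rejected
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(make_truth(4, "i", corr_I = bad), "positive-definite")
})

test_that("LKJ shape-2 draws have zero-mean off-diagonals", {
  set.seed(8)
  rhos <- t(replicate(500, tcrossprod(rlkj_chol(3, 2))[lower.tri(diag(3))]))
  for (j in 1:3) {
    se <- sd(rhos[, j]) / sqrt(nrow(rhos))
    expect_lt(abs(mean(rhos[, j])), 3 * se + 1e-12)
  }
})

test_that("zero truth yields near-uniform categories; softmax inversion works", {
  cfg <- sim_config(n_children = 12, n_households = 5, K = 4,
                    n_events = 4000, household_size_mean = 2.4,
                    variant = "i", seed = 3)
  roster <- simulate_community(cfg)
  ev0 <- simulate_observations(roster, draw_truth(cfg, recipe = "zero"), cfg)
  freq <- tabulate(ev0$behavior_code, 4) / 4000
  se <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(freq - 0.25) < 3 * se))

  # intercepts set to reference-normalized log target frequencies
  target <- c(0.4, 0.3, 0.2, 0.1)
  truth <- make_truth(4, "i", alpha = log(target[1:3] / target[4]))
  ev1 <- simulate_observations(roster, truth, cfg)
  freq1 <- tabulate(ev1$behavior_code, 4) / 4000
  se1 <- sqrt(target * (1 - target) / 4000)
  expect_true(all(abs(freq1 - target) < 3 * se1))
})

test_that("event generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_children = 10, n_households = 4, K = 4, n_events = 60,
                    household_size_mean = 2.5, variant = "iF", seed = 4)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_observations(sim1$events, f1)
  write_observations(sim2$events, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("same-household dyads get higher exposure when multiplied", {
  cfg <- sim_config(n_children = 30, n_households = 10, K = 4,
                    n_events = 2000, household_size_mean = 3,
                    same_household_multiplier = 10, variant = "i", seed = 5)
  roster <- simulate_community(cfg)
  ev <- simulate_observations(roster, draw_truth(cfg, recipe = "zero"), cfg)
  led <- attr(ev, "ledger")
  expect_equal(sum(led$n_events), 2000)
  expect_gt(mean(led$n_events[led$same_household]),
            mean(led$n_events[!led$same_household]))
})

test_that("empirical conditional frequencies converge to the model's cell probabilities", {
  # two children, one household: two directed dyads = two covariate cells
  cfg <- sim_config(n_children = 2, n_households = 1, K = 4,
                    n_events = 30000, household_size_mean = 2,
                    variant = "iF", seed = 6)
  truth <- make_truth(4, "iF",
                      alpha = c(0.3, -0.2, 0.1),
                      beta_I = cbind(age = c(0.8, -0.5, 0.2),
                                     sex = c(0.4, 0, -0.3),
                                     age_sex = c(0, 0.2, 0)),
                      beta_R = cbind(age = c(-0.4, 0.3, 0),
                                     sex = c(0.2, -0.2, 0.1),
                                     age_sex = c(0, 0, 0)),
                      beta_H = c(0.2, 0.1, -0.1))
  roster <- simulate_community(cfg)
  ev <- simulate_observations(roster, truth, cfg)
  dd <- build_design(ev, roster, behavior_taxonomy(sprintf("b%d", 1:4)))
  params <- attr(ev, "params")
  eta <- linear_predictor(params, dd)
  for (who in unique(dd$i_idx)) {
    rows <- which(dd$i_idx == who)
    pcell <- category_probabilities(eta[rows[1], ])
    emp <- tabulate(dd$y[rows], 4) / length(rows)
    se <- sqrt(pcell * (1 - pcell) / length(rows))
    expect_true(all(abs(emp - pcell) < 4 * se))
  }
})

test_that("truth bundles round-trip through JSON", {
  truth <- demo_truth()
  f <- tempfile(fileext = ".json")
  write_truth(truth, f)
  back <- read_truth(f)
  expect_equal(back$alpha, truth$alpha)
  expect_equal(unname(back$beta_I), unname(truth$beta_I))
  expect_equal(back$corr_I, truth$corr_I)
  expect_equal(back$scale_R, truth$scale_R)
})
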