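# deterministic fake posteriors around the toy design
toy3_design <- function() {
  tax3 <- behavior_taxonomy(c("x", "y", "z"))
  ev <- toy_events_df()
  ev$behavior_code <- c(1L, 2L, 3L, 1L, 2L, 3L)
  roster <- load_roster(toy_roster_file())
  build_design(load_observations(toy_events_file(ev), tax3, roster),
               roster, tax3)
}

const_draws_fit <- function(spec, data, edits = list(), n = 50) {
  lay <- dyadmnl:::param_layout(spec, data)
  theta <- numeric(attr(lay, "total"))
  for (nm in names(edits)) theta[lay[[nm]]] <- edits[[nm]]
  m <- matrix(theta, nrow = n, ncol = length(theta), byrow = TRUE)
  fake_fit(spec, data, list(m, m))
}

test_that("correlation recomposition recovers the factor's correlations", {
  dd3 <- toy3_design()
  spec <- model_spec("i", dd3$taxonomy)
  # identity factor: all correlations zero, none significant
  f0 <- const_draws_fit(spec, dd3)
  rc0 <- recompose_correlations(f0, "initiator")
  expect_equal(rc0$mean, 0)
  expect_false(any(rc0$significant))
  # L = [[1,0],[0.6,0.8]] encodes rho = 0.6 exactly
  L <- rbind(c(1, 0), c(0.6, 0.8))
  f1 <- const_draws_fit(spec, dd3, list(y_I = y_from_corr_chol(L)))
  rc1 <- recompose_correlations(f1, "initiator")
  expect_equal(rc1$mean, 0.6, tolerance = 1e-12)
  expect_true(rc1$significant)   # degenerate interval excludes zero
  # household roles are unavailable under variant i
  expect_error(recompose_correlations(f1, "household_initiator"),
               "household")
})

test_that("correlation round trip through draws is exact", {
  dd <- toy_design()
  spec <- model_spec("i", toy_taxonomy())
  set.seed(31)
  R0 <- tcrossprod(rlkj_chol(3, 2))
  f <- const_draws_fit(spec, dd,
                       list(y_I = y_from_corr_chol(corr_to_chol(R0))))
  rc <- recompose_correlations(f, "initiator")
  expect_equal(attr(rc, "mean_matrix"), R0, tolerance = 1e-10)
})

test_that("random-effect SD summaries are labelled per category", {
  dd3 <- toy3_design()
  spec <- model_spec("i", dd3$taxonomy)
  f <- const_draws_fit(spec, dd3,
                       list(lsigma_I = log(c(0.2, 0.9))))
  sds <- random_effect_sds(f, "initiator")
  expect_equal(sds$mean, c(0.2, 0.9), tolerance = 1e-12)
  expect_equal(sds$behavior, c("x", "y"))
  expect_equal(sds$role, rep("initiator", 2))
})

test_that("predictions equal the direct softmax for a known posterior", {
  dd3 <- toy3_design()
  spec <- model_spec("iF", dd3$taxonomy)
  alpha <- c(0.5, -0.3)
  bI <- cbind(age = c(0.8, -0.2), sex = c(0.3, 0.1), age_sex = c(0, 0.2))
  bR <- cbind(age = c(-0.4, 0.6), sex = c(0, 0), age_sex = c(0, 0))
  bH <- c(0.25, -0.15)
  f <- const_draws_fit(spec, dd3,
                       list(alpha = alpha, beta_I = as.vector(bI),
                            beta_R = as.vector(bR), beta_H = bH))
  sc <- prediction_scenario(initiator_age = 5, recipient_age = 2,
                            initiator_sex = "male", same_household = TRUE)
  pc <- predict_probabilities(f, sc)
  zi <- standardize_age(5, dd3$scaler, "initiator")
  zj <- standardize_age(2, dd3$scaler, "recipient")
  eta <- alpha + bI %*% c(zi, 1, zi) + bR %*% c(zj, 0, 0) + bH
  expect_equal(pc$mean, category_probabilities(drop(eta)), tolerance = 1e-12)
  # per-draw simplexes sum to one by construction
  expect_equal(sum(pc$mean), 1, tolerance = 1e-12)
})

test_that("an all-zero fixed-effect posterior gives flat curves", {
  dd3 <- toy3_design()
  spec <- model_spec("iF", dd3$taxonomy)
  set.seed(32)
  # alpha varies across draws; betas are zero
  lay <- dyadmnl:::param_layout(spec, dd3)
  n <- 80
  draws <- matrix(0, n, attr(lay, "total"))
  draws[, lay$alpha] <- rnorm(2 * n, sd = 0.3)
  f <- fake_fit(spec, dd3, list(draws, draws))
  pc <- predict_probabilities(
    f, prediction_scenario("initiator_age", grid = c(3, 5, 7)))
  for (k in 1:3) {
    vals <- pc$mean[pc$category == k]
    expect_equal(vals, rep(vals[1], 3), tolerance = 1e-12)
  }
})

test_that("scenario contrasts are antisymmetric and null for equal scenarios", {
  fit <- small_fit("iF")
  a <- prediction_scenario(initiator_sex = "male")
  b <- prediction_scenario(initiator_sex = "female")
  same <- contrast_scenarios(fit, a, a)
  expect_equal(same$mean, rep(0, 4))
  expect_false(any(same$significant))
  ab <- contrast_scenarios(fit, a, b)
  ba <- contrast_scenarios(fit, b, a)
  expect_equal(ab$mean, -ba$mean, tolerance = 1e-12)
  expect_equal(ab$significant, ba$significant)
  # the generator planted a strong initiator-sex effect on category 1
  expect_true(ab$significant[1])
  expect_error(
    contrast_scenarios(fit, a,
                       prediction_scenario("initiator_age", grid = 1:3)),
    "grids")
})

test_that("prediction bands do not collapse under posterior thinning", {
  # empirical percentile bands from 10x-thinned draws fluctuate around the
  # full-posterior bands; on average they must not shrink materially
  fit <- small_fit("iF")
  sc <- prediction_scenario(initiator_age = 5)
  full <- predict_probabilities(fit, sc)
  wfull <- full$upper - full$lower
  set.seed(41)
  widths <- replicate(20, {
    idx <- sample(nrow(fit$draws), nrow(fit$draws) %/% 10)
    sub <- fit
    sub$draws <- fit$draws[idx, , drop = FALSE]
    p <- predict_probabilities(sub, sc)
    p$upper - p$lower
  })
  expect_gte(min(rowMeans(widths) / wfull), 0.85)
})

test_that("age-trend labels follow the documented rule", {
  mk_curve <- function(fn, grid = seq(0, 12, 0.5)) {
    cc <- data.frame(value = grid, category = 1L, behavior = "b1",
                     mean = vapply(grid, fn, 0))
    cc$lower <- cc$mean - 0.01
    cc$upper <- cc$mean + 0.01
    attr(cc, "varying") <- "initiator_age"
    class(cc) <- c("prediction_curve", "data.frame")
    cc
  }
  up <- mk_curve(function(g) 0.1 + 0.05 * g)
  expect_equal(label_age_trend(up)$trend, "increasing")
  peak <- mk_curve(function(g) exp(-(g - 3.5)^2))
  lab <- label_age_trend(peak)
  expect_equal(lab$trend, "peaked")
  expect_equal(lab$peak_lower, 3)
  expect_equal(lab$peak_upper, 4)

  # logistic-in-age posterior: sign of the age coefficient determines
  # monotonicity of each category's curve analytically
  dd3 <- toy3_design()
  spec <- model_spec("iF", dd3$taxonomy)
  f <- const_draws_fit(
    spec, dd3, list(alpha = c(0.2, -0.1),
                    beta_I = as.vector(cbind(age = c(1.5, 0),
                                             sex = c(0, 0),
                                             age_sex = c(0, 0)))))
  # toy ages span 2-9, so the full 0-12 grid warns about extrapolation
  expect_warning(
    pc <- predict_probabilities(
      f, prediction_scenario("initiator_age", grid = seq(0, 12, 0.5))),
    "age range")
  lab2 <- label_age_trend(pc)
  expect_equal(lab2$trend, c("increasing", "decreasing", "decreasing"))
  expect_error(label_age_trend(predict_probabilities(f)), "age grid")
})

test_that("dyad descriptives tally totals, dyads and averages", {
  roster <- load_roster(toy_roster_file())
  # one dyad, five events of one behavior
  ev1 <- data.frame(event_id = 1:5, episode_id = 1L, date = "1959-01-01",
                    initiator_id = "a1", recipient_id = "a2",
                    behavior_code = 2L, initiator_age = 3.5,
                    recipient_age = 6.0, stringsAsFactors = FALSE)
  d1 <- dyad_descriptives(ev1, roster)
  expect_equal(d1$by_group$total, 5)
  expect_equal(d1$by_group$dyads, 1)
  expect_equal(d1$by_group$avg_per_dyad, 5)

  # three dyads spanning same/different household and sex groupings
  ev3 <- data.frame(
    event_id = 1:5, episode_id = 1L, date = "1959-01-01",
    initiator_id = c("a1", "a1", "a2", "a2", "b1"),
    recipient_id = c("a2", "a2", "b2", "b2", "a1"),
    behavior_code = 1L,
    initiator_age = 1, recipient_age = 2, stringsAsFactors = FALSE)
  d3 <- dyad_descriptives(ev3, roster)
  g <- d3$by_group
  # a1->a2: same household, cross sex, 2 events
  expect_equal(g$total[g$same_household & !g$same_sex], 2)
  expect_equal(g$avg_per_dyad[g$same_household & !g$same_sex], 2)
  # a2->b2 (male-male, 2 events) and b1->a1 (female-female, 1 event) both
  # fall in the same-sex / different-household group: 2 dyads, 3 events
  expect_equal(g$dyads[!g$same_household & g$same_sex], 2)
  expect_equal(g$total[!g$same_household & g$same_sex], 3)
  # conservation: group totals sum to the event count
  expect_equal(sum(g$total), nrow(ev3))
  # participation counts: each event counts initiator and recipient once
  expect_equal(sum(d3$per_child$n), 2 * nrow(ev3))
  expect_equal(d3$child_mean, 2 * nrow(ev3) / nrow(roster))
  expect_equal(sum(d3$per_household$n), 2 * nrow(ev3))
})

test_that("descriptives of a synthetic community have the expected scale", {
  cfg <- sim_config(n_children = 30, n_households = 12, K = 4,
                    n_events = 900, household_size_mean = 2.5,
                    variant = "i", seed = 33)
  sim <- simulate_dataset(cfg, draw_truth(cfg, recipe = "zero"))
  de <- dyad_descriptives(sim$events, sim$roster)
  expect_equal(de$n_events, 900)
  expect_equal(de$child_mean, 2 * 900 / 30)
  expect_equal(de$household_mean, 2 * 900 / 12)
  expect_equal(sum(de$by_group$total), 900)
  # same-household dyads interact more per dyad on average (exposure
  # multiplier), mirroring the field pattern
  g <- de$by_group
  avg_same <- sum(g$total[g$same_household]) / sum(g$dyads[g$same_household])
  avg_diff <- sum(g$total[!g$same_household]) / sum(g$dyads[!g$same_household])
  expect_gt(avg_same, avg_diff)
})
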