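test_that("category probabilities match the brute-force softmax", {
  # uniform at zero contrasts
  p <- category_probabilities(numeric(18))
  expect_equal(p, rep(1 / 19, 19))
  # a single log-2 contrast doubles that category's odds vs the reference
  eta <- c(log(2), rep(0, 17))
  p <- category_probabilities(eta)
  expect_equal(p[1] / p[19], 2, tolerance = 1e-12)
  # random contrasts against exp/normalize oracle
  set.seed(1)
  for (r in 1:20) {
    eta <- rnorm(5, 0, 3)
    oracle <- exp(c(eta, 0)) / sum(exp(c(eta, 0)))
    expect_equal(category_probabilities(eta), oracle, tolerance = 1e-12)
    expect_equal(sum(category_probabilities(eta)), 1, tolerance = 1e-12)
    # reference invariance: shifting all K unnormalized log-scores
    shifted <- exp(c(eta, 0) + 7.3) / sum(exp(c(eta, 0) + 7.3))
    expect_equal(category_probabilities(eta), shifted, tolerance = 1e-12)
  }
  expect_error(category_probabilities(c(Inf, 0, 0)), "non-finite")
})

test_that("linear predictor sums exactly the variant's terms", {
  dd <- toy_design()
  spec <- model_spec("iF", toy_taxonomy())
  p0 <- params_zero(spec, dd)
  expect_equal(linear_predictor(p0, dd), matrix(0, 6, 3),
               ignore_attr = TRUE)
  p1 <- p0
  p1$alpha <- c(1, 0, 0)
  expect_equal(linear_predictor(p1, dd, event = 1), c(1, 0, 0))

  # random small instance vs term-by-term hand summation
  set.seed(2)
  p <- p0
  p$alpha <- rnorm(3)
  p$beta_I <- matrix(rnorm(9), 3, 3)
  p$beta_R <- matrix(rnorm(9), 3, 3)
  p$beta_H <- rnorm(3)
  p$nu_I <- matrix(rnorm(3 * dd$I), 3)
  p$nu_R <- matrix(rnorm(3 * dd$I), 3)
  eta <- linear_predictor(p, dd)
  for (n in 1:6) {
    for (k in 1:3) {
      hand <- p$alpha[k] +
        sum(p$beta_I[k, ] * dd$X_I[n, ]) +
        sum(p$beta_R[k, ] * dd$X_R[n, ]) +
        p$beta_H[k] * dd$x_H[n] +
        p$nu_I[k, dd$i_idx[n]] + p$nu_R[k, dd$j_idx[n]]
      expect_equal(eta[n, k], hand, tolerance = 1e-12)
    }
  }
})

test_that("household variants share h terms within a household", {
  dd <- toy_design()
  spec <- model_spec("ih", toy_taxonomy())
  p <- params_zero(spec, dd)
  set.seed(3)
  p$h_I <- matrix(rnorm(3 * dd$H), 3)
  p$h_R <- matrix(rnorm(3 * dd$H), 3)
  eta <- linear_predictor(p, dd)
  # events 1 and 3 share initiator a1 and hence a1's household hA
  hA <- dd$hi_idx[1]
  expect_equal(dd$hi_idx[3], hA)
  # initiators a1 (event 1) and a2 (event 2) are different children of the
  # same household: identical h contribution
  expect_equal(eta[1, ] - p$h_R[, dd$hj_idx[1]],
               p$alpha + p$h_I[, hA])
})

test_that("pointwise log-likelihood equals the categorical log-pmf", {
  dd <- toy_design()
  spec <- model_spec("i", toy_taxonomy())
  # all-zero parameters, K = 4: every event scores log(1/4)
  ll <- log_likelihood_pointwise(params_zero(spec, dd), dd)
  expect_equal(ll, rep(log(1 / 4), 6))
  # K = 3 toy with known parameters vs hand computation
  tax3 <- behavior_taxonomy(c("x", "y", "z"))
  ev <- toy_events_df()
  ev$behavior_code <- c(1L, 2L, 3L, 1L, 2L, 3L)
  roster <- load_roster(toy_roster_file())
  dd3 <- build_design(load_observations(toy_events_file(ev), tax3, roster),
                      roster, tax3)
  p <- params_zero(model_spec("i", tax3), dd3)
  p$alpha <- c(0.7, -0.4)
  pi3 <- exp(c(0.7, -0.4, 0)) / sum(exp(c(0.7, -0.4, 0)))
  ll3 <- log_likelihood_pointwise(p, dd3)
  expect_equal(ll3, log(pi3)[ev$behavior_code], tolerance = 1e-12)
  # identical events get identical pointwise values
  expect_equal(ll3[1], ll3[4])
})

test_that("variant i equals variant iF with the covariate block at zero", {
  dd <- toy_design()
  set.seed(4)
  pi_ <- params_zero(model_spec("i", toy_taxonomy()), dd)
  pi_$alpha <- rnorm(3)
  pi_$sigma_I <- abs(rnorm(3)); pi_$sigma_R <- abs(rnorm(3))
  pi_$z_I <- matrix(rnorm(3 * dd$I), 3)
  pi_$z_R <- matrix(rnorm(3 * dd$I), 3)
  pi_$L_I <- rlkj_chol(3, 2); pi_$L_R <- rlkj_chol(3, 2)
  pif <- pi_
  pif$beta_I <- matrix(0, 3, 3); pif$beta_R <- matrix(0, 3, 3)
  pif$beta_H <- numeric(3)
  expect_equal(log_likelihood_pointwise(pi_, dd),
               log_likelihood_pointwise(pif, dd), tolerance = 1e-12)
})

test_that("correlation Cholesky transforms round-trip", {
  # closed form: 2x2 factor encodes rho = 0.6
  L <- rbind(c(1, 0), c(0.6, 0.8))
  expect_equal(tcrossprod(L)[2, 1], 0.6, tolerance = 1e-12)
  expect_equal(corr_chol_from_y(y_from_corr_chol(L), 2), L,
               tolerance = 1e-12)
  # random correlation matrices round-trip through y within 1e-10
  set.seed(5)
  for (d in c(2, 5, 18)) {
    L0 <- rlkj_chol(d, 2)
    R0 <- tcrossprod(L0)
    L1 <- corr_to_chol(R0)
    y <- y_from_corr_chol(L1)
    expect_equal(tcrossprod(corr_chol_from_y(y, d)), R0, tolerance = 1e-10)
  }
  expect_error(corr_to_chol(matrix(c(2, 0, 0, 2), 2)), "correlation")
})

test_that("LKJ-Cholesky density matches the bivariate closed form", {
  # for d = 2 the implied density of rho is Beta(eta, eta) rescaled
  for (eta in c(1, 2, 4)) {
    for (rho in c(-0.7, 0, 0.45)) {
      L <- rbind(c(1, 0), c(rho, sqrt(1 - rho^2)))
      expect_equal(lkj_chol_lpdf(L, eta),
                   (eta - 1) * log(1 - rho^2) -
                     ((2 * eta - 1) * log(2) + lbeta(eta, eta)),
                   tolerance = 1e-12)
    }
  }
})

test_that("log prior sums the stated component densities", {
  dd <- toy_design()
  spec <- model_spec("i", toy_taxonomy())
  set.seed(6)
  p <- params_zero(spec, dd)
  p$alpha <- rnorm(3)
  p$sigma_I <- abs(rnorm(3)); p$sigma_R <- abs(rnorm(3))
  p$z_I <- matrix(rnorm(3 * dd$I), 3); p$z_R <- matrix(rnorm(3 * dd$I), 3)
  p$L_I <- rlkj_chol(3, 2); p$L_R <- rlkj_chol(3, 2)
  # independent term-by-term oracle
  oracle <- sum(dnorm(p$alpha, log = TRUE)) +
    sum(dnorm(p$z_I, log = TRUE)) + sum(dnorm(p$z_R, log = TRUE)) +
    lkj_chol_lpdf(p$L_I, 2) + lkj_chol_lpdf(p$L_R, 2) +
    sum(log(2) + dnorm(p$sigma_I, log = TRUE)) +
    sum(log(2) + dnorm(p$sigma_R, log = TRUE))
  expect_equal(log_prior(p, spec), oracle, tolerance = 1e-12)
  # the zero-intercept scalar contribution is the standard normal at 0
  p0 <- p
  p0$alpha <- c(0, p$alpha[2:3])
  expect_equal(log_prior(p0, spec) - log_prior(p, spec),
               dnorm(0, log = TRUE) - dnorm(p$alpha[1], log = TRUE),
               tolerance = 1e-12)
  # doubling the LKJ shape changes only the correlation-factor terms
  spec4 <- model_spec("i", toy_taxonomy(),
                      priors = prior_config(lkj_shape = 4))
  expect_equal(log_prior(p, spec4) - log_prior(p, spec),
               lkj_chol_lpdf(p$L_I, 4) + lkj_chol_lpdf(p$L_R, 4) -
                 lkj_chol_lpdf(p$L_I, 2) - lkj_chol_lpdf(p$L_R, 2),
               tolerance = 1e-12)
})

test_that("non-centered effects have the intended marginal covariance", {
  set.seed(7)
  d <- 3
  L <- rlkj_chol(d, 2)
  sig <- c(0.5, 1, 1.5)
  n <- 1e5
  nu <- diag(sig) %*% L %*% matrix(rnorm(d * n), d)
  emp <- tcrossprod(nu) / n
  expected <- diag(sig) %*% tcrossprod(L) %*% diag(sig)
  expect_equal(emp, expected, tolerance = 0.05)
})
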