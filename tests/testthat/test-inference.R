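# The hierarchical learner: marginal likelihood, conditional modes, and
# maximum-likelihood fitting, checked against closed forms, brute-force
# integration, a grid-refined oracle, and lme4.

test_that("degenerate marginal likelihoods match closed forms", {
  # sigma = 0: plain binomial likelihood
  st <- make_state(freq = 1, n_red = 1)
  expect_equal(marginal_loglik(st, b0 = 0, sigma = 0), log(0.5))
  st2 <- make_state(freq = 2, n_red = 1)
  expect_equal(marginal_loglik(st2, b0 = 0, sigma = 0),
               log(choose(2, 1) * 0.25))
  expect_error(marginal_loglik(st, b0 = 0, sigma = -1), "sigma")
})

test_that("quadrature agrees with brute-force integration", {
  set.seed(42)
  # sigma spanning the operating range of the word-effect spread
  for (i in 1:50) {
    w <- sample(1:5, 1)
    f <- sample(1:10, w, replace = TRUE)
    st <- make_state(freq = f, n_red = vapply(f, function(k)
      sample(0:k, 1), integer(1)))
    b0 <- runif(1, -3, 3)
    sigma <- runif(1, 0.05, 1)
    agq <- marginal_loglik(st, b0 = b0, sigma = sigma, n_quad = 15)
    oracle <- brute_loglik(st, b0 = b0, sigma = sigma)
    expect_lt(abs(agq - oracle), 1e-6)
    # quadrature order is converged by 15 nodes
    expect_lt(abs(agq - marginal_loglik(st, b0 = b0, sigma = sigma,
                                        n_quad = 25)), 1e-6)
  }
  # wide word-effect spreads need a few more nodes
  set.seed(43)
  for (i in 1:10) {
    f <- sample(1:10, 3, replace = TRUE)
    st <- make_state(freq = f, n_red = vapply(f, function(k)
      sample(0:k, 1), integer(1)))
    sigma <- runif(1, 1, 2)
    expect_lt(abs(marginal_loglik(st, b0 = 0, sigma = sigma, n_quad = 25) -
                    brute_loglik(st, b0 = 0, sigma = sigma)), 1e-6)
  }
})

test_that("the fitted optimum matches a grid-refined oracle", {
  set.seed(7)
  for (i in 1:3) {
    f <- c(8, 10, 6)
    u <- rnorm(3, 0, 0.8)
    st <- make_state(freq = f, n_red = rbinom(3, f, plogis(-0.5 + u)))
    fit <- fit_learner(st, n_quad = 15)
    oracle <- grid_mle(st)
    expect_equal(fit$b0_hat, oracle$b0, tolerance = 1e-2)
    expect_equal(fit$sigma_hat, oracle$sigma, tolerance = 1e-2)
    # evaluated by the same integrator, the fitted optimum is no worse
    expect_gte(brute_loglik(st, b0 = fit$b0_hat, sigma = fit$sigma_hat)
               + 1e-6, oracle$loglik)
  }
})

test_that("fits agree with lme4 on a mixed dataset", {
  skip_if_not_installed("lme4")
  set.seed(31)
  f <- c(1, 1, 2, 3, 5, 9, 20, 30, 80, 211)
  st <- make_state(freq = f, n_red = rbinom(10, f, plogis(-1 + rnorm(10, 0, 0.8))))
  ours <- fit_learner(st, n_quad = 15)
  m <- lme4::glmer(cbind(n_red, freq - n_red) ~ 1 + (1 | word),
                   data = st, family = binomial, nAGQ = 15)
  expect_equal(ours$b0_hat, unname(lme4::fixef(m)[1]), tolerance = 1e-3)
  expect_equal(ours$sigma_hat,
               sqrt(unname(lme4::VarCorr(m)$word[1])), tolerance = 1e-3)
  u_lme4 <- lme4::ranef(m)$word[st$word, 1]
  expect_equal(unname(ours$u_hat[st$word]), u_lme4, tolerance = 1e-2)
})

test_that("homogeneous data give a null intercept and vanishing sigma", {
  st <- make_state(freq = rep(1000, 8), n_red = rep(500, 8))
  fit <- fit_learner(st)
  expect_lt(abs(fit$b0_hat), 0.05)
  expect_lt(fit$sigma_hat, 0.05)
  expect_true(all(abs(fit$u_hat) < 0.05))
})

test_that("conditional modes behave as partial pooling requires", {
  st <- make_state(freq = c(4, 10, 100), n_red = c(2, 10, 100))
  # sigma = 0 pins every mode at zero
  expect_equal(unname(conditional_modes(st, 0, 0)), c(0, 0, 0))
  # symmetric likelihood at eta = 0: the f=4, n=2 word stays at zero
  m <- conditional_modes(st, 0, 1)
  expect_equal(unname(m[1]), 0, tolerance = 1e-8)
  # always-reduced words sit above the fixed effect, more so when frequent
  expect_gt(m[2], 0)
  expect_gt(m[3], m[2])

  # equal observed proportions deviating from the prediction: the more
  # frequent word's effect is at least as large in magnitude
  st2 <- make_state(freq = c(10, 100), n_red = c(8, 80))
  m2 <- conditional_modes(st2, stats::qlogis(0.2), 0.7)
  expect_gte(abs(m2[2]), abs(m2[1]))
})

test_that("parameters are recovered across replicate seeded lexica", {
  lex <- zipf_lexicon(762, 236, 2793, seed = 8)
  sp <- seed_params(-1, 0, 0.4)
  fits <- purrr::map(1:20, function(i) {
    st <- seed_generation(lex, sp, seed = 100 + i)
    glance(fit_learner(st))
  }) |> dplyr::bind_rows()
  expect_equal(mean(fits$b0_hat), -1, tolerance = 0.1)
  expect_equal(mean(fits$sigma_hat), 0.4, tolerance = 0.1)
  expect_true(all(fits$converged))
})

test_that("sigma collapses to the boundary when words are exchangeable", {
  # with sigma = 0 in truth and many tokens per word, the estimate is at
  # or vanishingly near the boundary (the interior mode shrinks as
  # information per word grows)
  lex <- lexicon(sprintf("w%d", 1:40), rep(1000, 40))
  sp <- seed_params(-0.5, 0, 0)
  at_zero <- vapply(1:20, function(i) {
    st <- seed_generation(lex, sp, seed = 200 + i)
    fit_learner(st)$sigma_hat < 0.05
  }, logical(1))
  expect_gte(mean(at_zero), 0.9)
})

test_that("learner variants estimate exactly their declared parameters", {
  set.seed(5)
  f <- c(2, 4, 8, 16, 32, 64, 128, 256)
  st <- make_state(freq = f, n_red = rbinom(8, f, plogis(-1 + 0.01 * f)))
  l2 <- fit_learner(st, learner_spec(estimate_intercept = FALSE))
  expect_identical(l2$b0_hat, 0)
  expect_identical(l2$b_freq_hat, 0)
  l3 <- fit_learner(st, learner_spec(estimate_freq_effect = TRUE))
  expect_false(l3$b_freq_hat == 0)
  # tidy/glance expose the fitted surface
  td <- tidy(l3)
  expect_equal(td$word, st$word)
  expect_equal(nrow(glance(l3)), 1)
})
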