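test_that("classic-utility subjective values match hand calculations", {
  # certainty with linear utility: value is the amount itself
  expect_equal(sv_classic(1, 0, 5, alpha = 1, beta = 0.65), 5)
  # pure expected value
  expect_equal(sv_classic(0.5, 0, 25, alpha = 1, beta = 0), 12.5)
  # ambiguity penalty on the probability term, then the power of the amount
  expect_equal(
    sv_classic(0.5, 0.74, 8, alpha = 0.72, beta = 1.0),
    (0.5 - 1.0 * 0.74 / 2) * 8^0.72
  )
  # vectorization and recycling
  expect_equal(
    sv_classic(c(0.25, 0.75), 0, 8, alpha = 1, beta = 0),
    c(2, 6)
  )
})

test_that("classic utility reduces correctly in the no-ambiguity and
           no-attitude cases", {
  p <- c(0.25, 0.5, 0.75)
  v <- c(5, 8, 12, 25)
  for (a in c(0.4, 1, 1.3)) {
    expect_equal(sv_classic(p, 0, 12, a, beta = 1.2), p * 12^a)
  }
  # beta = 0: ambiguity has no effect
  expect_equal(
    sv_classic(0.5, 0.74, v, 0.8, beta = 0),
    sv_classic(0.5, 0, v, 0.8, beta = 0)
  )
})

test_that("estimated-value model cumulates increments over ordinal levels", {
  nu <- c(7.22, 4.13, 6.23, 8.77)
  expect_equal(sv_estimated(1, 0, 1, nu, beta = 0.9), 7.22)
  expect_equal(sv_estimated(1, 0, 3, nu, beta = 0), 7.22 + 4.13 + 6.23)
  # full ambiguity with beta = 1 cancels the probability term entirely
  expect_equal(sv_estimated(0.5, 1.0, 2, nu, beta = 1), 0)
  # nondecreasing in level for any nonnegative increments
  for (i in 1:20) {
    nu_r <- rexp(4)
    vals <- sv_estimated(rep(0.5, 4), 0, 1:4, nu_r, beta = 0.3)
    expect_true(all(diff(vals) >= 0))
  }
  # matrix form: one increment row per evaluated trial
  m <- rbind(nu, nu * 2)
  expect_equal(
    sv_estimated(c(1, 1), 0, c(2, 2), m, beta = 0),
    c(11.35, 22.70)
  )
})

test_that("estimated-value and classic models agree when increments encode
           the power utility", {
  alpha <- 0.8
  v <- c(5, 8, 12, 25)
  nu <- c(v[1]^alpha, diff(v^alpha))
  for (lev in 1:4) {
    expect_equal(
      sv_estimated(0.5, 0.24, lev, nu, beta = 0.6),
      sv_classic(0.5, 0.24, v[lev], alpha, beta = 0.6)
    )
  }
})

test_that("baseline valuation uses the raw category index", {
  expect_equal(sv_fixed(1, 0, 2), 2)
  expect_equal(sv_fixed(0.75, 0, 4), 3)
  expect_equal(sv_fixed(0.5, 0.5, 4), 1)
})

test_that("both choice rules are calibrated at indifference and monotone", {
  expect_equal(choice_prob_logistic(5, 5, gamma = 2), 0.5)
  expect_equal(choice_prob_trembling(5, 5, delta = 0), 0.5)
  expect_equal(choice_prob_trembling(0, 100, delta = 1), 0.5)
  expect_equal(choice_prob_logistic(5, 6, gamma = 1), 1 / (1 + exp(-1)))
  # trembling bounds: [delta/2, 1 - delta/2]
  expect_equal(choice_prob_trembling(0, 1e6, delta = 0.2), 0.9)
  expect_equal(choice_prob_trembling(1e6, 0, delta = 0.2), 0.1)
  sv <- seq(-5, 5, length.out = 50)
  expect_true(all(diff(choice_prob_logistic(0, sv, gamma = 0.7)) > 0))
  expect_true(all(diff(choice_prob_trembling(0, sv, delta = 0.3)) > 0))
})

test_that("logistic rule is numerically stable and sharpens with gamma", {
  expect_equal(choice_prob_logistic(0, 1e6, gamma = 1), 1)
  expect_equal(choice_prob_logistic(1e6, 0, gamma = 1), 0)
  expect_false(is.nan(choice_prob_logistic(-1e8, 1e8, gamma = 100)))
  # gamma -> inf approaches a step function
  expect_gt(choice_prob_logistic(5, 5.01, gamma = 1e4), 0.99)
  expect_lt(choice_prob_logistic(5, 4.99, gamma = 1e4), 0.01)
})

test_that("argument validation rejects out-of-domain inputs", {
  expect_error(sv_classic(0, 0, 5, 1, 0), "p")
  expect_error(sv_classic(0.5, 1.2, 5, 1, 0), "a")
  expect_error(sv_classic(0.5, 0, -1, 1, 0), "v")
  expect_error(sv_estimated(0.5, 0, 5, rep(1, 4), 0), "level")
  expect_error(sv_estimated(0.5, 0, 2, c(1, -1, 1, 1), 0), "nonnegative")
  expect_error(choice_prob_logistic(1, 2, gamma = 0), "gamma")
  expect_error(choice_prob_trembling(1, 2, delta = 1.5), "delta")
})

test_that("plug-in prior mean of the risk attitude reflects the hyperprior
           locations", {
  expect_equal(prior_mean_alpha(hyperprior_settings()), 8 / 11)
  expect_lt(abs(prior_mean_alpha(hyperprior_settings()) - 0.72), 0.01)
  expect_equal(
    prior_mean_alpha(hyperprior_settings(
      alpha_shape1_loc = 1, alpha_shape2_loc = 1
    )), 1
  )
  expect_equal(
    prior_mean_alpha(hyperprior_settings(
      alpha_shape1_loc = 4, alpha_shape2_loc = 4
    )), 1
  )
})

test_that("hyperprior settings validate overrides and round-trip as YAML", {
  expect_error(hyperprior_settings(nonsense = 1), "unknown")
  expect_error(hyperprior_settings(beta_mean_scale = -1), "positive")
  expect_error(hyperprior_settings(beta_lower = -2), "symmetric")
  hp <- hyperprior_settings(nu_mean_loc = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_hyperpriors(hp, path)
  expect_equal(read_hyperpriors(path), hp)
})
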