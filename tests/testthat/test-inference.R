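test_that("model specs validate their combinations", {
  expect_s3_class(model_spec("estimated_value"), "ordval_model_spec")
  expect_error(model_spec("estimated_value", "trembling_hand"), "classic")
  expect_error(model_spec("nonsense"), "arg")
  set <- paper_model_set()
  expect_named(set, c(
    "estimated_value", "classic_utility", "trembling_hand",
    "no_subjective_params"
  ))
  expect_equal(set$trembling_hand$choice_rule, "trembling_hand")
  expect_error(sampler_settings(chains = 1), "chains")
})

test_that("fitting rejects inadequate data and ordinal-only data for the
           utility models", {
  data <- small_dataset(n = 4L, seed = 61)
  expect_error(
    fit_model(model_spec("classic_utility"), data[data$subject_id == "s001", ],
      quick_settings()),
    "2 subjects"
  )
  med <- data
  med$amount <- NA_real_
  med$domain <- "medical"
  expect_error(
    fit_model(model_spec("classic_utility"), med, quick_settings()),
    "amounts"
  )
  expect_error(fit_model(model_spec("estimated_value"), data.frame(a = 1)),
    "columns")
})

test_that("a small estimated-value fit has coherent structure and seeded
           determinism", {
  data <- small_dataset(n = 6L, seed = 62)
  fit <- fit_model(model_spec("estimated_value"), data,
    quick_settings(draws = 200, tune = 200))
  expect_s3_class(fit, "ordval_fit")
  expect_equal(dim(fit$log_lik), c(2L * 200L, nrow(data)))
  expect_true(all(is.finite(fit$log_lik)))
  expect_equal(length(fit$mcmc), 2L)
  # posterior cumulative values are nondecreasing across levels in every draw
  dr <- as.matrix(fit$mcmc[[1]])
  for (s in seq_along(fit$subjects)) {
    nu <- dr[, sprintf("nu[%d,%d]", s, 1:4)]
    expect_true(all(nu >= 0))
  }
  # identical seed reproduces the draws exactly
  fit2 <- fit_model(model_spec("estimated_value"), data,
    quick_settings(draws = 200, tune = 200))
  expect_equal(as.matrix(fit$mcmc[[1]]), as.matrix(fit2$mcmc[[1]]))
})

test_that("subject estimates expose each model's parameter families", {
  data <- small_dataset(n = 5L, seed = 63)
  fit_ev <- fit_model(model_spec("estimated_value"), data,
    quick_settings(draws = 150, tune = 150))
  est <- extract_subject_estimates(fit_ev)
  expect_equal(nrow(est), 5L)
  expect_true(all(c("beta_mean", "gamma_mean", "nu1_mean", "nu4_sd")
    %in% names(est)))
  expect_true(all(est[, grepl("^nu[1-4]_mean$", names(est))] >= 0))
  expect_error(extract_subject_estimates(fit_ev, "alpha"), "not in this model")
  only_beta <- extract_subject_estimates(fit_ev, "beta")
  expect_equal(names(only_beta), c("subject_id", "beta_mean", "beta_sd"))

  fit_nsp <- fit_model(model_spec("no_subjective_params"), data,
    quick_settings(draws = 150, tune = 150))
  expect_equal(nrow(extract_subject_estimates(fit_nsp)), 0L)
})

test_that("the model assigns higher predictive density to its own data than
           to shuffled choices", {
  data <- small_dataset(n = 6L, seed = 64)
  fit <- fit_model(model_spec("classic_utility"), data,
    quick_settings(draws = 250, tune = 250))
  mean_lpd <- mean(rowSums(fit$log_lik))
  expect_true(is.finite(mean_lpd))
  shuffled <- data
  set.seed(1)
  shuffled$chose_lottery <- sample(shuffled$chose_lottery)
  ll_shuf <- ordval:::.pointwise_loglik(
    fit$spec, fit$mcmc, {
      d <- shuffled
      d$sub_index <- match(d$subject_id, fit$subjects)
      d
    },
    length(fit$subjects)
  )
  expect_gt(mean_lpd, mean(rowSums(ll_shuf)))
})

test_that("NUTS and the JAGS reference engine agree on the posterior of a
           shared-parameter model", {
  data <- small_dataset(n = 6L, seed = 65)
  s <- sampler_settings(draws = 1500, tune = 500, chains = 2, seed = 9)
  f_nuts <- fit_model(model_spec("no_subjective_params"), data, s)
  f_jags <- fit_model(model_spec("no_subjective_params"), data, s,
    engine = "jags")
  g_nuts <- unlist(lapply(f_nuts$mcmc, function(m) as.numeric(m[, "gamma"])))
  g_jags <- unlist(lapply(f_jags$mcmc, function(m) as.numeric(m[, "gamma"])))
  expect_equal(mean(g_nuts), mean(g_jags), tolerance = 0.02)
  expect_equal(sd(g_nuts), sd(g_jags), tolerance = 0.15)
})

test_that("NUTS and JAGS agree on subject-level posteriors of the classic
           utility model on small data", {
  data <- small_dataset(n = 5L, seed = 66)
  s <- sampler_settings(draws = 1000, tune = 500, chains = 2, seed = 10)
  f_nuts <- fit_model(model_spec("classic_utility"), data, s)
  f_jags <- fit_model(model_spec("classic_utility"), data, s, engine = "jags")
  e_nuts <- extract_subject_estimates(f_nuts)
  e_jags <- extract_subject_estimates(f_jags)
  # same posterior, two independent samplers: means agree within MC error
  expect_lt(max(abs(e_nuts$beta_mean - e_jags$beta_mean)), 0.1)
  expect_lt(max(abs(e_nuts$alpha_mean - e_jags$alpha_mean)), 0.1)
  expect_gt(cor(e_nuts$gamma_mean, e_jags$gamma_mean), 0.9)
})

test_that("the baseline never outranks the estimated-value model on
           heterogeneous-agent data", {
  data <- small_dataset(n = 8L, seed = 67)
  s <- quick_settings(draws = 300, tune = 300)
  f_ev <- fit_model(model_spec("estimated_value"), data, s)
  f_nsp <- fit_model(model_spec("no_subjective_params"), data, s)
  cmp <- compare_models(list(
    estimated_value = suppressWarnings(psis_loo(f_ev$log_lik)),
    no_subjective_params = suppressWarnings(psis_loo(f_nsp$log_lik))
  ))
  expect_equal(cmp$model[cmp$rank == 0L], "estimated_value")
  expect_gt(cmp$d_loo[cmp$model == "no_subjective_params"], 0)
})
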