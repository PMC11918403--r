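# Exact-LOO oracle: a one-parameter Bayesian logistic model evaluated by
# dense grid quadrature, independent of the PSIS code path.
grid_logistic_fixture <- function(n = 40, n_draws = 2000, seed = 31) {
  set.seed(seed)
  x <- rnorm(n)
  theta_true <- 1.2
  y <- rbinom(n, 1, plogis(theta_true * x))
  grid <- seq(-6, 6, length.out = 4001)
  log_lik_g <- vapply(
    seq_len(n),
    function(i) dbinom(y[i], 1, plogis(grid * x[i]), log = TRUE),
    numeric(length(grid))
  ) # grid x n
  log_post <- dnorm(grid, 0, 1.5, log = TRUE) + rowSums(log_lik_g)
  w <- exp(log_post - max(log_post))
  # exact leave-one-out predictive density by quadrature
  elpd_exact <- vapply(seq_len(n), function(i) {
    w_i <- w / exp(log_lik_g[, i]) # posterior without trial i
    log(sum(w_i * exp(log_lik_g[, i])) / sum(w_i))
  }, numeric(1))
  # posterior draws for the PSIS path
  idx <- sample.int(length(grid), n_draws, replace = TRUE, prob = w)
  list(
    log_lik = log_lik_g[idx, , drop = FALSE],
    elpd_exact = sum(elpd_exact)
  )
}

test_that("PSIS-LOO matches exact quadrature leave-one-out on a small
           logistic model", {
  fx <- grid_logistic_fixture()
  res <- psis_loo(fx$log_lik)
  expect_lt(abs(res$elpd_loo - fx$elpd_exact), 2 * res$se)
  # with one well-identified parameter the agreement is in fact much tighter
  expect_lt(abs(res$elpd_loo - fx$elpd_exact), 0.5)
  expect_gt(res$p_loo, 0)
  expect_lt(res$p_loo, 3)
  expect_true(all(res$pareto_k[is.finite(res$pareto_k)] < 0.7))
})

test_that("zero posterior variance collapses LOO to the log-likelihood sum", {
  ll <- matrix(rep(log(runif(25)), each = 150), 150, 25)
  res <- suppressWarnings(psis_loo(ll))
  expect_equal(res$elpd_loo, sum(ll[1, ]))
  expect_equal(res$p_loo, 0, tolerance = 1e-10)
  expect_equal(res$se, sqrt(25) * sd(ll[1, ]))
})

test_that("duplicating every trial doubles the ELPD estimate", {
  fx <- grid_logistic_fixture(n = 30, seed = 33)
  res1 <- psis_loo(fx$log_lik)
  res2 <- psis_loo(cbind(fx$log_lik, fx$log_lik))
  expect_equal(res2$elpd_loo, 2 * res1$elpd_loo, tolerance = 0.02)
})

test_that("model ranking is invariant to a constant log-lik shift", {
  fx <- grid_logistic_fixture(n = 30, seed = 34)
  noisy <- fx$log_lik + rnorm(length(fx$log_lik), sd = 0.3)
  base <- compare_models(list(a = psis_loo(fx$log_lik), b = psis_loo(noisy)))
  shifted <- compare_models(list(
    a = psis_loo(fx$log_lik + 5), b = psis_loo(noisy + 5)
  ))
  expect_equal(base$model, shifted$model)
  expect_equal(base$rank, shifted$rank)
  expect_equal(base$d_loo, shifted$d_loo, tolerance = 1e-6)
})

test_that("comparison table is ordered, tied models split the weight, and
           the best model gets d_loo 0", {
  fx <- grid_logistic_fixture(n = 30, seed = 35)
  l1 <- psis_loo(fx$log_lik)
  tied <- compare_models(list(m2 = l1, m1 = l1))
  expect_equal(tied$d_loo, c(0, 0))
  expect_equal(tied$weight, c(0.5, 0.5), tolerance = 1e-3)
  expect_equal(tied$model, c("m1", "m2")) # name tie-break, stable
  expect_equal(tied$rank, c(0L, 1L))

  worse <- psis_loo(fx$log_lik - 0.5)
  cmp <- compare_models(list(bad = worse, good = l1))
  expect_equal(cmp$model, c("good", "bad"))
  expect_equal(cmp$elpd_loo[1], l1$elpd_loo)
  expect_equal(cmp$d_loo[2], 0.5 * 30, tolerance = 1e-6)
  expect_gt(cmp$weight[1], 0.9)
  expect_equal(sum(cmp$weight), 1)
  expect_equal(cmp$d_se[2], 0, tolerance = 1e-6) # constant pointwise shift
})

test_that("ill-formed comparisons are rejected", {
  fx <- grid_logistic_fixture(n = 20, seed = 36)
  l1 <- psis_loo(fx$log_lik)
  l2 <- psis_loo(fx$log_lik[, 1:10])
  expect_error(compare_models(list(a = l1, b = l2)), "same trials")
  expect_error(compare_models(list(l1, l1)), "named")
  expect_error(compare_models(list(a = l1)), "at least 2")
  expect_error(psis_loo(fx$log_lik[1:50, ]), "100")
  bad <- fx$log_lik
  bad[1, 1] <- NA
  expect_error(psis_loo(bad), "finite")
})
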