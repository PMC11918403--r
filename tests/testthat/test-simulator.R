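test_that("agent parameters respect their constraint ranges and seed", {
  ag <- draw_agents(300, noise_sd = 0.3, seed = 5)
  expect_equal(nrow(ag), 300L)
  expect_true(all(ag$alpha >= 0.1 & ag$alpha <= 1.6))
  expect_true(all(ag$beta >= -1.4 & ag$beta <= 1.4))
  expect_identical(ag, draw_agents(300, noise_sd = 0.3, seed = 5))
  expect_false(identical(
    ag$alpha, draw_agents(300, noise_sd = 0.3, seed = 6)$alpha
  ))
  expect_error(draw_agents(0), ">= 1")
  expect_error(draw_agents(5, noise_sd = -1), "nonnegative")
})

test_that("uniform draws center on the range midpoints at large n", {
  ag <- draw_agents(10000, seed = 8)
  # Monte-Carlo error ~ range/sqrt(12 n) ~ 0.005
  expect_lt(abs(mean(ag$alpha) - 0.85), 0.02)
  expect_lt(abs(mean(ag$beta) - 0), 0.03)
})

test_that("noise-free agents choose by the classic-utility argmax", {
  design <- data.frame(
    domain = "monetary", trial_index = 1:2, level = c(3L, 2L),
    win_prob = c(0.5, 0.25), ambiguity = 0, is_catch = FALSE,
    repetition = 1L, amount = c(12, 8)
  )
  ag <- data.frame(subject_id = "s1", alpha = 1, beta = 0, noise_sd = 0)
  ch <- simulate_choices(ag, design, seed = 1)
  # SV 6 > 5 certain: lottery; SV 2 < 5: certain
  expect_identical(ch$chose_lottery, c(TRUE, FALSE))
})

test_that("noise-free agents never take the dominated catch lottery for
           moderate ambiguity attitudes", {
  d <- build_design("in_person", "monetary")
  ag <- draw_agents(20, noise_sd = 0, seed = 3, beta_range = c(-1, 1))
  ch <- simulate_choices(ag, d, seed = 4)
  expect_false(any(ch$chose_lottery[ch$is_catch]))
})

test_that("extreme ambiguity seekers can rationally fail high-ambiguity
           catch trials", {
  # beta A/2 > P - 1 flips the dominance: (0.5 + 1.4*0.37) > 1
  d <- build_design("in_person", "monetary")
  ag <- data.frame(subject_id = "s1", alpha = 1, beta = -1.4, noise_sd = 0)
  ch <- simulate_choices(ag, d, seed = 1)
  catch_hi <- ch$is_catch & ch$ambiguity == 0.74
  expect_true(all(ch$chose_lottery[catch_hi]))
  expect_false(any(ch$chose_lottery[ch$is_catch & ch$ambiguity == 0]))
})

test_that("catch failures increase monotonically with decision noise", {
  d <- build_design("in_person", "monetary")
  rate <- vapply(c(0, 0.3, 1.0), function(ns) {
    ag <- draw_agents(40, noise_sd = ns, seed = 7, beta_range = c(-1, 1))
    ch <- simulate_choices(ag, d, seed = 8)
    mean(ch$chose_lottery[ch$is_catch])
  }, numeric(1))
  expect_equal(rate[1], 0)
  expect_true(all(diff(rate) > 0))
})

test_that("lottery choice rate increases with the offered amount", {
  d <- build_design("in_person", "monetary")
  ag <- draw_agents(100, noise_sd = 0.5, seed = 9)
  ch <- simulate_choices(ag, d, seed = 10)
  risky50 <- ch[!ch$is_catch & ch$ambiguity == 0 & ch$win_prob == 0.5, ]
  rate_by_v <- tapply(risky50$chose_lottery, risky50$amount, mean)
  expect_true(all(diff(rate_by_v[order(as.numeric(names(rate_by_v)))]) > 0))
})

test_that("the simulation grid yields one reproducible dataset per cell", {
  g <- simulation_grid(seed = 2)
  expect_equal(nrow(g), 7L)
  expect_setequal(
    paste(g$n_subjects, g$noise_sd),
    c("30 0.1", "30 0.3", "30 0.5", "60 0.3", "60 0.5", "120 0.5", "300 0.5")
  )
  d <- build_design("in_person", "monetary")
  small <- g[1:2, ]
  attr(small, "seed") <- 2L
  out <- run_simulation_grid(small, d)
  expect_named(out, c("n30_noise0.1", "n30_noise0.3"))
  expect_equal(nrow(out[[1]]), 30L * nrow(d))
  expect_equal(length(unique(out[[1]]$subject_id)), 30L)
  expect_false(is.null(attr(out[[1]], "agents")))
  out2 <- run_simulation_grid(small, d)
  expect_identical(out, out2)
})

test_that("simulation refuses designs without numeric amounts", {
  d <- build_design("in_person", "medical")
  ag <- draw_agents(3, seed = 1)
  expect_error(simulate_choices(ag, d), "amounts")
})
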