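# shared fixtures: small seeded simulations and reduced sampler settings

quick_settings <- function(draws = 300L, tune = 300L, chains = 2L, seed = 42L) {
  sampler_settings(draws = draws, tune = tune, chains = chains, seed = seed)
}

# a small excluded-and-filtered dataset for fitting tests
small_dataset <- function(n = 8L, noise_sd = 0.3, seed = 11L) {
  d <- build_design("in_person", "monetary")
  cd <- simulate_choices(draw_agents(n, noise_sd = noise_sd, seed = seed),
    d,
    seed = seed + 1L
  )
  apply_exclusions(cd)$data
}

# hand-built dataset: one subject with a chosen number of catch failures and
# lottery choices, padded with a well-behaved second subject
two_subject_dataset <- function(catch_failures, lottery_choices) {
  d <- build_design("in_person", "monetary")
  mk <- function(id, fails, lotto) {
    x <- cbind(data.frame(subject_id = id), d)
    x$chose_lottery <- FALSE
    ci <- which(x$is_catch)
    x$chose_lottery[ci[seq_len(fails)]] <- TRUE
    ni <- which(!x$is_catch)
    x$chose_lottery[ni[seq_len(lotto)]] <- TRUE
    x
  }
  rbind(mk("target", catch_failures, lottery_choices), mk("filler", 0L, 30L))
}
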