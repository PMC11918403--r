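#' Draw simulated agents with heterogeneous uncertainty attitudes
#'
#' Each agent gets an independent risk attitude alpha drawn uniformly from
#' \[0.1, 1.6\] and ambiguity attitude beta uniform on \[-1.4, 1.4\] (the
#' ranges that keep the classic utility model identifiable in recovery
#' studies), plus a common decision-noise standard deviation.
#'
#' @param n Number of agents, at least 1.
#' @param noise_sd Standard deviation of the zero-mean Gaussian decision
#'   noise added to the subjective-value difference on each trial.
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param alpha_range,beta_range Numeric length-2 ranges for the uniform
#'   parameter draws.
#' @return A data.frame with columns \code{subject_id}, \code{alpha},
#'   \code{beta}, \code{noise_sd}.
#' @examples
#' draw_agents(5, noise_sd = 0.3, seed = 1)
#' @export
draw_agents <- function(n, noise_sd = 0, seed = 1,
                        alpha_range = c(0.1, 1.6),
                        beta_range = c(-1.4, 1.4)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a single integer >= 1")
  }
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  n <- as.integer(n)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    alpha = stats::runif(n, alpha_range[1], alpha_range[2]),
    beta = stats::runif(n, beta_range[1], beta_range[2]),
    noise_sd = noise_sd
  )
}

#' Simulate choices from classic-utility agents on a task design
#'
#' For every agent and trial, the lottery's subjective value is computed
#' with [sv_classic()] from the agent's (alpha, beta) and compared with the
#' certain option's value (the level-1 amount at P = 1, A = 0). A single
#' zero-mean Gaussian noise draw with the agent's \code{noise_sd} is added
#' to the value difference; the agent chooses the lottery iff the noisy
#' difference is positive (ties go to the certain option). With
#' \code{noise_sd = 0} the policy is the deterministic argmax of the model.
#'
#' @param agents Agents from [draw_agents()] (columns subject_id, alpha,
#'   beta, noise_sd).
#' @param design A trial table from [build_design()]; must be a monetary
#'   design (the generator needs numeric amounts).
#' @param seed Integer seed for the noise draws.
#' @return A \code{ChoiceDataset}: long data.frame with one row per
#'   agent x trial, the design columns, and \code{chose_lottery}; the true
#'   generating parameters are attached as attribute \code{"agents"}.
#' @export
simulate_choices <- function(agents, design, seed = 1) {
  req <- c("subject_id", "alpha", "beta", "noise_sd")
  if (!is.data.frame(agents) || !all(req %in% names(agents)) ||
    nrow(agents) == 0L) {
    stop("'agents' must be a nonempty data.frame from draw_agents()")
  }
  if (!is.data.frame(design) || nrow(design) == 0L) {
    stop("'design' must be a nonempty trial table")
  }
  if (anyNA(design$amount)) {
    stop("simulation requires a design with numeric amounts (monetary domain)")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  n_s <- nrow(agents)
  n_t <- nrow(design)
  idx_s <- rep(seq_len(n_s), each = n_t)
  idx_t <- rep(seq_len(n_t), times = n_s)

  certain_amount <- outcome_scale("monetary")$amounts[1L]
  alpha <- agents$alpha[idx_s]
  beta <- agents$beta[idx_s]
  sv_lot <- sv_classic(
    design$win_prob[idx_t], design$ambiguity[idx_t],
    design$amount[idx_t], alpha, beta
  )
  sv_cer <- certain_amount^alpha
  noise <- stats::rnorm(n_s * n_t, mean = 0, sd = agents$noise_sd[idx_s])

  out <- cbind(
    data.frame(subject_id = agents$subject_id[idx_s]),
    design[idx_t, , drop = FALSE],
    data.frame(chose_lottery = (sv_lot - sv_cer + noise) > 0)
  )
  rownames(out) <- NULL
  attr(out, "agents") <- agents
  out
}

#' The default simulation grid of (sample size, noise) cells
#'
#' Seven cells spanning the sample sizes and decision-noise levels used for
#' the model-recovery study: (30, 0.1), (30, 0.3), (30, 0.5), (60, 0.3),
#' (60, 0.5), (120, 0.5), (300, 0.5).
#'
#' @param seed Integer base seed recorded in the grid.
#' @return A data.frame with columns \code{n_subjects}, \code{noise_sd} and
#'   attribute \code{"seed"}.
#' @export
simulation_grid <- function(seed = 1) {
  g <- data.frame(
    n_subjects = c(30L, 30L, 30L, 60L, 60L, 120L, 300L),
    noise_sd = c(0.1, 0.3, 0.5, 0.3, 0.5, 0.5, 0.5)
  )
  attr(g, "seed") <- as.integer(seed)
  g
}

#' Run the full simulation grid
#'
#' Generates one simulated dataset per grid cell: fresh agents at the cell's
#' sample size and noise level, choices on the given design. Per-cell seeds
#' are derived deterministically from the grid seed, so the whole grid is
#' reproducible.
#'
#' @param grid A [simulation_grid()] data.frame (columns n_subjects,
#'   noise_sd; attribute "seed").
#' @param design A monetary trial table from [build_design()].
#' @return A named list of ChoiceDatasets, names like \code{"n30_noise0.1"};
#'   each carries its true agents as attribute \code{"agents"}.
#' @export
run_simulation_grid <- function(grid = simulation_grid(), design) {
  if (!all(c("n_subjects", "noise_sd") %in% names(grid)) || nrow(grid) == 0L) {
    stop("'grid' must have columns n_subjects and noise_sd")
  }
  base_seed <- attr(grid, "seed")
  if (is.null(base_seed)) base_seed <- 1L
  out <- vector("list", nrow(grid))
  names(out) <- sprintf("n%d_noise%g", grid$n_subjects, grid$noise_sd)
  for (i in seq_len(nrow(grid))) {
    agents <- draw_agents(grid$n_subjects[i],
      noise_sd = grid$noise_sd[i],
      seed = base_seed + 1000L * i
    )
    out[[i]] <- simulate_choices(agents, design, seed = base_seed + 1000L * i + 1L)
  }
  out
}
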