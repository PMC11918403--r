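#' Specify a hierarchical choice model
#'
#' Combines a subjective-value model with a choice rule. The model set
#' mirrors the four fitted variants: estimated-value and classic-utility
#' with the logistic rule, classic-utility with the trembling-hand rule,
#' and the no-subjective-parameters baseline. The trembling-hand rule is
#' only available with the classic utility model.
#'
#' @param sv_model One of "classic_utility", "estimated_value",
#'   "no_subjective_params".
#' @param choice_rule "logistic" or "trembling_hand".
#' @param hyperpriors An [hyperprior_settings()] object.
#' @return An object of class \code{ordval_model_spec}.
#' @examples
#' model_spec("estimated_value")
#' @export
model_spec <- function(sv_model = c(
                         "classic_utility", "estimated_value",
                         "no_subjective_params"
                       ),
                       choice_rule = c("logistic", "trembling_hand"),
                       hyperpriors = hyperprior_settings()) {
  sv_model <- match.arg(sv_model)
  choice_rule <- match.arg(choice_rule)
  stopifnot(inherits(hyperpriors, "ordval_hyperpriors"))
  if (choice_rule == "trembling_hand" && sv_model != "classic_utility") {
    stop("the trembling-hand rule is only paired with the classic utility model")
  }
  structure(
    list(
      sv_model = sv_model, choice_rule = choice_rule,
      hyperpriors = hyperpriors
    ),
    class = "ordval_model_spec"
  )
}

#' @export
print.ordval_model_spec <- function(x, ...) {
  cat("Model spec:", x$sv_model, "+", x$choice_rule, "choice rule\n")
  invisible(x)
}

#' The canonical model set
#'
#' The four model variants compared against each other; medical-domain data
#' support only the estimated-value and baseline models (no cardinal
#' outcome amounts).
#'
#' @param hyperpriors An [hyperprior_settings()] object shared by all
#'   specs.
#' @return Named list of \code{ordval_model_spec} objects.
#' @export
paper_model_set <- function(hyperpriors = hyperprior_settings()) {
  list(
    estimated_value = model_spec("estimated_value", "logistic", hyperpriors),
    classic_utility = model_spec("classic_utility", "logistic", hyperpriors),
    trembling_hand = model_spec("classic_utility", "trembling_hand", hyperpriors),
    no_subjective_params = model_spec("no_subjective_params", "logistic", hyperpriors)
  )
}

#' MCMC sampler settings
#'
#' Defaults: 1000 retained draws per chain after 1000 tuning steps, 4
#' chains, no thinning. \code{tune} is spent half on sampler adaptation and
#' half on burn-in. \code{target_accept} is recorded for provenance; the
#' Gibbs/slice sampler has no step-size acceptance tuning, so it is inert.
#'
#' @param draws Retained draws per chain.
#' @param tune Tuning (adaptation + burn-in) steps per chain.
#' @param chains Number of chains (>= 2; split R-hat needs multiple chains).
#' @param target_accept Recorded target acceptance rate.
#' @param seed Integer seed controlling inits and all chain RNGs.
#' @return An object of class \code{ordval_sampler_settings}.
#' @export
sampler_settings <- function(draws = 1000L, tune = 1000L, chains = 4L,
                             target_accept = 0.8, seed = 1L) {
  stopifnot(draws >= 1, tune >= 1, chains >= 2)
  structure(
    list(
      draws = as.integer(draws), tune = as.integer(tune),
      chains = as.integer(chains), target_accept = target_accept,
      seed = as.integer(seed)
    ),
    class = "ordval_sampler_settings"
  )
}

# ---- JAGS model code -------------------------------------------------------

.jags_hyper_block <- function(hp) {
  # shared beta-hierarchy block; dnorm takes precision
  sprintf(
    "  mub ~ dnorm(%g, %g)\n  sigb ~ dgamma(%g, %g)\n  taub <- pow(sigb, -2)\n",
    hp$beta_mean_loc, 1 / hp$beta_mean_scale^2,
    hp$beta_sd_shape, hp$beta_sd_rate
  )
}

.jags_model_code <- function(spec) {
  hp <- spec$hyperpriors
  glog <- sprintf(
    "gamma[s] ~ dlnorm(%g, %g)",
    hp$gamma_log_loc, 1 / hp$gamma_log_scale^2
  )
  beta_s <- sprintf(
    "beta[s] ~ dnorm(mub, taub) T(%g, %g)", hp$beta_lower, hp$beta_upper
  )
  if (spec$sv_model == "classic_utility") {
    alpha_block <- sprintf(
      paste0(
        "  a1 ~ dnorm(%g, %g) T(0,)\n",
        "  a2 ~ dnorm(%g, %g) T(0,)\n"
      ),
      hp$alpha_shape1_loc, 1 / hp$alpha_shape1_scale^2,
      hp$alpha_shape2_loc, 1 / hp$alpha_shape2_scale^2
    )
    sv <- paste0(
      "    svl[t] <- (P[t] - beta[sub[t]] * A[t] / 2) * pow(V[t], alpha[sub[t]])\n",
      "    svs[t] <- pow(Vc, alpha[sub[t]])\n"
    )
    if (spec$choice_rule == "logistic") {
      subj <- paste0(
        "    ar[s] ~ dbeta(a1, a2)\n",
        "    alpha[s] <- 2 * ar[s]\n",
        "    ", beta_s, "\n",
        "    ", glog, "\n"
      )
      lik <- paste0(
        sv,
        "    eta[t] <- gamma[sub[t]] * (svl[t] - svs[t])\n",
        "    p[t] <- ilogit(max(-30, min(30, eta[t])))\n"
      )
      extra <- ""
    } else {
      subj <- paste0(
        "    ar[s] ~ dbeta(a1, a2)\n",
        "    alpha[s] <- 2 * ar[s]\n",
        "    ", beta_s, "\n",
        "    delta[s] ~ dbeta(d1, d2)\n"
      )
      lik <- paste0(
        sv,
        "    eta[t] <- svl[t] - svs[t]\n",
        "    p[t] <- (1 - delta[sub[t]]) * ilogit(max(-30, min(30, eta[t]))) + delta[sub[t]] * 0.5\n"
      )
      extra <- sprintf(
        "  d1 ~ dnorm(%g, %g) T(1,)\n  d2 ~ dnorm(%g, %g) T(1,)\n",
        hp$delta_shape1_loc, 1 / hp$delta_shape1_scale^2,
        hp$delta_shape2_loc, 1 / hp$delta_shape2_scale^2
      )
    }
    code <- paste0(
      "model {\n", alpha_block, extra, .jags_hyper_block(hp),
      "  for (s in 1:S) {\n", subj, "  }\n",
      "  for (t in 1:N) {\n", lik,
      "    y[t] ~ dbern(p[t])\n  }\n}\n"
    )
  } else if (spec$sv_model == "estimated_value") {
    code <- paste0(
      "model {\n",
      sprintf(
        paste0(
          "  for (i in 1:4) {\n",
          "    munu[i] ~ dnorm(%g, %g) T(0,)\n",
          "    signu[i] ~ dgamma(%g, %g)\n",
          "    taunu[i] <- pow(signu[i], -2)\n  }\n"
        ),
        hp$nu_mean_loc, 1 / hp$nu_mean_scale^2,
        hp$nu_sd_shape, hp$nu_sd_rate
      ),
      .jags_hyper_block(hp),
      "  for (s in 1:S) {\n",
      "    ", beta_s, "\n",
      "    ", glog, "\n",
      "    for (i in 1:4) {\n      nu[s, i] ~ dnorm(munu[i], taunu[i]) T(0,)\n    }\n",
      "    cum[s, 1] <- nu[s, 1]\n",
      "    for (i in 2:4) {\n      cum[s, i] <- cum[s, i - 1] + nu[s, i]\n    }\n",
      "  }\n",
      "  for (t in 1:N) {\n",
      "    svl[t] <- (P[t] - beta[sub[t]] * A[t] / 2) * cum[sub[t], LVL[t]]\n",
      "    eta[t] <- gamma[sub[t]] * (svl[t] - cum[sub[t], 1])\n",
      "    p[t] <- ilogit(max(-30, min(30, eta[t])))\n",
      "    y[t] ~ dbern(p[t])\n  }\n}\n"
    )
  } else { # no_subjective_params
    code <- paste0(
      "model {\n",
      sprintf(
        "  gamma ~ dlnorm(%g, %g)\n",
        hp$gamma_log_loc, 1 / hp$gamma_log_scale^2
      ),
      "  for (t in 1:N) {\n",
      "    svl[t] <- (P[t] - A[t] / 2) * LVL[t]\n",
      "    eta[t] <- gamma * (svl[t] - 1)\n",
      "    p[t] <- ilogit(max(-30, min(30, eta[t])))\n",
      "    y[t] ~ dbern(p[t])\n  }\n}\n"
    )
  }
  code
}

.jags_inits <- function(spec, n_subjects, settings) {
  hp <- spec$hyperpriors
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  lapply(seq_len(settings$chains), function(ch) {
    set.seed(settings$seed * 1000L + ch)
    s <- n_subjects
    ini <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = settings$seed * 1000L + ch
    )
    if (spec$sv_model == "no_subjective_params") {
      ini$gamma <- stats::rlnorm(1, hp$gamma_log_loc, hp$gamma_log_scale)
      return(ini)
    }
    ini$mub <- stats::rnorm(1, hp$beta_mean_loc, 0.3)
    ini$sigb <- stats::rgamma(1, hp$beta_sd_shape, hp$beta_sd_rate)
    ini$beta <- pmin(hp$beta_upper - 0.05, pmax(
      hp$beta_lower + 0.05,
      stats::rnorm(s, hp$beta_mean_loc, 0.4)
    ))
    if (spec$sv_model == "classic_utility") {
      ini$a1 <- abs(stats::rnorm(1, hp$alpha_shape1_loc, hp$alpha_shape1_scale)) + 0.5
      ini$a2 <- abs(stats::rnorm(1, hp$alpha_shape2_loc, hp$alpha_shape2_scale)) + 0.5
      ini$ar <- stats::rbeta(s, 4, 7)
      if (spec$choice_rule == "trembling_hand") {
        ini$d1 <- 1 + abs(stats::rnorm(1, 1, 0.5))
        ini$d2 <- 1 + abs(stats::rnorm(1, 1, 0.5))
        ini$delta <- stats::rbeta(s, 2, 8)
      } else {
        ini$gamma <- stats::rlnorm(s, hp$gamma_log_loc, hp$gamma_log_scale)
      }
    } else {
      ini$munu <- abs(stats::rnorm(4, hp$nu_mean_loc, 1)) + 0.5
      ini$signu <- stats::rgamma(4, hp$nu_sd_shape, hp$nu_sd_rate)
      ini$nu <- matrix(abs(stats::rnorm(s * 4, hp$nu_mean_loc, 1)) + 0.2, s, 4)
      ini$gamma <- stats::rlnorm(s, hp$gamma_log_loc, hp$gamma_log_scale)
    }
    ini
  })
}

.monitored <- function(spec) {
  switch(spec$sv_model,
    classic_utility = c(
      "alpha", "beta", "a1", "a2", "mub", "sigb",
      if (spec$choice_rule == "logistic") "gamma" else c("delta", "d1", "d2")
    ),
    estimated_value = c("beta", "gamma", "nu", "munu", "signu", "mub", "sigb"),
    no_subjective_params = "gamma"
  )
}

# prepare model-ready trial data: non-catch rows, subject index, validated
.fit_frame <- function(spec, data) {
  req <- c("subject_id", "level", "win_prob", "ambiguity", "chose_lottery")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    stop("'data' must have columns ", paste(req, collapse = ", "))
  }
  if ("is_catch" %in% names(data) && any(data$is_catch)) {
    message("dropping ", sum(data$is_catch), " catch trials before fitting")
    data <- data[!data$is_catch, , drop = FALSE]
  }
  if (spec$sv_model == "classic_utility") {
    if (!"amount" %in% names(data) || anyNA(data$amount)) {
      stop(
        "the ", spec$sv_model, " model needs numeric outcome amounts; ",
        "ordinal-only (medical) data support the estimated_value and ",
        "no_subjective_params models"
      )
    }
  }
  subjects <- unique(data$subject_id)
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  per <- table(data$subject_id)
  if (any(per < 2L)) stop("every subject needs at least 2 modeled trials")
  data$sub_index <- match(data$subject_id, subjects)
  list(data = data, subjects = subjects)
}

#' Fit a hierarchical choice model by MCMC
#'
#' Builds the hierarchical Bayesian model implied by \code{spec} (partial
#' pooling of subject-level parameters through group-level hyperpriors) and
#' samples the posterior with the package's No-U-Turn sampler (NUTS):
#' Hamiltonian Monte Carlo on the unconstrained scale with dual-averaging
#' step-size adaptation to \code{target_accept} and a diagonal mass matrix
#' estimated during warmup. Per-trial pointwise log-likelihoods are
#' computed from the retained draws for PSIS-LOO, and convergence
#' diagnostics (rank-normalized split R-hat, bulk ESS, divergence count)
#' are attached. A Gibbs/slice reference implementation of the same models
#' (JAGS) is available via \code{engine = "jags"}; it defines the identical
#' posterior and serves as an independent cross-check, but mixes less
#' efficiently per draw.
#'
#' @param spec An [model_spec()] object.
#' @param data A ChoiceDataset, normally after [apply_exclusions()]; catch
#'   trials still present are dropped with a message. At least 2 subjects
#'   with at least 2 trials each.
#' @param settings An [sampler_settings()] object.
#' @param engine "nuts" (default) or "jags" (reference implementation).
#' @return An object of class \code{ordval_fit}: list with \code{mcmc}
#'   (a \code{coda::mcmc.list} of monitored parameters), \code{log_lik}
#'   (draws x trials matrix), \code{diagnostics} (see [diagnostics()]),
#'   \code{spec}, \code{settings}, \code{subjects}, \code{data} (the
#'   modeled trials), \code{sampler_info} and \code{converged} (max R-hat
#'   <= 1.01 and no non-finite likelihood).
#' @examples
#' \donttest{
#' d <- simulate_choices(draw_agents(8, 0.3, seed = 1),
#'                       build_design("in_person", "monetary"))
#' ex <- apply_exclusions(d)
#' fit <- fit_model(model_spec("no_subjective_params"), ex$data,
#'                  sampler_settings(draws = 200, tune = 200, chains = 2))
#' fit$diagnostics$max_rhat
#' }
#' @export
fit_model <- function(spec, data, settings = sampler_settings(),
                      engine = c("nuts", "jags")) {
  stopifnot(inherits(spec, "ordval_model_spec"))
  stopifnot(inherits(settings, "ordval_sampler_settings"))
  engine <- match.arg(engine)
  ff <- .fit_frame(spec, data)
  d <- ff$data
  n_s <- length(ff$subjects)

  if (engine == "nuts") {
    mcl_info <- .fit_nuts(spec, d, n_s, settings)
  } else {
    mcl_info <- .fit_jags(spec, d, n_s, settings)
  }
  mcl <- mcl_info$mcmc

  log_lik <- .pointwise_loglik(spec, mcl, d, n_s)
  diag <- diagnostics(mcl)
  diag$n_divergences <- mcl_info$n_divergences
  fit <- structure(
    list(
      mcmc = mcl,
      log_lik = log_lik,
      diagnostics = diag,
      spec = spec,
      settings = settings,
      subjects = ff$subjects,
      data = d,
      sampler_info = mcl_info$info,
      converged = is.finite(diag$max_rhat) && diag$max_rhat <= 1.01 &&
        all(is.finite(log_lik))
    ),
    class = "ordval_fit"
  )
  if (!all(is.finite(log_lik))) {
    warning("non-finite pointwise log-likelihoods; inspect the fit",
      call. = FALSE
    )
  }
  if (diag$n_divergences > 0L) {
    warning(diag$n_divergences, " divergent transitions after warmup",
      call. = FALSE
    )
  }
  fit
}

# ---- NUTS engine -----------------------------------------------------------

.hyper_vec <- function(spec) {
  hp <- spec$hyperpriors
  switch(spec$sv_model,
    classic_utility = c(
      hp$alpha_shape1_loc, hp$alpha_shape1_scale,
      hp$alpha_shape2_loc, hp$alpha_shape2_scale,
      hp$beta_mean_loc, hp$beta_mean_scale,
      hp$beta_sd_shape, hp$beta_sd_rate,
      hp$beta_lower, hp$beta_upper,
      hp$gamma_log_loc, hp$gamma_log_scale,
      hp$delta_shape1_loc, hp$delta_shape1_scale
    ),
    estimated_value = c(
      hp$beta_mean_loc, hp$beta_mean_scale,
      hp$beta_sd_shape, hp$beta_sd_rate,
      hp$beta_lower, hp$beta_upper,
      hp$gamma_log_loc, hp$gamma_log_scale,
      hp$nu_mean_loc, hp$nu_mean_scale,
      hp$nu_sd_shape, hp$nu_sd_rate
    ),
    no_subjective_params = c(hp$gamma_log_loc, hp$gamma_log_scale)
  )
}

.fit_nuts <- function(spec, d, n_s, settings) {
  ndata <- list(
    y = as.integer(d$chose_lottery),
    sub = as.integer(d$sub_index - 1L),
    P = d$win_prob,
    A = d$ambiguity,
    S = n_s,
    hyper = .hyper_vec(spec)
  )
  kernel <- switch(spec$sv_model,
    classic_utility = {
      ndata$V <- d$amount
      ndata$Vc <- outcome_scale(d$domain[1L])$amounts[1L]
      if (spec$choice_rule == "logistic") {
        lp_grad_cu_logistic
      } else {
        lp_grad_cu_trembling
      }
    },
    estimated_value = {
      ndata$LVL <- as.integer(d$level)
      lp_grad_ev
    },
    no_subjective_params = {
      ndata$sv <- (d$win_prob - d$ambiguity / 2) * d$level
      lp_grad_nsp
    }
  )
  lp_grad <- function(theta) kernel(theta, ndata)

  dim_u <- switch(spec$sv_model,
    classic_utility = if (spec$choice_rule == "logistic") {
      4L + 3L * n_s
    } else {
      6L + 3L * n_s
    },
    estimated_value = 10L + 6L * n_s,
    no_subjective_params = 1L
  )
  center <- .init_center(spec, n_s)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  inits <- lapply(seq_len(settings$chains), function(ch) {
    set.seed(settings$seed * 1000L + 500L + ch)
    center + stats::rnorm(dim_u, 0, 0.15)
  })

  chains <- .nuts_sample(lp_grad, inits,
    n_warmup = settings$tune, n_draws = settings$draws,
    target_accept = settings$target_accept, seed = settings$seed
  )
  mcl <- coda::mcmc.list(lapply(chains, function(ch) {
    coda::mcmc(.constrain_draws(spec, ch$draws, n_s))
  }))
  list(
    mcmc = mcl,
    n_divergences = sum(vapply(chains, `[[`, integer(1), "n_divergences")),
    info = list(
      engine = "nuts",
      step_size = vapply(chains, `[[`, numeric(1), "eps"),
      accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
      mean_treedepth = vapply(chains, `[[`, numeric(1), "mean_treedepth")
    )
  )
}

# unconstrained initialization centers (prior-typical values)
.init_center <- function(spec, n_s) {
  hp <- spec$hyperpriors
  switch(spec$sv_model,
    classic_utility = {
      head <- c(
        log(hp$alpha_shape1_loc), log(hp$alpha_shape2_loc),
        hp$beta_mean_loc, 0,
        if (spec$choice_rule == "trembling_hand") c(0, 0)
      )
      c(head, rep(0, 3L * n_s))
    },
    estimated_value = c(
      hp$beta_mean_loc, 0,
      rep(log(hp$nu_mean_loc), 4L), rep(log(2), 4L),
      rep(0, 2L * n_s), rep(0, 4L * n_s)
    ),
    no_subjective_params = hp$gamma_log_loc
  )
}

# map unconstrained NUTS draws to the constrained, conventionally named
# parameter matrix used across the package
.constrain_draws <- function(spec, u, n_s) {
  hp <- spec$hyperpriors
  bL <- hp$beta_lower
  bU <- hp$beta_upper
  pl <- function(x) stats::plogis(x)
  if (spec$sv_model == "classic_utility") {
    trembling <- spec$choice_rule == "trembling_hand"
    off <- if (trembling) 6L else 4L
    out <- cbind(
      exp(u[, 1L]), exp(u[, 2L]), u[, 3L], exp(u[, 4L]),
      if (trembling) 1 + exp(u[, 5L]),
      if (trembling) 1 + exp(u[, 6L]),
      2 * pl(u[, off + seq_len(n_s), drop = FALSE]),
      bL + (bU - bL) * pl(u[, off + n_s + seq_len(n_s), drop = FALSE]),
      if (trembling) {
        pl(u[, off + 2L * n_s + seq_len(n_s), drop = FALSE])
      } else {
        exp(u[, off + 2L * n_s + seq_len(n_s), drop = FALSE])
      }
    )
    colnames(out) <- c(
      "a1", "a2", "mub", "sigb",
      if (trembling) c("d1", "d2"),
      sprintf("alpha[%d]", seq_len(n_s)),
      sprintf("beta[%d]", seq_len(n_s)),
      sprintf(if (trembling) "delta[%d]" else "gamma[%d]", seq_len(n_s))
    )
  } else if (spec$sv_model == "estimated_value") {
    munu <- exp(u[, 2L + 1:4, drop = FALSE])
    signu <- exp(u[, 6L + 1:4, drop = FALSE])
    # nu is non-centered through the truncated-normal inverse CDF
    w <- u[, 10L + 2L * n_s + seq_len(4L * n_s), drop = FALSE]
    ii <- rep(1:4, each = n_s)
    r <- munu[, ii, drop = FALSE] / signu[, ii, drop = FALSE]
    uq <- pnorm(-r) + pnorm(w) * pnorm(r)
    uq <- pmin(pmax(uq, 1e-16), 1 - 1e-16)
    nu <- munu[, ii, drop = FALSE] + signu[, ii, drop = FALSE] * qnorm(uq)
    nu <- pmax(nu, 1e-12)
    out <- cbind(
      u[, 1L], exp(u[, 2L]),
      exp(u[, 2L + 1:4, drop = FALSE]), signu,
      bL + (bU - bL) * pl(u[, 10L + seq_len(n_s), drop = FALSE]),
      exp(u[, 10L + n_s + seq_len(n_s), drop = FALSE]),
      nu
    )
    colnames(out) <- c(
      "mub", "sigb", sprintf("munu[%d]", 1:4), sprintf("signu[%d]", 1:4),
      sprintf("beta[%d]", seq_len(n_s)),
      sprintf("gamma[%d]", seq_len(n_s)),
      sprintf("nu[%d,%d]", rep(seq_len(n_s), 4L), rep(1:4, each = n_s))
    )
  } else {
    out <- cbind(exp(u[, 1L, drop = FALSE]))
    colnames(out) <- "gamma"
  }
  out
}

# ---- JAGS reference engine -------------------------------------------------

.fit_jags <- function(spec, d, n_s, settings) {
  jdata <- list(
    N = nrow(d),
    y = as.integer(d$chose_lottery),
    sub = d$sub_index,
    P = d$win_prob,
    A = d$ambiguity
  )
  if (spec$sv_model == "classic_utility") {
    jdata$V <- d$amount
    jdata$Vc <- outcome_scale(d$domain[1L])$amounts[1L]
    jdata$S <- n_s
  } else if (spec$sv_model == "estimated_value") {
    jdata$LVL <- d$level
    jdata$S <- n_s
  } else {
    jdata$LVL <- d$level
    jdata$sub <- NULL
  }

  code <- .jags_model_code(spec)
  inits <- .jags_inits(spec, n_s, settings)
  adapt <- max(100L, floor(settings$tune / 2))
  burn <- settings$tune - adapt

  jm <- rjags::jags.model(textConnection(code),
    data = jdata, inits = inits,
    n.chains = settings$chains, n.adapt = adapt, quiet = TRUE
  )
  if (burn > 0L) stats::update(jm, n.iter = burn, progress.bar = "none")
  mcl <- rjags::coda.samples(jm, .monitored(spec),
    n.iter = settings$draws,
    progress.bar = "none"
  )

  list(mcmc = mcl, n_divergences = 0L, info = list(engine = "jags"))
}

#' @export
print.ordval_fit <- function(x, ...) {
  cat(
    "Hierarchical fit:", x$spec$sv_model, "+", x$spec$choice_rule, "rule\n",
    length(x$subjects), "subjects,", nrow(x$data), "trials,",
    x$settings$chains, "chains x", x$settings$draws, "draws\n"
  )
  cat(sprintf(
    "  max split R-hat %.4f | min bulk ESS %.0f | converged: %s\n",
    x$diagnostics$max_rhat, x$diagnostics$min_ess, x$converged
  ))
  invisible(x)
}

# draws x trials pointwise Bernoulli log-likelihood; log probabilities are
# evaluated on the log scale so extreme value differences stay finite
.pointwise_loglik <- function(spec, mcl, d, n_s) {
  draws <- as.matrix(do.call(rbind, lapply(mcl, as.matrix)))
  s_draws <- nrow(draws)
  n <- nrow(d)
  ll <- matrix(NA_real_, s_draws, n)
  y <- as.integer(d$chose_lottery)
  # log P(choice) for a logistic predictor: plogis on the log scale
  bern_ll <- function(yi, eta) {
    if (yi == 1L) {
      stats::plogis(eta, log.p = TRUE)
    } else {
      stats::plogis(-eta, log.p = TRUE)
    }
  }

  if (spec$sv_model == "classic_utility") {
    vc <- outcome_scale(d$domain[1L])$amounts[1L]
    alpha <- draws[, sprintf("alpha[%d]", seq_len(n_s)), drop = FALSE]
    beta <- draws[, sprintf("beta[%d]", seq_len(n_s)), drop = FALSE]
    if (spec$choice_rule == "logistic") {
      gamma <- draws[, sprintf("gamma[%d]", seq_len(n_s)), drop = FALSE]
    } else {
      delta <- draws[, sprintf("delta[%d]", seq_len(n_s)), drop = FALSE]
    }
    for (t in seq_len(n)) {
      s <- d$sub_index[t]
      svl <- (d$win_prob[t] - beta[, s] * d$ambiguity[t] / 2) *
        d$amount[t]^alpha[, s]
      svs <- vc^alpha[, s]
      if (spec$choice_rule == "logistic") {
        ll[, t] <- bern_ll(y[t], gamma[, s] * (svl - svs))
      } else {
        p <- (1 - delta[, s]) * stats::plogis(svl - svs) + delta[, s] / 2
        p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
        ll[, t] <- if (y[t] == 1L) log(p) else log1p(-p)
      }
    }
  } else if (spec$sv_model == "estimated_value") {
    beta <- draws[, sprintf("beta[%d]", seq_len(n_s)), drop = FALSE]
    gamma <- draws[, sprintf("gamma[%d]", seq_len(n_s)), drop = FALSE]
    nu <- lapply(1:4, function(i) {
      draws[, sprintf("nu[%d,%d]", seq_len(n_s), i), drop = FALSE]
    })
    cum <- vector("list", 4L)
    cum[[1L]] <- nu[[1L]]
    for (i in 2:4) cum[[i]] <- cum[[i - 1L]] + nu[[i]]
    for (t in seq_len(n)) {
      s <- d$sub_index[t]
      svl <- (d$win_prob[t] - beta[, s] * d$ambiguity[t] / 2) *
        cum[[d$level[t]]][, s]
      ll[, t] <- bern_ll(y[t], gamma[, s] * (svl - cum[[1L]][, s]))
    }
  } else {
    gamma <- draws[, "gamma"]
    svl <- (d$win_prob - d$ambiguity / 2) * d$level
    for (t in seq_len(n)) {
      ll[, t] <- bern_ll(y[t], gamma * (svl[t] - 1))
    }
  }
  ll
}

#' Per-subject posterior summaries
#'
#' Posterior means and standard deviations of every subject-level parameter
#' of a fit: alpha/beta and gamma or delta for the utility models, beta,
#' gamma and the four additive value increments (nu1..nu4, level-to-level
#' gains) for the estimated-value model. The baseline model has no
#' subject-level parameters and yields an empty table.
#'
#' @param fit An \code{ordval_fit}.
#' @param parameters Optional character vector restricting the output
#'   (e.g. \code{"beta"}); requesting a parameter the model does not have
#'   is an error.
#' @return A data.frame with one row per subject and \code{<par>_mean} /
#'   \code{<par>_sd} columns.
#' @export
extract_subject_estimates <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "ordval_fit"))
  spec <- fit$spec
  fam <- switch(spec$sv_model,
    classic_utility = c(
      "alpha", "beta",
      if (spec$choice_rule == "logistic") "gamma" else "delta"
    ),
    estimated_value = c("beta", "gamma", "nu1", "nu2", "nu3", "nu4"),
    no_subjective_params = character(0)
  )
  if (!is.null(parameters)) {
    absent <- setdiff(parameters, fam)
    if (length(absent)) {
      stop(
        "parameter(s) not in this model: ", paste(absent, collapse = ", ")
      )
    }
    fam <- parameters
  }
  n_s <- length(fit$subjects)
  out <- data.frame(subject_id = fit$subjects)
  if (length(fam) == 0L) {
    return(out[0L, , drop = FALSE])
  }
  draws <- as.matrix(do.call(rbind, lapply(fit$mcmc, as.matrix)))
  for (p in fam) {
    cols <- if (grepl("^nu[1-4]$", p)) {
      sprintf("nu[%d,%s]", seq_len(n_s), sub("nu", "", p))
    } else {
      sprintf("%s[%d]", p, seq_len(n_s))
    }
    m <- draws[, cols, drop = FALSE]
    out[[paste0(p, "_mean")]] <- colMeans(m)
    out[[paste0(p, "_sd")]] <- apply(m, 2L, stats::sd)
  }
  out
}
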