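# Convergence diagnostics for multi-chain MCMC output: rank-normalized
# split R-hat and bulk effective sample size, following the modern
# (rank-normalization + folding-free bulk) definitions used by current
# Bayesian workflow tooling.

.split_chains <- function(draws) {
  # draws: iterations x chains matrix -> floor(n/2) x 2*chains
  n <- nrow(draws)
  half <- floor(n / 2)
  lower <- draws[seq_len(half), , drop = FALSE]
  upper <- draws[seq.int(n - half + 1L, n), , drop = FALSE]
  cbind(lower, upper)
}

.z_scale <- function(draws) {
  # rank-normalize jointly across all chains (fractional offset 3/8)
  r <- rank(draws, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(draws) + 1 / 4))
  matrix(z, nrow = nrow(draws), ncol = ncol(draws))
}

.rhat_basic <- function(draws) {
  n <- nrow(draws)
  chain_means <- colMeans(draws)
  chain_vars <- apply(draws, 2L, stats::var)
  w <- mean(chain_vars)
  b <- n * stats::var(chain_means)
  var_plus <- (n - 1) / n * w + b / n
  if (w == 0) {
    return(if (b == 0) 1 else Inf)
  }
  sqrt(var_plus / w)
}

.ess_basic <- function(draws) {
  # Geyer initial monotone positive sequence over chain-combined
  # autocorrelations
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4L) {
    return(NA_real_)
  }
  chain_vars <- apply(draws, 2L, stats::var)
  if (all(chain_vars == 0)) {
    return(NA_real_)
  }
  acov <- apply(draws, 2L, function(x) {
    # biased (divisor n) autocovariance, as the ESS estimator expects
    stats::acf(x, lag.max = n - 1L, plot = FALSE, type = "covariance",
      demean = TRUE)$acf[, 1, 1]
  })
  acov <- matrix(acov, nrow = n, ncol = m)
  mean_var <- mean(acov[1L, ]) * n / (n - 1)
  chain_means <- colMeans(draws)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + stats::var(chain_means)

  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus # rho[1] = lag 0
  rho[is.nan(rho)] <- 0
  # paired sums P_t = rho_{2t} + rho_{2t+1}
  max_t <- floor((n - 2) / 2)
  p <- numeric(0)
  t <- 0L
  while (t <= max_t) {
    s <- rho[2 * t + 1L] + if (2 * t + 2L <= n) rho[2 * t + 2L] else 0
    if (t > 0L && s < 0) break
    p <- c(p, max(s, 0))
    t <- t + 1L
  }
  # enforce monotone decrease
  if (length(p) > 1L) {
    for (i in 2:length(p)) p[i] <- min(p[i], p[i - 1L])
  }
  tau <- -1 + 2 * sum(p)
  tau <- max(tau, 1 / log10(n * m + 10)) # guard against antithetic chains
  ess <- n * m / tau
  min(ess, n * m * log10(n * m))
}

#' Split R-hat for one parameter
#'
#' Rank-normalized split R-hat: chains are split in half, draws are
#' rank-normalized jointly, and the classic between/within-chain variance
#' ratio is computed on the normalized splits. Values close to 1 indicate
#' convergence; the conventional threshold is 1.01.
#'
#' @param draws An iterations x chains numeric matrix (at least 2 chains).
#' @return Scalar R-hat.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("split R-hat requires at least 2 chains")
  if (nrow(draws) < 4L) stop("too few iterations per chain")
  .rhat_basic(.z_scale(.split_chains(draws)))
}

#' Bulk effective sample size for one parameter
#'
#' Effective sample size computed on rank-normalized split chains, using
#' chain-combined autocorrelations truncated by Geyer's initial monotone
#' positive sequence. Measures sampling efficiency in the bulk of the
#' posterior distribution.
#'
#' @param draws An iterations x chains numeric matrix.
#' @return Scalar ESS.
#' @export
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 4L) stop("too few iterations per chain")
  .ess_basic(.z_scale(.split_chains(draws)))
}

#' Convergence diagnostics for a fitted model
#'
#' Computes rank-normalized split R-hat and bulk ESS for every sampled
#' parameter of a fit and reports the worst cases.
#'
#' @param fit An \code{ordval_fit} object from [fit_model()], or a
#'   \code{coda::mcmc.list}.
#' @return A list with \code{max_rhat}, \code{min_ess},
#'   \code{n_divergences} (always 0 for the Gibbs/slice sampler, kept for
#'   interface stability) and \code{per_parameter} (data.frame with rhat
#'   and ess_bulk per parameter).
#' @export
diagnostics <- function(fit) {
  if (inherits(fit, "ordval_fit")) {
    mcl <- fit$mcmc
  } else if (inherits(fit, "mcmc.list")) {
    mcl <- fit
  } else {
    stop("'fit' must be an ordval_fit or an mcmc.list")
  }
  if (length(mcl) < 2L) stop("diagnostics require at least 2 chains")
  pars <- colnames(mcl[[1L]])
  per <- data.frame(
    parameter = pars,
    rhat = NA_real_,
    ess_bulk = NA_real_,
    row.names = NULL
  )
  for (j in seq_along(pars)) {
    m <- vapply(mcl, function(ch) as.numeric(ch[, j]), numeric(nrow(mcl[[1L]])))
    if (stats::sd(m) == 0) {
      # constant parameter (e.g. a degenerate corner); perfectly "converged"
      per$rhat[j] <- 1
      per$ess_bulk[j] <- NA_real_
      next
    }
    per$rhat[j] <- split_rhat(m)
    per$ess_bulk[j] <- ess_bulk(m)
  }
  list(
    max_rhat = max(per$rhat, na.rm = TRUE),
    min_ess = min(per$ess_bulk, na.rm = TRUE),
    n_divergences = 0L,
    per_parameter = per
  )
}
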