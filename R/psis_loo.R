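# Pareto-smoothed importance-sampling leave-one-out cross-validation.
# The estimator follows the standard PSIS-LOO recipe: per observation,
# importance ratios are the inverse likelihoods of the posterior draws; the
# largest 20% of log-ratios are replaced by expected order statistics of a
# generalized Pareto distribution fitted to the tail, then truncated at the
# raw maximum.

.log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

# Empirical-Bayes profile-likelihood fit of the generalized Pareto
# distribution to exceedances x > 0 (Zhang & Stephens 2009), with the
# weakly informative adjustment pulling khat toward 0.5 at small n.
.gpd_fit <- function(x, wip = TRUE) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  prior_k <- 10
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  ll <- n * (log(bs / ks) + ks - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(ll - ll[j])), numeric(1))
  b <- sum(bs * w)
  # tail index xi = -k_ZS; weakly informative prior pulls xi toward 0.5
  k <- mean(log1p(-b * x))
  sigma <- -k / b
  if (wip) k <- (k * n + prior_k * 0.5) / (n + prior_k)
  list(k = k, sigma = sigma)
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) {
    return(-sigma * log1p(-p))
  }
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance weights; returns the smoothed
# (unnormalized) log weights and the tail-shape estimate khat.
.psis_smooth <- function(lw) {
  s <- length(lw)
  lw <- lw - max(lw)
  tail_len <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  if (tail_len < 5L) {
    return(list(lw = lw, khat = Inf))
  }
  cutoff <- sort(lw, partial = s - tail_len)[s - tail_len]
  tail_idx <- which(lw > cutoff)
  if (length(tail_idx) < 5L) {
    # (near-)degenerate tail, e.g. constant weights: nothing to smooth
    return(list(lw = lw, khat = -Inf))
  }
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  fit <- .gpd_fit(exceed)
  if (!is.finite(fit$k)) {
    return(list(lw = lw, khat = fit$k))
  }
  n_tail <- length(tail_idx)
  pp <- (seq_len(n_tail) - 0.5) / n_tail
  smoothed <- log(exp(cutoff) + .qgpd(pp, fit$k, fit$sigma))
  lw[tail_idx[order(lw[tail_idx])]] <- smoothed
  lw <- pmin(lw, 0) # truncate at the raw maximum (lw was max-centered)
  list(lw = lw, khat = fit$k)
}

#' PSIS leave-one-out cross-validation from pointwise log-likelihoods
#'
#' Estimates the expected log pointwise predictive density (ELPD) of
#' leave-one-out cross-validation from a matrix of per-draw, per-trial
#' log-likelihoods, using Pareto-smoothed importance sampling. Higher ELPD
#' means better out-of-sample predictive fit; \code{p_loo} is the effective
#' number of parameters (the gap between in-sample log predictive density
#' and ELPD).
#'
#' @param log_lik A draws x trials matrix of pointwise log-likelihoods
#'   (finite, at least 100 draws).
#' @return An object of class \code{ordval_loo}: list with \code{elpd_loo},
#'   \code{p_loo}, \code{se} (standard error of elpd over trials),
#'   \code{pointwise} (per-trial elpd contributions), \code{pareto_k}
#'   (per-trial tail-shape diagnostics) and \code{n_trials}. A warning is
#'   attached (and emitted) when any pareto_k exceeds 0.7.
#' @examples
#' ll <- matrix(dnorm(rnorm(200), log = TRUE), nrow = 100)
#' psis_loo(ll)
#' @export
psis_loo <- function(log_lik) {
  log_lik <- as.matrix(log_lik)
  if (nrow(log_lik) < 100L) stop("need at least 100 posterior draws")
  if (any(!is.finite(log_lik))) stop("'log_lik' must be finite")
  s <- nrow(log_lik)
  n <- ncol(log_lik)
  pointwise <- numeric(n)
  khat <- numeric(n)
  lpd <- numeric(n)
  for (i in seq_len(n)) {
    ll <- log_lik[, i]
    sm <- .psis_smooth(-ll)
    lw <- sm$lw - .log_sum_exp(sm$lw)
    pointwise[i] <- .log_sum_exp(lw + ll)
    khat[i] <- sm$khat
    lpd[i] <- .log_sum_exp(ll) - log(s)
  }
  elpd <- sum(pointwise)
  res <- structure(
    list(
      elpd_loo = elpd,
      p_loo = sum(lpd - pointwise),
      se = sqrt(n) * stats::sd(pointwise),
      pointwise = pointwise,
      pareto_k = khat,
      n_trials = n,
      n_draws = s
    ),
    class = "ordval_loo"
  )
  bad <- sum(is.finite(khat) & khat > 0.7)
  if (bad > 0L) {
    res$warning <- sprintf(
      "%d of %d trials have Pareto k > 0.7; elpd may be unreliable", bad, n
    )
    warning(res$warning, call. = FALSE)
  }
  res
}

#' @export
print.ordval_loo <- function(x, ...) {
  cat("PSIS-LOO estimate (", x$n_trials, " trials, ", x$n_draws, " draws)\n",
    sep = ""
  )
  cat(sprintf("  elpd_loo %10.2f  (SE %.2f)\n", x$elpd_loo, x$se))
  cat(sprintf("  p_loo    %10.2f\n", x$p_loo))
  k <- x$pareto_k[is.finite(x$pareto_k)]
  cat(sprintf(
    "  Pareto k: %d good (<0.5), %d ok, %d bad (>0.7)\n",
    sum(k < 0.5), sum(k >= 0.5 & k <= 0.7), sum(k > 0.7)
  ))
  invisible(x)
}

# stacking weights: maximize sum_i log( sum_k w_k exp(elpd_ik) ) over the
# simplex, via a softmax reparameterization
.stacking_weights <- function(pointwise) {
  k <- ncol(pointwise)
  if (k == 1L) {
    return(1)
  }
  # work with exp of centered pointwise elpd for stability
  center <- apply(pointwise, 1L, max)
  p <- exp(pointwise - center)
  obj <- function(theta) {
    w <- exp(c(theta, 0))
    w <- w / sum(w)
    -sum(log(p %*% w))
  }
  opt <- stats::optim(rep(0, k - 1L), obj,
    method = "BFGS",
    control = list(maxit = 500)
  )
  w <- exp(c(opt$par, 0))
  w / sum(w)
}

#' Compare fitted models by PSIS-LOO
#'
#' Ranks models by ELPD (rank 0 = best), reports the ELPD difference to the
#' best model (\code{d_loo}) with its standard error, and stacking weights
#' (the convex combination of models maximizing the pointwise LOO
#' predictive density).
#'
#' @param results A named list of \code{ordval_loo} objects (>= 2), all
#'   computed on the same trials.
#' @return An object of class \code{ordval_comparison}: data.frame with
#'   columns \code{model}, \code{rank}, \code{elpd_loo}, \code{p_loo},
#'   \code{d_loo}, \code{d_se}, \code{weight}, \code{se}, ordered by rank.
#' @examples
#' ll1 <- matrix(dnorm(rnorm(400), log = TRUE), nrow = 200)
#' ll2 <- ll1 - 0.1
#' compare_models(list(a = psis_loo(ll1), b = psis_loo(ll2)))
#' @export
compare_models <- function(results) {
  if (!is.list(results) || length(results) < 2L) {
    stop("'results' must be a named list of at least 2 ordval_loo objects")
  }
  if (is.null(names(results)) || any(names(results) == "")) {
    stop("'results' must be named")
  }
  if (!all(vapply(results, inherits, logical(1), "ordval_loo"))) {
    stop("all elements must be ordval_loo objects")
  }
  n_trials <- vapply(results, function(r) r$n_trials, numeric(1))
  if (length(unique(n_trials)) != 1L) {
    stop("all models must be evaluated on the same trials (trial counts differ)")
  }
  nm <- names(results)
  elpd <- vapply(results, function(r) r$elpd_loo, numeric(1))
  # stable tie-break: order by elpd descending, then model name
  ord <- order(-elpd, nm)
  pointwise <- vapply(results, function(r) r$pointwise,
    numeric(n_trials[[1L]])
  )
  best <- ord[1L]
  d_se <- vapply(seq_along(results), function(k) {
    if (k == best) {
      return(0)
    }
    d <- pointwise[, best] - pointwise[, k]
    sqrt(length(d)) * stats::sd(d)
  }, numeric(1))
  tab <- data.frame(
    model = nm,
    rank = order(ord) - 1L,
    elpd_loo = elpd,
    p_loo = vapply(results, function(r) r$p_loo, numeric(1)),
    d_loo = elpd[best] - elpd,
    d_se = d_se,
    weight = .stacking_weights(pointwise),
    se = vapply(results, function(r) r$se, numeric(1)),
    row.names = NULL
  )
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("ordval_comparison", "data.frame")
  tab
}

#' @export
print.ordval_comparison <- function(x, ...) {
  cat("Model comparison by PSIS-LOO (rank 0 = best):\n")
  y <- as.data.frame(x)
  y$elpd_loo <- round(y$elpd_loo, 2)
  y$p_loo <- round(y$p_loo, 2)
  y$d_loo <- round(y$d_loo, 2)
  y$d_se <- round(y$d_se, 2)
  y$weight <- round(y$weight, 3)
  y$se <- round(y$se, 2)
  print(y, row.names = FALSE)
  invisible(x)
}
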