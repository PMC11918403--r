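#' Subjective value under the classic power-utility model
#'
#' Computes the subjective value of an uncertain prospect as
#' \deqn{SV = (P - \beta A / 2) \, V^{\alpha}}
#' where \eqn{P} is the objective winning probability, \eqn{A} the ambiguity
#' level (the occluded fraction of the probability display; ambiguous
#' prospects carry \eqn{P = 0.5}), \eqn{V} the outcome amount, \eqn{\alpha}
#' the risk attitude (utility curvature; \eqn{\alpha < 1} is risk averse) and
#' \eqn{\beta} the ambiguity attitude (\eqn{\beta > 0} is ambiguity averse).
#' The certain option is \code{sv_classic(1, 0, v, alpha, beta) = v^alpha}.
#'
#' All arguments are vectorized and recycled.
#'
#' @param p Winning probability, in (0, 1].
#' @param a Ambiguity level, in \[0, 1\]; 0 for risky and certain options.
#' @param v Outcome amount, positive.
#' @param alpha Risk attitude, positive.
#' @param beta Ambiguity attitude.
#' @return Numeric vector of subjective values.
#' @seealso [sv_estimated()], [sv_fixed()], [choice_prob_logistic()]
#' @examples
#' sv_classic(0.5, 0, 25, alpha = 1, beta = 0)   # expected value 12.5
#' sv_classic(1, 0, 5, alpha = 0.8, beta = 0.65) # certain $5
#' @export
sv_classic <- function(p, a, v, alpha, beta) {
  stopifnot(is.numeric(p), is.numeric(a), is.numeric(v))
  if (any(p <= 0 | p > 1)) stop("'p' must lie in (0, 1]")
  if (any(a < 0 | a > 1)) stop("'a' must lie in [0, 1]")
  if (any(v <= 0)) stop("'v' must be positive")
  (p - beta * a / 2) * v^alpha
}

#' Subjective value under the estimated-value model for ordinal outcomes
#'
#' For ordinal outcome levels \eqn{i = 1, \dots, 4}, the subjective value of
#' level \eqn{i} is the cumulative sum of nonnegative increments
#' \eqn{\nu_1, \dots, \nu_i}: each increment is the added value of moving up
#' one level, so values are nondecreasing in level by construction. The
#' prospect value is
#' \deqn{SV = (P - \beta A / 2) \sum_{j=1}^{i} \nu_j .}
#' There is no separate risk-attitude parameter: utility curvature is
#' absorbed by the increments.
#'
#' @param p,a Probability and ambiguity, as in [sv_classic()].
#' @param level Integer ordinal outcome level in 1..4.
#' @param nu Numeric vector of 4 nonnegative increments, or a matrix with 4
#'   columns (one row per element of \code{level}).
#' @param beta Ambiguity attitude.
#' @return Numeric vector of subjective values.
#' @examples
#' sv_estimated(1, 0, 3, nu = c(7.22, 4.13, 6.23, 8.77), beta = 0) # 17.58
#' @export
sv_estimated <- function(p, a, level, nu, beta) {
  if (any(p <= 0 | p > 1)) stop("'p' must lie in (0, 1]")
  if (any(a < 0 | a > 1)) stop("'a' must lie in [0, 1]")
  if (any(!(level %in% 1:4))) stop("'level' must be an integer in 1..4")
  if (is.matrix(nu)) {
    if (ncol(nu) != 4L) stop("'nu' matrix must have 4 columns")
    if (any(nu < 0)) stop("all 'nu' increments must be nonnegative")
    cum <- t(apply(nu, 1L, cumsum))
    val <- cum[cbind(seq_len(nrow(cum)), level)]
  } else {
    if (length(nu) != 4L) stop("'nu' must have 4 increments")
    if (any(nu < 0)) stop("all 'nu' increments must be nonnegative")
    val <- cumsum(nu)[level]
  }
  (p - beta * a / 2) * val
}

#' Subjective value with no subject-specific parameters (baseline)
#'
#' Baseline ("straw man") valuation: the ordinal category index itself is the
#' value and ambiguity is penalized at a fixed unit rate,
#' \deqn{SV = (P - A/2) \, i .}
#'
#' @param p,a Probability and ambiguity, as in [sv_classic()].
#' @param level Integer ordinal outcome level in 1..4.
#' @return Numeric vector of subjective values.
#' @export
sv_fixed <- function(p, a, level) {
  if (any(p <= 0 | p > 1)) stop("'p' must lie in (0, 1]")
  if (any(a < 0 | a > 1)) stop("'a' must lie in [0, 1]")
  if (any(!(level %in% 1:4))) stop("'level' must be an integer in 1..4")
  (p - a / 2) * level
}

#' Logistic (softmax) choice rule
#'
#' Probability of choosing the lottery given the subjective values of the
#' certain option and the lottery:
#' \deqn{P(\mathrm{lottery}) = \frac{1}{1 + \exp\{\gamma (SV_{safe} - SV_{lottery})\}}}
#' with inverse temperature \eqn{\gamma > 0}. Numerically stable for large
#' value differences (uses \code{plogis}).
#'
#' @param sv_safe Subjective value of the certain option.
#' @param sv_risky Subjective value of the lottery.
#' @param gamma Inverse temperature, positive.
#' @return Choice probability in (0, 1).
#' @export
choice_prob_logistic <- function(sv_safe, sv_risky, gamma) {
  if (any(gamma <= 0)) stop("'gamma' must be positive")
  stats::plogis(gamma * (sv_risky - sv_safe))
}

#' Trembling-hand choice rule
#'
#' A lapse-augmented logistic rule: with probability \eqn{\delta} the chooser
#' responds at random (50/50), otherwise follows a unit-temperature logistic
#' comparison of subjective values:
#' \deqn{P(\mathrm{lottery}) = (1-\delta)\,\mathrm{logistic}(SV_{lottery} - SV_{safe}) + \delta/2 .}
#' Probabilities are bounded in \eqn{[\delta/2, 1 - \delta/2]}, which
#' decouples the asymptotes of the choice function from the value parameters.
#'
#' @param sv_safe,sv_risky Subjective values of the two options.
#' @param delta Lapse rate in \[0, 1\].
#' @return Choice probability.
#' @export
choice_prob_trembling <- function(sv_safe, sv_risky, delta) {
  if (any(delta < 0 | delta > 1)) stop("'delta' must lie in [0, 1]")
  (1 - delta) * stats::plogis(sv_risky - sv_safe) + delta / 2
}

#' Hyperprior settings for the hierarchical models
#'
#' Returns the group-level prior specification shared by all fitting
#' functions, with the package defaults chosen to encode slight risk and
#' ambiguity aversion:
#' \itemize{
#'   \item risk attitude: \eqn{\alpha \sim 2\,\mathrm{Beta}(\alpha_1,\alpha_2)}
#'     with \eqn{\alpha_1 \sim N(4,1)} and \eqn{\alpha_2 \sim N(7,3)}, both
#'     truncated at 0 (support of \eqn{\alpha} is (0, 2));
#'   \item ambiguity attitude: \eqn{\beta \sim N(\mu_\beta, \sigma_\beta)}
#'     truncated to \[-1.5, 1.5\], \eqn{\mu_\beta \sim N(0.65, 1)},
#'     \eqn{\sigma_\beta \sim \mathrm{Gamma}(2, 1)};
#'   \item inverse temperature: \eqn{\gamma \sim \mathrm{LogNormal}(0, 0.25)};
#'   \item lapse rate: \eqn{\delta \sim \mathrm{Beta}(\delta_1, \delta_2)},
#'     \eqn{\delta_{1,2} \sim N(2, 1)} truncated at 1;
#'   \item ordinal value increments: \eqn{\nu_i \sim N(\mu_{\nu_i},
#'     \sigma_{\nu_i})} truncated at 0, \eqn{\mu_{\nu_i} \sim N(4, 2)}
#'     truncated at 0, \eqn{\sigma_{\nu_i} \sim \mathrm{Gamma}(3, 1)}.
#' }
#' All normal scale arguments are standard deviations; Gamma arguments are
#' (shape, rate).
#'
#' @param ... Named overrides of any default component.
#' @return An object of class \code{ordval_hyperpriors} (a named list).
#' @examples
#' hp <- hyperprior_settings()
#' prior_mean_alpha(hp)
#' @export
hyperprior_settings <- function(...) {
  hp <- list(
    alpha_shape1_loc = 4, alpha_shape1_scale = 1,
    alpha_shape2_loc = 7, alpha_shape2_scale = 3,
    beta_mean_loc = 0.65, beta_mean_scale = 1,
    beta_sd_shape = 2, beta_sd_rate = 1,
    beta_lower = -1.5, beta_upper = 1.5,
    gamma_log_loc = 0, gamma_log_scale = 0.25,
    delta_shape1_loc = 2, delta_shape1_scale = 1,
    delta_shape2_loc = 2, delta_shape2_scale = 1,
    nu_mean_loc = 4, nu_mean_scale = 2,
    nu_sd_shape = 3, nu_sd_rate = 1
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(hp))
    if (length(unknown)) {
      stop("unknown hyperprior component(s): ", paste(unknown, collapse = ", "))
    }
    hp[names(dots)] <- dots
  }
  scales <- hp[grepl("_(scale|sd_shape|sd_rate)$", names(hp))]
  if (any(unlist(scales) <= 0)) stop("all scale/shape/rate components must be positive")
  if (hp$beta_lower != -hp$beta_upper) {
    stop("beta truncation bounds must be symmetric about 0")
  }
  structure(hp, class = "ordval_hyperpriors")
}

#' @export
print.ordval_hyperpriors <- function(x, ...) {
  cat("Hyperprior settings:\n")
  cat(sprintf(
    "  alpha  ~ 2*Beta(a1, a2); a1 ~ N(%g, %g)T[0,), a2 ~ N(%g, %g)T[0,)\n",
    x$alpha_shape1_loc, x$alpha_shape1_scale, x$alpha_shape2_loc, x$alpha_shape2_scale
  ))
  cat(sprintf(
    "  beta   ~ N(mu_b, sd_b)T[%g, %g]; mu_b ~ N(%g, %g), sd_b ~ Gamma(%g, %g)\n",
    x$beta_lower, x$beta_upper, x$beta_mean_loc, x$beta_mean_scale,
    x$beta_sd_shape, x$beta_sd_rate
  ))
  cat(sprintf("  gamma  ~ LogNormal(%g, %g)\n", x$gamma_log_loc, x$gamma_log_scale))
  cat(sprintf(
    "  delta  ~ Beta(d1, d2); d1, d2 ~ N(%g, %g)T[1,)\n",
    x$delta_shape1_loc, x$delta_shape1_scale
  ))
  cat(sprintf(
    "  nu_i   ~ N(mu_nu_i, sd_nu_i)T[0,); mu_nu ~ N(%g, %g)T[0,), sd_nu ~ Gamma(%g, %g)\n",
    x$nu_mean_loc, x$nu_mean_scale, x$nu_sd_shape, x$nu_sd_rate
  ))
  invisible(x)
}

#' Plug-in prior mean of the risk attitude
#'
#' The risk-attitude prior is \eqn{\alpha \sim 2\,\mathrm{Beta}(a, b)} with
#' hyperprior location values \eqn{a, b}. Plugging the locations into the
#' Beta mean gives the central prior mean \eqn{2a/(a+b)}; with the default
#' locations (4, 7) this is \eqn{8/11 \approx 0.73}, i.e. slight risk
#' aversion.
#'
#' @param settings An [hyperprior_settings()] object.
#' @return Scalar prior mean of alpha.
#' @export
prior_mean_alpha <- function(settings = hyperprior_settings()) {
  stopifnot(inherits(settings, "ordval_hyperpriors"))
  a <- settings$alpha_shape1_loc
  b <- settings$alpha_shape2_loc
  2 * a / (a + b)
}

#' Read or write hyperprior settings as YAML
#'
#' @param path File path.
#' @param settings An [hyperprior_settings()] object.
#' @return \code{read_hyperpriors} returns an \code{ordval_hyperpriors}
#'   object; \code{write_hyperpriors} returns \code{path} invisibly.
#' @export
read_hyperpriors <- function(path) {
  do.call(hyperprior_settings, yaml::read_yaml(path))
}

#' @rdname read_hyperpriors
#' @export
write_hyperpriors <- function(settings, path) {
  stopifnot(inherits(settings, "ordval_hyperpriors"))
  yaml::write_yaml(unclass(settings), path)
  invisible(path)
}
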