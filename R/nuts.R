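# No-U-Turn sampler with dual-averaging step-size adaptation and a
# diagonal mass matrix estimated during warmup. The target is supplied as
# a function(theta) -> list(lp, grad) on the unconstrained scale.

.nuts_chain <- function(lp_grad, init, n_warmup, n_draws,
                        target_accept = 0.8, seed = 1L,
                        max_treedepth = 10L) {
  set.seed(as.integer(seed))
  d <- length(init)
  invm <- rep(1, d) # inverse metric (posterior variance estimate)
  theta <- init
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at the initial value")

  minv_mult <- function(p) invm * p
  draw_momentum <- function() stats::rnorm(d) / sqrt(invm)
  kin <- function(p) 0.5 * sum(p^2 * invm)

  leapfrog <- function(theta, p, grad, eps) {
    p <- p + 0.5 * eps * grad
    theta <- theta + eps * minv_mult(p)
    lg <- lp_grad(theta)
    if (!is.finite(lg$lp) || any(!is.finite(lg$grad))) {
      lg$lp <- -Inf
      lg$grad <- rep(0, d)
    }
    p <- p + 0.5 * eps * lg$grad
    list(theta = theta, p = p, lp = lg$lp, grad = lg$grad)
  }

  find_eps <- function(theta, cur) {
    eps <- 1
    p0 <- draw_momentum()
    h0 <- cur$lp - kin(p0)
    st <- leapfrog(theta, p0, cur$grad, eps)
    h1 <- st$lp - kin(st$p)
    if (!is.finite(h1)) {
      while (!is.finite(h1) && eps > 1e-10) {
        eps <- eps / 2
        st <- leapfrog(theta, p0, cur$grad, eps)
        h1 <- st$lp - kin(st$p)
      }
    }
    a <- if (h1 - h0 > log(0.5)) 1 else -1
    while (a * (st$lp - kin(st$p) - h0) > -a * log(2) && eps < 1e3 &&
      eps > 1e-10) {
      eps <- eps * 2^a
      st <- leapfrog(theta, p0, cur$grad, eps)
      if (!is.finite(st$lp)) break
    }
    max(eps, 1e-8)
  }

  log_add <- function(a, b) {
    if (a == -Inf && b == -Inf) {
      return(-Inf)
    }
    m <- max(a, b)
    m + log(exp(a - m) + exp(b - m))
  }

  # recursive tree building, multinomial variant: trajectory states are
  # weighted by exp(H - H0); subtree proposals merge in proportion to
  # their total weights
  build <- function(theta, p, grad, v, j, eps, h0) {
    if (j == 0L) {
      st <- leapfrog(theta, p, grad, v * eps)
      h <- st$lp - kin(st$p)
      div <- !is.finite(h) || (h0 - h) > 1000
      list(
        tm = st$theta, pm = st$p, gm = st$grad,
        tp = st$theta, pp = st$p, gp = st$grad,
        prop = st, lw = if (div) -Inf else h - h0,
        s = as.integer(!div),
        a = if (div) 0 else min(1, exp(h - h0)), na = 1L, div = div
      )
    } else {
      t1 <- build(theta, p, grad, v, j - 1L, eps, h0)
      if (t1$s == 1L) {
        if (v == -1) {
          t2 <- build(t1$tm, t1$pm, t1$gm, v, j - 1L, eps, h0)
          t1$tm <- t2$tm
          t1$pm <- t2$pm
          t1$gm <- t2$gm
        } else {
          t2 <- build(t1$tp, t1$pp, t1$gp, v, j - 1L, eps, h0)
          t1$tp <- t2$tp
          t1$pp <- t2$pp
          t1$gp <- t2$gp
        }
        lw_comb <- log_add(t1$lw, t2$lw)
        if (is.finite(t2$lw) &&
          stats::runif(1) < exp(t2$lw - lw_comb)) {
          t1$prop <- t2$prop
        }
        dt <- t1$tp - t1$tm
        t1$s <- t2$s *
          as.integer(sum(dt * minv_mult(t1$pm)) >= 0) *
          as.integer(sum(dt * minv_mult(t1$pp)) >= 0)
        t1$lw <- lw_comb
        t1$a <- t1$a + t2$a
        t1$na <- t1$na + t2$na
        t1$div <- t1$div || t2$div
      }
      t1
    }
  }

  # dual-averaging state
  eps <- find_eps(theta, cur)
  mu <- log(10 * eps)
  log_eps_bar <- 0
  h_bar <- 0
  gamma0 <- 0.05
  t0 <- 10
  kappa <- 0.75
  m_adapt <- 0L

  # expanding mass-adaptation windows between an initial and a terminal
  # step-size-only buffer (25, 50, 100, ... iterations, doubling)
  init_buf <- min(75L, floor(0.15 * n_warmup))
  term_buf <- min(50L, floor(0.1 * n_warmup))
  win_ends <- integer(0)
  pos <- init_buf
  w <- 25L
  while (pos + w < n_warmup - term_buf) {
    pos <- pos + w
    win_ends <- c(win_ends, pos)
    w <- w * 2L
  }
  if (length(win_ends) == 0L && n_warmup > init_buf + term_buf + 10L) {
    win_ends <- n_warmup - term_buf
  } else if (length(win_ends) > 0L) {
    win_ends[length(win_ends)] <- n_warmup - term_buf
  }
  win_start <- init_buf + 1L
  acc <- matrix(NA_real_, n_warmup, d) # warmup draws for windowed variance

  draws <- matrix(NA_real_, n_draws, d)
  n_div <- 0L
  accept_sum <- 0
  depth_sum <- 0L

  total <- n_warmup + n_draws
  for (it in seq_len(total)) {
    warm <- it <= n_warmup
    p0 <- draw_momentum()
    h0 <- cur$lp - kin(p0)
    tm <- theta
    tp <- theta
    pm <- p0
    pp <- p0
    gm <- cur$grad
    gp <- cur$grad
    prop <- NULL
    lw_tot <- 0 # weight of the initial state
    s <- 1L
    j <- 0L
    a_stat <- 0
    na_stat <- 0L
    div_it <- FALSE
    while (s == 1L && j < max_treedepth) {
      v <- sample(c(-1, 1), 1L)
      if (v == -1) {
        tr <- build(tm, pm, gm, v, j, eps, h0)
        tm <- tr$tm
        pm <- tr$pm
        gm <- tr$gm
      } else {
        tr <- build(tp, pp, gp, v, j, eps, h0)
        tp <- tr$tp
        pp <- tr$pp
        gp <- tr$gp
      }
      # biased progressive sampling favors the newly built half
      if (tr$s == 1L && is.finite(tr$lw) &&
        stats::runif(1) < min(1, exp(tr$lw - lw_tot))) {
        prop <- tr$prop
      }
      lw_tot <- log_add(lw_tot, tr$lw)
      dt <- tp - tm
      s <- tr$s *
        as.integer(sum(dt * minv_mult(pm)) >= 0) *
        as.integer(sum(dt * minv_mult(pp)) >= 0)
      a_stat <- a_stat + tr$a
      na_stat <- na_stat + tr$na
      div_it <- div_it || tr$div
      j <- j + 1L
    }
    if (!is.null(prop)) {
      theta <- prop$theta
      cur <- list(lp = prop$lp, grad = prop$grad)
    }
    accept_frac <- if (na_stat == 0L) 0 else a_stat / na_stat

    if (warm) {
      m_adapt <- m_adapt + 1L
      h_bar <- (1 - 1 / (m_adapt + t0)) * h_bar +
        (target_accept - accept_frac) / (m_adapt + t0)
      log_eps <- mu - sqrt(m_adapt) / gamma0 * h_bar
      eps <- exp(log_eps)
      w <- m_adapt^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      acc[it, ] <- theta
      if (it %in% win_ends) {
        rows <- win_start:it
        nw <- length(rows)
        v_est <- apply(acc[rows, , drop = FALSE], 2L, stats::var)
        invm <- v_est * nw / (nw + 5) + 1e-3 * (5 / (nw + 5))
        # restart step-size adaptation around the current adapted step
        mu <- log(10 * eps)
        h_bar <- 0
        log_eps_bar <- log(eps)
        m_adapt <- 0L
        win_start <- it + 1L
      }
    } else {
      if (it == n_warmup + 1L) eps <- exp(log_eps_bar)
      draws[it - n_warmup, ] <- theta
      if (div_it) n_div <- n_div + 1L
      accept_sum <- accept_sum + accept_frac
      depth_sum <- depth_sum + j
    }
  }
  list(
    draws = draws,
    eps = eps,
    invm = invm,
    n_divergences = n_div,
    accept_rate = accept_sum / n_draws,
    mean_treedepth = depth_sum / n_draws
  )
}

# multi-chain front end; returns list of unconstrained draw matrices
.nuts_sample <- function(lp_grad, inits, n_warmup, n_draws,
                         target_accept = 0.8, seed = 1L,
                         max_treedepth = 10L) {
  lapply(seq_along(inits), function(ch) {
    .nuts_chain(lp_grad, inits[[ch]], n_warmup, n_draws,
      target_accept = target_accept,
      seed = as.integer(seed) * 1000L + ch,
      max_treedepth = max_treedepth
    )
  })
}
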