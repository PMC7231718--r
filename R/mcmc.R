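# Component-wise adaptive random-walk Metropolis.
#
# `logpost` takes the full parameter vector and returns the (unnormalized)
# log posterior, -Inf outside the support.  Step sizes are adapted toward
# `target_accept` every `adapt_interval` iterations, during burn-in ONLY,
# so the post-burn-in chain is a valid fixed-kernel Metropolis sampler.
rwm_chain <- function(logpost, init, n_iter, burn_in, thin = 1L,
                      step = NULL, adapt_interval = 50L,
                      target_accept = 0.3, param_names = names(init)) {
  p <- length(init)
  if (is.null(step)) step <- rep(0.1, p)
  step <- rep_len(step, p)
  if (burn_in >= n_iter) stop("'burn_in' must be < 'n_iter'", call. = FALSE)
  if (thin < 1L) stop("'thin' must be >= 1", call. = FALSE)
  cur <- init
  lp <- logpost(cur)
  if (!is.finite(lp))
    stop("log posterior is not finite at the initial values", call. = FALSE)
  n_keep <- floor((n_iter - burn_in) / thin)
  draws <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, param_names))
  acc_win <- integer(p)
  acc_post <- integer(p)
  kept <- 0L
  stalled <- FALSE
  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      prop <- cur
      prop[j] <- cur[j] + step[j] * stats::rnorm(1L)
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) && log(stats::runif(1L)) < lp_prop - lp) {
        cur <- prop
        lp <- lp_prop
        acc_win[j] <- acc_win[j] + 1L
        if (it > burn_in) acc_post[j] <- acc_post[j] + 1L
      }
    }
    if (it <= burn_in && it %% adapt_interval == 0L) {
      rate <- acc_win / adapt_interval
      if (!stalled && any(rate == 0)) {
        warning(sprintf(
          "no proposals accepted in an adaptation window for component(s) %s; steps: %s",
          paste(which(rate == 0), collapse = ","),
          paste(signif(step[rate == 0], 3), collapse = ",")), call. = FALSE)
        stalled <- TRUE
      }
      step <- step * exp(rate - target_accept)
      acc_win <- integer(p)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- cur
    }
  }
  list(draws = draws, accept = acc_post / (n_iter - burn_in), step = step)
}

# half-normal log prior density at natural value x > 0
halfnorm_lp <- function(x, sd) stats::dnorm(x, 0, sd, log = TRUE) + log(2)

# the same prior seen from the log-scale parameterization lx = log(x):
# half-normal density at exp(lx) times the Jacobian exp(lx); integrates to
# one over the real line
lp_pos <- function(lx, sd) halfnorm_lp(exp(lx), sd) + lx

# Specialized sampler for the promotion-time cure model.  Identical target
# to rwm_chain over cure_loglik + priors, but exploits the model structure:
# a coefficient proposal only shifts the linear predictor by one column,
# and the latent GBS pieces are cached between coefficient updates.
# Positive parameters (alpha, beta_scale, nu) are sampled on the log scale
# with the Jacobian folded into the prior term.
mcmc_cure <- function(time, event, x, prior, control) {
  p <- ncol(x)
  n_iter <- control$n_iter
  burn_in <- control$burn_in
  thin <- control$thin
  adapt_interval <- control$adapt_interval
  target <- control$target_accept
  d <- event == 1

  scale_sd <- prior$scale_sd
  if (is.null(scale_sd)) scale_sd <- 2 * stats::median(time)

  init <- control$init
  if (identical(init, "default")) {
    ev_rate <- max(mean(event), 1 / length(event))
    b0 <- stats::qlogis(min(1 - ev_rate, 0.99))
    beta <- c(b0, rep(0, p - 1L))
    med_ev <- if (any(d)) stats::median(time[d]) else stats::median(time)
    lgbs <- log(c(alpha = 1, beta_scale = med_ev, nu = 0.5))
  } else {
    beta <- init$beta
    lgbs <- log(c(init$alpha, init$beta_scale, init$nu))
  }

  logt <- log(time)
  ev0 <- which(d) - 1L                 # 0-based event indices for C++
  gbs_pieces <- function(lgbs)
    .gbs_pieces_cpp(logt, ev0, exp(lgbs[1L]), exp(lgbs[2L]), exp(lgbs[3L]))
  loglik <- function(eta, gp) .cure_parts_cpp(eta, gp$S, gp$lf_ev, ev0)

  eta <- drop(x %*% beta)
  gp <- gbs_pieces(lgbs)
  ll <- loglik(eta, gp)
  if (!is.finite(ll))
    stop("log likelihood not finite at the initial values", call. = FALSE)

  step <- rep_len(control$step_init, p + 3L)
  n_keep <- floor((n_iter - burn_in) / thin)
  nm <- c(colnames(x), "alpha", "beta_scale", "nu")
  draws <- matrix(NA_real_, n_keep, p + 3L, dimnames = list(NULL, nm))
  acc_win <- integer(p + 3L)
  acc_post <- integer(p + 3L)
  kept <- 0L
  stalled <- FALSE

  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      delta <- step[j] * stats::rnorm(1L)
      bj_new <- beta[j] + delta
      eta_new <- eta + x[, j] * delta
      ll_new <- loglik(eta_new, gp)
      lr <- ll_new - ll +
        stats::dnorm(bj_new, 0, prior$beta_sd, log = TRUE) -
        stats::dnorm(beta[j], 0, prior$beta_sd, log = TRUE)
      if (is.finite(ll_new) && log(stats::runif(1L)) < lr) {
        beta[j] <- bj_new
        eta <- eta_new
        ll <- ll_new
        acc_win[j] <- acc_win[j] + 1L
        if (it > burn_in) acc_post[j] <- acc_post[j] + 1L
      }
    }
    sds <- c(prior$alpha_sd, scale_sd, prior$nu_sd)
    for (k in 1:3) {
      jj <- p + k
      lg_new <- lgbs
      lg_new[k] <- lgbs[k] + step[jj] * stats::rnorm(1L)
      gp_new <- gbs_pieces(lg_new)
      ll_new <- loglik(eta, gp_new)
      lr <- ll_new - ll + lp_pos(lg_new[k], sds[k]) - lp_pos(lgbs[k], sds[k])
      if (is.finite(ll_new) && log(stats::runif(1L)) < lr) {
        lgbs <- lg_new
        gp <- gp_new
        ll <- ll_new
        acc_win[jj] <- acc_win[jj] + 1L
        if (it > burn_in) acc_post[jj] <- acc_post[jj] + 1L
      }
    }
    if (it <= burn_in && it %% adapt_interval == 0L) {
      rate <- acc_win / adapt_interval
      if (!stalled && any(rate == 0)) {
        warning(sprintf(
          "no accepted proposals in an adaptation window for %s",
          paste(nm[rate == 0], collapse = ", ")), call. = FALSE)
        stalled <- TRUE
      }
      step <- step * exp(rate - target)
      acc_win <- integer(p + 3L)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(beta, exp(lgbs))
    }
  }
  list(draws = draws, accept = stats::setNames(acc_post / (n_iter - burn_in), nm),
       step = step, scale_sd = scale_sd)
}

# effective sample size from the autocorrelation function, truncated at the
# first non-positive lag (advisory diagnostic)
ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  cut <- which(rho <= 0)
  if (length(cut)) rho <- rho[seq_len(cut[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

# Geweke convergence z score: first 10% vs last 50% of the chain, with
# batch-mean standard errors
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  x1 <- x[seq_len(max(2L, floor(frac1 * n)))]
  x2 <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  bse <- function(v) {
    nb <- max(2L, floor(sqrt(length(v))))
    bm <- tapply(v, cut(seq_along(v), nb), mean)
    stats::sd(bm) / sqrt(nb)
  }
  (mean(x1) - mean(x2)) / sqrt(bse(x1)^2 + bse(x2)^2)
}
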