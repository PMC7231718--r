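# Independent oracles, deliberately coded apart from the package internals.

# classical two-parameter Birnbaum-Saunders law, standard textbook formulas
bs_cdf <- function(t, a, b) pnorm((sqrt(t / b) - sqrt(b / t)) / a)
bs_pdf <- function(t, a, b) {
  xi <- (sqrt(t / b) - sqrt(b / t)) / a
  dxi <- (sqrt(t / b) + sqrt(b / t)) / (2 * a * t)
  dnorm(xi) * dxi
}

# population survival of the promotion-time model by brute-force truncation
# of the geometric series sum_m theta (1-theta)^m S^m
geom_series_sp <- function(theta, S, tol = 1e-15) {
  total <- 0
  term <- theta
  m <- 0
  repeat {
    total <- total + term
    m <- m + 1
    term <- theta * (1 - theta)^m * S^m
    if (term < tol || m > 1e6) break
  }
  total
}

# product-limit estimator and Greenwood variance written from the defining
# formulas, looping over distinct times
km_oracle <- function(time, event) {
  ts <- sort(unique(time))
  surv <- numeric(length(ts))
  se <- numeric(length(ts))
  s <- 1
  gw <- 0
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    if (d_i > 0) {
      s <- s * (1 - d_i / n_i)
      if (n_i > d_i) gw <- gw + d_i / (n_i * (n_i - d_i))
    }
    surv[i] <- s
    se[i] <- s * sqrt(gw)
  }
  list(time = ts, surv = surv, se = se)
}

# step-function lookup on an oracle curve
km_oracle_at <- function(or, t) {
  idx <- findInterval(t, or$time)
  c(1, or$surv)[idx + 1L]
}

# exhaustive minimal-window HPD: check every window of ceiling(prob*n)
# sorted draws
hpd_oracle <- function(x, prob = 0.95) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(prob * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1L)) {
    lo <- s[i]
    hi <- s[i + m - 1L]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# small random censored cohorts with ties, for KM cross-checks
random_cohort <- function(n = 40) {
  data.frame(time = ceiling(rexp(n, 0.25) * 4) / 4,
             event = rbinom(n, 1, 0.6))
}

# compact synthetic fit for method tests (shared across files via lazy eval)
small_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      co <- generate_cohort(cohort_config(n = 400), seed = 11)
      fit <<- gbscure(
        survival::Surv(time, event) ~ lvi + tumor_size, data = co,
        control = gbscure_control(n_iter = 1500, burn_in = 500, thin = 2,
                                  seed = 3))
    }
    fit
  }
})
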