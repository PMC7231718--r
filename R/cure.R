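#' Cure fraction under the logit link
#'
#' Maps a design matrix and coefficient vector to per-subject cure
#' probabilities \eqn{\theta = \mathrm{logit}^{-1}(x'\beta)}.  Under this
#' link \eqn{e^{\beta_j}} is the cure odds ratio of covariate level `j`
#' against its reference level.
#'
#' @param x a numeric design matrix (or a single row as a vector) whose
#'   columns match `beta`, intercept included.
#' @param beta numeric coefficient vector on the cure log-odds scale.
#' @return numeric vector of cure probabilities in (0, 1).
#' @examples
#' cure_fraction(c(1, 0), c(0, 2))     # logistic(0) = 0.5
#' cure_fraction(c(1, 1), c(0, -1.139))
#' @export
cure_fraction <- function(x, beta) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(beta))
    stop("ncol(x) must equal length(beta)", call. = FALSE)
  stats::plogis(drop(x %*% beta))
}

#' Population survival and density of the promotion-time cure model
#'
#' In the non-mixture (promotion-time) construction each subject carries
#' \eqn{M} latent competing causes, \eqn{M \sim \mathrm{Geometric}(\theta)}
#' on \eqn{\{0, 1, 2, \dots\}} with \eqn{P(M = m) = \theta(1-\theta)^m}, and
#' each cause an independent GBS event time.  A subject with \eqn{M = 0} is
#' cured.  The population (improper) survival function is the probability
#' generating function of \eqn{M} evaluated at the latent survival
#' \eqn{S(t)}:
#' \deqn{S_p(t) = \frac{\theta}{1 - (1-\theta)S(t)},}
#' which decreases from 1 at \eqn{t = 0} to the cure fraction \eqn{\theta}
#' as \eqn{t \to \infty} (the survival plateau).  Its negative derivative is
#' \deqn{f_p(t) = \frac{\theta(1-\theta) f(t)}{[1 - (1-\theta)S(t)]^2},}
#' with \eqn{f} the GBS density.
#'
#' @param t vector of positive times.
#' @param theta cure fraction(s) in (0, 1]; recycled against `t`.
#' @param alpha,beta,nu GBS parameters of the latent event-time law (see
#'   [pgbs()]).
#' @param log logical; return the log survival/density.
#' @return numeric vector: `pop_survival` the population survival
#'   probability, `pop_density` the population (sub-)density.  The density
#'   integrates to \eqn{1 - \theta}, the susceptible mass.
#' @examples
#' pop_survival(2.5, theta = 0.5, alpha = 0.9, beta = 2.5)  # 0.5/(1-0.25)
#' @export
pop_survival <- function(t, theta, alpha, beta, nu = 0.5, log = FALSE) {
  if (any(!is.finite(theta) | theta <= 0 | theta > 1))
    stop("'theta' must lie in (0, 1]", call. = FALSE)
  S <- pgbs(t, alpha, beta, nu, lower.tail = FALSE)
  out <- log(theta) - log1p(-(1 - theta) * S)
  if (log) out else exp(out)
}

#' @rdname pop_survival
#' @export
pop_density <- function(t, theta, alpha, beta, nu = 0.5, log = FALSE) {
  if (any(!is.finite(theta) | theta <= 0 | theta > 1))
    stop("'theta' must lie in (0, 1]", call. = FALSE)
  S <- pgbs(t, alpha, beta, nu, lower.tail = FALSE)
  lf <- dgbs(t, alpha, beta, nu, log = TRUE)
  # theta == 1 gives log1p(-theta) = -Inf: no susceptibles, density zero
  out <- log(theta) + log1p(-theta) + lf - 2 * log1p(-(1 - theta) * S)
  if (log) out else exp(out)
}

#' Log likelihood of the promotion-time cure model
#'
#' Right-censored log likelihood
#' \eqn{\sum_i [\delta_i \log f_p(t_i) + (1-\delta_i) \log S_p(t_i)]}
#' with the population survival/density of [pop_survival()] and a logit
#' link on the cure fraction.  Everything is evaluated in the log domain;
#' out-of-support parameter values return `-Inf` rather than `NaN`.
#'
#' @param time positive follow-up times.
#' @param event event indicators (1 = event, 0 = right censored).
#' @param x design matrix, intercept included.
#' @param beta coefficients on the cure log-odds scale, `ncol(x)` long.
#' @param alpha,beta_scale,nu GBS parameters of the latent event-time law.
#' @return the log likelihood (a single number; `-Inf` if the parameters
#'   fall outside the support).
#' @export
cure_loglik <- function(time, event, x, beta, alpha, beta_scale, nu = 0.5) {
  if (any(!is.finite(time)) || any(time <= 0))
    stop("'time' must be finite and > 0", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("'event' must be 0/1", call. = FALSE)
  if (!all(is.finite(c(beta, alpha, beta_scale, nu))) ||
      alpha <= 0 || beta_scale <= 0 || nu <= 0) return(-Inf)
  eta <- drop(x %*% beta)
  S <- pgbs(time, alpha, beta_scale, nu, lower.tail = FALSE)
  lf <- dgbs(time, alpha, beta_scale, nu, log = TRUE)
  cure_loglik_parts(eta, S, lf, event)
}

# core likelihood given cached pieces; used by the sampler's fast path.
# eta = x beta, S = latent survival, lf = latent log density (only the
# event entries are ever used), event = 0/1 vector.
cure_loglik_parts <- function(eta, S, lf, event) {
  lth <- stats::plogis(eta, log.p = TRUE)       # log theta
  lmth <- stats::plogis(-eta, log.p = TRUE)     # log(1 - theta)
  th <- exp(lth)
  lA <- log1p(-(1 - th) * S)                    # log[1 - (1-theta) S]
  d <- event == 1
  ll <- sum(lth) - sum(lA) + sum(lmth[d] + lf[d] - lA[d])
  if (is.nan(ll)) -Inf else ll
}
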