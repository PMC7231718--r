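#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function with Greenwood standard
#' errors, computed via [survival::survfit()] and returned as a light
#' `"km_curve"` object.  Events precede censorings at tied times (the
#' standard convention), so censored subjects at an event time still count
#' as at risk for that time.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param conf.level confidence level for pointwise intervals (log(-log)
#'   transformed so they stay in \[0, 1\]).
#' @return an object of class `"km_curve"`: a list with `time` (distinct
#'   event/censoring times), `n_risk`, `n_event`, `n_censor`, `surv`, `se`
#'   (Greenwood), `lower`/`upper`, and counts `n`, `n_censored`.
#' @examples
#' km <- km_fit(c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 0))
#' survival_at(km, c(2.5, 10))
#' restricted_mean(km, horizon = 5)
#' @export
km_fit <- function(time, event, conf.level = 0.95) {
  if (length(time) == 0L) stop("empty cohort", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("'time' must be finite and > 0", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("'event' must be 0/1", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "log-log", conf.int = conf.level)
  # survfit stores se(log S); Greenwood se of S itself is S * that, and 0
  # once the curve reaches 0 (where std.err is infinite)
  se <- ifelse(sf$surv == 0, 0, sf$std.err * sf$surv)
  structure(list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 n_censor = sf$n.censor, surv = sf$surv,
                 se = se,
                 lower = sf$lower, upper = sf$upper,
                 n = length(time), n_censored = sum(event == 0),
                 conf.level = conf.level),
            class = "km_curve")
}

#' Kaplan-Meier curves by group
#'
#' @param data a data frame with `time` and `event` columns.
#' @param group name of a factor column of `data`; `NULL` for a single
#'   overall curve.
#' @return a named list of [km_fit()] curves (or a single curve when
#'   `group` is `NULL`).
#' @export
km_by <- function(data, group = NULL) {
  if (is.null(group)) return(km_fit(data$time, data$event))
  g <- data[[group]]
  if (is.null(g)) stop("no column '", group, "' in 'data'", call. = FALSE)
  idx <- split(seq_len(nrow(data)), g, drop = FALSE)
  empty <- vapply(idx, length, integer(1L)) == 0L
  if (any(empty))
    stop("empty group(s): ", paste(names(idx)[empty], collapse = ", "),
         call. = FALSE)
  lapply(idx, function(i) km_fit(data$time[i], data$event[i]))
}

#' Survival probabilities at landmark times
#'
#' Right-continuous step-function lookup on a Kaplan-Meier curve:
#' probability 1 before the first event, the last estimate beyond the last
#' observed time.
#'
#' @param curve a [km_fit()] object.
#' @param times non-negative landmark times.
#' @return numeric vector of survival probabilities.
#' @export
survival_at <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(times < 0)) stop("'times' must be >= 0", call. = FALSE)
  idx <- findInterval(times, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve up to a truncation horizon, with the
#' standard restricted-mean variance
#' \eqn{\widehat{\mathrm{Var}} = \sum_i A_i^2\, d_i / [n_i (n_i - d_i)]}
#' where the sum runs over event times before the horizon and \eqn{A_i} is
#' the area remaining beyond that event time.  This is the "mean survival
#' time" that standard survival software reports for censored data.
#'
#' @param curve a [km_fit()] object.
#' @param horizon truncation time; defaults to the largest observed time.
#' @param conf.level confidence level of the normal-theory interval.
#' @return a list of class `"rmst"`: `mean`, `se`, `ci_low`, `ci_high`,
#'   `horizon`.
#' @export
restricted_mean <- function(curve, horizon = NULL, conf.level = 0.95) {
  stopifnot(inherits(curve, "km_curve"))
  if (is.null(horizon)) horizon <- max(curve$time)
  if (!is.finite(horizon) || horizon <= 0)
    stop("'horizon' must be > 0", call. = FALSE)
  if (horizon > max(curve$time) + 1e-12)
    stop("'horizon' must not exceed the largest observed time", call. = FALSE)
  # step function: S = 1 on [0, t1), curve$surv[i] on [t_i, t_{i+1})
  tt <- c(0, curve$time[curve$time < horizon], horizon)
  ss <- c(1, curve$surv[curve$time < horizon])
  area <- sum(ss * diff(tt))
  # remaining area beyond each event time, and Greenwood-type variance
  ev <- which(curve$n_event > 0 & curve$time < horizon)
  v <- 0
  if (length(ev)) {
    seg_area <- ss * diff(tt)                 # area of each step segment
    # cumulative area from each time point to the horizon
    rem <- rev(cumsum(rev(seg_area)))
    # A_i: area after event time t_i = total minus area up to t_i
    pos <- match(curve$time[ev], tt)          # segment starting at t_i
    A <- rem[pos]
    d <- curve$n_event[ev]
    nr <- curve$n_risk[ev]
    ok <- nr > d
    v <- sum(A[ok]^2 * d[ok] / (nr[ok] * (nr[ok] - d[ok])))
  }
  se <- sqrt(v)
  zq <- stats::qnorm(1 - (1 - conf.level) / 2)
  structure(list(mean = area, se = se, ci_low = area - zq * se,
                 ci_high = area + zq * se, horizon = horizon,
                 conf.level = conf.level), class = "rmst")
}

#' @export
print.rmst <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Restricted mean survival time (horizon %.3g): %.*f (se %.*f, %g%% CI %.*f-%.*f)\n",
    x$horizon, digits, x$mean, digits, x$se, 100 * x$conf.level,
    digits, x$ci_low, digits, x$ci_high))
  invisible(x)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d (%.1f%% censored)\n",
              x$n, x$n - x$n_censored, 100 * x$n_censored / x$n))
  cat(sprintf("follow-up %.3g-%.3g, final survival %.3f\n",
              min(x$time), max(x$time), x$surv[length(x$surv)]))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, conf = TRUE, col = "black", xlab = "Time",
                          ylab = "Survival probability", ...) {
  tt <- c(0, x$time)
  ss <- c(1, x$surv)
  plot(tt, ss, type = "s", ylim = c(0, 1), col = col, xlab = xlab,
       ylab = ylab, ...)
  if (conf) {
    graphics::lines(tt, c(1, x$lower), type = "s", lty = 3, col = col)
    graphics::lines(tt, c(1, x$upper), type = "s", lty = 3, col = col)
  }
  invisible(x)
}
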