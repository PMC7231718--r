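#' Empirical highest posterior density interval
#'
#' Chen-Shao estimate of the highest posterior density (HPD) interval from
#' a sample of draws: sort the draws, slide a window containing
#' \eqn{m = \lceil \mathrm{prob}\cdot n\rceil} consecutive order statistics,
#' and return the narrowest such window (ties broken by the earliest
#' window).  For a unimodal posterior this is the shortest interval holding
#' the requested mass.
#'
#' @param x numeric vector of draws (at least 20).
#' @param prob target probability mass, default 0.95.
#' @return a named numeric vector `c(lower, upper)` with attribute
#'   `"prob"`.
#' @examples
#' hpd(1:100)          # window of 95 order statistics: c(1, 95)
#' @export
hpd <- function(x, prob = 0.95) {
  if (length(prob) != 1L || !is.finite(prob) || prob <= 0 || prob > 1)
    stop("'prob' must be in (0, 1]", call. = FALSE)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20L) stop("need at least 20 draws for an HPD interval", call. = FALSE)
  m <- ceiling(prob * n)
  if (m > n) m <- n
  s <- sort(x)
  if (m == n) {
    out <- c(lower = s[1L], upper = s[n])
  } else {
    width <- s[m:n] - s[seq_len(n - m + 1L)]
    i <- which.min(width)                 # which.min takes the earliest tie
    out <- c(lower = s[i], upper = s[i + m - 1L])
  }
  attr(out, "prob") <- prob
  out
}
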