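#' Storey q-values
#'
#' Converts p-values to false-discovery-rate q-values.  The proportion of
#' true nulls \eqn{\pi_0} is estimated on the grid
#' `lambda = 0.05, 0.10, ..., 0.95` as
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m (1 - \lambda))},
#' smoothed by a natural cubic smoothing spline (df = 3) and evaluated at
#' the largest lambda, then clipped to (0, 1].  Q-values are the step-down
#' minima \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0 m p_{(j)} / j}.  With
#' `pi0 = 1` the result equals Benjamini-Hochberg adjusted p-values.
#'
#' @param pvals Vector of p-values in \[0, 1\].
#' @param pi0 Optional fixed value for \eqn{\pi_0} (e.g. 1); default:
#'   Storey's smoother estimate.
#' @param lambda Grid for \eqn{\pi_0} estimation.
#' @return List with `qvalues` (same order as `pvals`) and `pi0`.
#' @examples
#' qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)$qvalues
#' @export
qvalues <- function(pvals, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(pvals)
  if (m == 0) abort("empty p-value vector.", class = "reactnorm_domain_error")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.",
          class = "reactnorm_domain_error")
  }
  if (is.null(pi0)) {
    pi0_grid <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
    if (all(pi0_grid <= 0) || m < 20) {
      warn("degenerate p-value distribution; falling back to pi0 = 1.")
      pi0 <- 1
    } else {
      fit <- stats::smooth.spline(lambda, pi0_grid, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      if (!is.finite(pi0) || pi0 <= 0) {
        warn("pi0 smoother degenerate; falling back to pi0 = 1.")
        pi0 <- 1
      }
      pi0 <- min(pi0, 1)
    }
  }
  ord <- order(pvals)
  q_ord <- pi0 * m * pvals[ord] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q_ord <- pmin(q_ord, 1)
  q <- numeric(m)
  q[ord] <- q_ord
  list(qvalues = q, pi0 = pi0)
}
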