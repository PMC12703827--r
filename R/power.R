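# Paired-t power utilities: post-hoc achieved power and sensitivity
# (minimum detectable effect size), both via the noncentral t distribution
# rather than a normal approximation.

#' Post-hoc power of a two-tailed paired t-test
#'
#' \code{power = P(|T'| > t_{1-alpha/2, n-1})} where T' is noncentral t
#' with df = n - 1 and noncentrality \code{dz * sqrt(n)}. Both rejection
#' tails are included; the lower tail contributes only in the fourth
#' decimal for typical effect sizes but is part of the exact two-tailed
#' definition. At \code{dz = 0} the function returns \code{alpha}, the
#' test's size.
#'
#' @param dz paired effect size (mean of within-pair differences divided
#'   by their SD), >= 0.
#' @param n number of pairs, >= 2.
#' @param alpha two-tailed significance level.
#' @return achieved power in (0, 1).
#' @examples
#' posthocPower(0.767, 30, 0.05)
#' @export
posthocPower <- function(dz, n, alpha = 0.05) {
  if (dz < 0) stop("dz must be >= 0")
  if (n < 2) stop("n must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- n - 1
  ncp <- dz * sqrt(n)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Sensitivity: minimum detectable paired effect size
#'
#' The dz at which the two-tailed paired t-test reaches the target power,
#' found by bracketed root-finding on \code{\link{posthocPower}} to 1e-6.
#'
#' @param n number of pairs.
#' @param alpha two-tailed significance level.
#' @param power target power, must exceed \code{alpha}.
#' @return minimal detectable dz.
#' @examples
#' sensitivityDz(30, 0.05, 0.80)
#' @export
sensitivityDz <- function(n, alpha = 0.05, power = 0.80) {
  if (power <= alpha)
    stop("target power must exceed alpha (no solution otherwise)")
  if (power >= 1) stop("power must be < 1")
  f <- function(dz) posthocPower(dz, n, alpha) - power
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}
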