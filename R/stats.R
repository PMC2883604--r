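## Shared statistical primitives with the exact conventions used throughout:
## doubled-tail exact binomial, Clopper-Pearson intervals, significance codes.

#' Exact two-sided binomial test (doubled smaller tail)
#'
#' Two-sided p-value computed as twice the smaller of `P(X <= x)` and
#' `P(X >= x)` under `Binomial(n, p0)`, capped at 1.  This doubled-tail
#' convention flags both enrichment and depletion symmetrically (it differs
#' from the likelihood-ordering rule of [stats::binom.test()]).
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param p0 null success probability.
#' @return p-value in \[0,1\].
#' @export
#' @examples
#' binomTestTwoSided(30, 50, 0.4)
binomTestTwoSided <- function(x, n, p0) {
  stopifnot(x >= 0, x <= n, p0 >= 0, p0 <= 1)
  lower <- pbinom(x, n, p0)
  upper <- if (x == 0) 1 else pbinom(x - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Numeric `c(lower, upper)` for the success proportion.
#' @export
#' @examples
#' clopperPearsonCI(40, 100)
clopperPearsonCI <- function(x, n, conf = 0.95) {
  stopifnot(x >= 0, x <= n, n > 0)
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Significance codes for p-values
#'
#' `***` p<0.001, `**` p<0.01, `*` p<0.05, empty otherwise; `NA` maps to
#' empty.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of codes.
#' @export
signifCode <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

#' One-sided hypergeometric enrichment/depletion p-values
#'
#' For `x` members of a size-`n` sample drawn from a population of `N` with
#' `K` marked: over-representation `P(X >= x)` and under-representation
#' `P(X <= x)`.
#'
#' @param x observed overlap.
#' @param K marked population size.
#' @param n sample size.
#' @param N population size.
#' @return Numeric `c(over, under)`.
#' @export
hypergeomTests <- function(x, K, n, N) {
  c(over = phyper(x - 1, K, N - K, n, lower.tail = FALSE),
    under = phyper(x, K, N - K, n))
}
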