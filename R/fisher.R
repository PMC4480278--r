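## One-sided Fisher (hypergeometric upper tail) for overrepresentation.

#' Upper-tail Fisher exact probability of an overlap
#'
#' \code{P(X >= k)} for \code{X} hypergeometric with \code{N} background
#' proteins of which \code{K} are positive for the term, drawing \code{n}
#' input proteins. Computed in log space via \code{stats::phyper}, accurate
#' to well below 1e-10 relative error. Vectorized over its arguments.
#'
#' @param N background universe size.
#' @param K background proteins positive for the term.
#' @param n input proteins in the universe.
#' @param k input proteins positive for the term.
#' @return Numeric vector of upper-tail probabilities.
#' @examples
#' fisherUpperTail(20, 5, 4, 3)  # 155/4845
#' @export
fisherUpperTail <- function(N, K, n, k) {
  bad <- K > N | n > N | k > pmin(K, n) | k < 0 | K < 0 | n < 0 | N < 0
  if (any(bad))
    stop("invalid contingency counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
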