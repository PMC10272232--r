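#' Upper-tail hypergeometric probability (over-representation test)
#'
#' P(X >= x) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `x` marked genes in `n` draws without replacement from a universe
#' of `N` genes of which `K` are marked. The tail is inclusive of the
#' observed count, so x = 0 always gives 1.
#'
#' @param x Observed number of marked genes in the group.
#' @param N Universe size (all genes with promoter windows).
#' @param K Marked genes in the universe (windows containing the class).
#' @param n Group size.
#' @return The p-value, in (0, 1]. All arguments recycle to a common length.
#' @export
hypergeom_upper_tail <- function(x, N, K, n) {
  len <- max(length(x), length(N), length(K), length(n))
  x <- rep_len(as.numeric(x), len)
  N <- rep_len(as.numeric(N), len)
  K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len)
  if (any(K < 0 | K > N) || any(n < 0 | n > N))
    stop("hypergeometric bounds violated: need 0 <= K <= N and 0 <= n <= N")
  if (any(x < 0 | x > pmin(n, K)))
    stop("hypergeometric bounds violated: need 0 <= x <= min(n, K)")
  stats::phyper(x - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}
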