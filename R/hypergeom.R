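#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` labelled genes in a window of `n`
#' genes drawn without replacement from a genome of `N` genes of which `K`
#' carry the label — the cluster enrichment statistic. Computed in log space
#' from log binomial coefficients (`lchoose`) with a log-sum-exp reduction,
#' so it stays accurate for the very small tail probabilities that dense
#' clusters produce.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param N Population size (total genes), `N >= 1`.
#' @param K Labelled genes in the population, `0 <= K <= N`.
#' @param n Window size in genes, `0 <= n <= N`.
#' @param k Labelled genes observed in the window, `0 <= k <= min(n, K)`.
#' @return Numeric vector of tail probabilities in `(0, 1]`;
#'   `k = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeom_tail(50, 10, 5, 5)  # choose(10, 5) / choose(50, 5)
hypergeom_tail <- function(N, K, n, k) {
  len <- max(length(N), length(K), length(n), length(k))
  N <- rep_len(as.numeric(N), len)
  K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len)
  k <- rep_len(as.numeric(k), len)
  ok <- N >= 1 & K >= 0 & K <= N & n >= 0 & n <= N & k >= 0 & k <= n & k <= K
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop(sprintf(
      "invalid hypergeometric arguments: N=%g K=%g n=%g k=%g",
      N[i], K[i], n[i], k[i]
    ), call. = FALSE)
  }
  vapply(seq_len(len), function(i) {
    hg_tail_scalar(N[i], K[i], n[i], k[i])
  }, numeric(1))
}

hg_tail_scalar <- function(N, K, n, k) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(lt)
  p <- exp(m + log(sum(exp(lt - m))))
  min(p, 1)
}
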