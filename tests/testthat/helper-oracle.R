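# Independent oracles. The frozen table fixtures/audic_exact.tsv holds
# exact-rational evaluations of the two-library pmf and its tails
# (computed once with arbitrary-precision rational arithmetic and stored
# to 17 significant digits). The live oracles below use R's
# dnbinom/pnbinom — the pmf is a negative-binomial density with
# size = x + 1 and prob = N1/(N1+N2), and R's tail goes through the
# incomplete beta function, a code path independent of the package's
# lgamma + log-sum-exp summation.

load_exact_audic <- function() {
  utils::read.delim(test_path("fixtures", "audic_exact.tsv"))
}

oracle_pmf <- function(x, y, N1, N2) {
  stats::dnbinom(y, size = x + 1, prob = N1 / (N1 + N2))
}

oracle_pvalue <- function(x, y, N1, N2) {
  p <- N1 / (N1 + N2)
  lower <- stats::pnbinom(y, size = x + 1, prob = p)
  upper <- if (y == 0) 1 else
    stats::pnbinom(y - 1, size = x + 1, prob = p, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# Literal O(m^2) step-up definition, independent of the package's cummin
# formulation and of stats::p.adjust.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(p[o][i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Exhaustive-enumeration hypergeometric upper tail: exact in doubles for
# N <= 25 (all binomials < 2^53).
brute_hyper_tail <- function(m, n, M, N) {
  i <- m:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

rel_err <- function(a, b) {
  ifelse(b == 0, abs(a - b), abs(a - b) / abs(b))
}
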