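# Independently coded oracles, kept deliberately naive so they cannot share a
# code path with the implementation they check.

# textbook pooled-variance two-sample two-tailed t test
oracle_t_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tstat), df = n1 + n2 - 2)
}

# hypergeometric upper tail P(X >= k) as an explicit factorial-ratio sum
oracle_hyper_tail <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# sort-and-pick median (midpoint of the two central values when even)
oracle_median <- function(v) {
  s <- sort(unname(v))
  m <- length(s)
  if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
}

# hand-rolled Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# convenience profile builder for selection tests; tissue vectors (including
# whole_body) are passed as named arguments
make_profile <- function(probe = "p1", gene = "g1", sym = "CG1000",
                         ..., present = NULL) {
  ints <- list(...)
  if (is.null(present)) {
    present <- lapply(ints, function(x) rep(TRUE, length(x)))
  }
  probe_profile(probe, gene, sym, ints, present, whole_body = "whole_body")
}
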