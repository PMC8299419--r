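## Independent brute-force oracles, written directly from the defining
## formulas. They deliberately share no code with the package.

bf_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bf_slope <- function(expression, lifespan) {
  me <- sum(expression) / length(expression)
  ml <- sum(lifespan) / length(lifespan)
  sum((expression - me) * (lifespan - ml)) / sum((expression - me)^2)
}

## P(X >= k) by explicit enumeration of the hypergeometric pmf
bf_hypergeom_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- seq.int(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## Benjamini-Hochberg step-up by hand
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## absolute-difference expectation (testthat's default tolerance is
## relative, which is too strict for near-zero correlations)
expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}

## small random score table keyed by gene, for cross-dataset tests
make_score_table <- function(dataset_id, gene_id, r) {
  structure(
    data.frame(dataset_id = dataset_id, gene_id = gene_id, r = r,
               slope = r * 100, n_used = 8L,
               pass_04 = !is.na(r) & abs(r) >= 0.4,
               pass_07 = !is.na(r) & abs(r) >= 0.7,
               stringsAsFactors = FALSE),
    class = c("longevity_scores", "data.frame"))
}

## tiny in-memory dataset builder
make_dataset <- function(values, dataset_id = "toy", ...) {
  omics_dataset(values, dataset_id = dataset_id, ...)
}
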