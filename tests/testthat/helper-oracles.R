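# Independent brute-force oracles used across the suite.

# O(n^2) union-find merge of overlapping half-open intervals (single chrom
# handled via keying); returns sorted disjoint spans.
bf_merge <- function(df) {
  n <- nrow(df)
  if (!n) return(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && df$chrom[i] == df$chrom[j] &&
        df$start[i] < df$end[j] && df$end[i] > df$start[j])
      parent[find(i)] <- find(j)
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(root), function(r) {
    grp <- df[root == r, , drop = FALSE]
    data.frame(chrom = grp$chrom[1], start = min(grp$start),
               end = max(grp$end), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# exact two-sided Fisher p by full hypergeometric enumeration
bf_fisher <- function(am, au, bm, bu) {
  M <- am + bm; nA <- am + au; nB <- bm + bu
  x <- max(0, M - nB):min(nA, M)
  d <- dhyper(x, M, nA + nB - M, nA)
  obs <- dhyper(am, M, nA + nB - M, nA)
  sum(d[d <= obs * (1 + 1e-7)])
}

# exact upper binomial tail by direct summation
bf_binom_tail <- function(a, n, p) sum(dbinom(a:n, n, p))

# exact upper hypergeometric tail by direct summation:
# X ~ Hyper(universe N, |A| draws, |B| successes)
bf_hyper_tail <- function(k, N, nA, nB) {
  x <- k:min(nA, nB)
  sum(choose(nB, x) * choose(N - nB, nA - x)) / choose(N, nA)
}

# random peak set on few chromosomes
rand_peaks <- function(n, chroms = c("chr1", "chr2"), span = 10000,
                       max_w = 300) {
  s <- sample.int(span, n, replace = TRUE)
  peak_set(sample(chroms, n, replace = TRUE), s,
           s + sample.int(max_w, n, replace = TRUE))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
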