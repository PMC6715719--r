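#' Fisher exact test for one CpG site
#'
#' Two-sided exact test on the 2x2 table of methylated/unmethylated calls in
#' two conditions: the p-value sums the hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's (up to a relative tie tolerance of 1e-7).
#'
#' @param a_meth,a_unmeth Counts in condition A.
#' @param b_meth,b_unmeth Counts in condition B.
#' @return Two-sided p-value.
#' @export
fisher_test_site <- function(a_meth, a_unmeth, b_meth, b_unmeth) {
  if (any(c(a_meth, a_unmeth, b_meth, b_unmeth) < 0))
    stop("counts must be non-negative")
  if (a_meth + a_unmeth == 0 || b_meth + b_unmeth == 0)
    stop("empty margin: both conditions need calls")
  stats::fisher.test(matrix(c(a_meth, a_unmeth, b_meth, b_unmeth), 2))$p.value
}

# Two-sided Fisher p for every achievable table with fixed margins:
# group sizes nA, nB (total calls) and pooled methylated count M.
# Returns p indexed by x = methylated calls in A (support offset attr).
# Used by the permutation layer, where all 1000 permuted tables share these
# margins; exactness vs stats::fisher.test is asserted in the test suite.
.fisher_p_support <- function(nA, nB, M) {
  lo <- max(0L, M - nB)
  hi <- min(nA, M)
  x <- lo:hi
  d <- stats::dhyper(x, M, nA + nB - M, nA)
  p <- vapply(d, function(dx) sum(d[d <= dx * (1 + 1e-7)]), numeric(1))
  p <- pmin(p, 1)
  structure(p, offset = lo)
}

#' Sequential permutation p-value for one CpG site
#'
#' The test statistic is the two-sided Fisher p of the observed split
#' (smaller = more extreme). Calls from both groups are pooled and randomly
#' re-split into the original group sizes each permutation; an exceedance is
#' a permuted statistic less than or equal to the observed one. The loop
#' stops early once `r` exceedances accumulate, reporting `r / b` (`b` =
#' permutations used); otherwise it runs all `B` permutations and reports
#' `(exceedances + 1) / (B + 1)`. Re-splitting is realized by drawing the
#' group-A methylated count from the matching hypergeometric distribution,
#' which is distributionally identical to an explicit uniform re-split.
#'
#' @param a_calls,b_calls Binary call vectors (1 = methylated) for the two
#'   groups; both non-empty.
#' @param B Maximum permutations (default 1000).
#' @param r Early-stopping exceedance count (default 10).
#' @param seed Integer seed.
#' @return List with `p` and `permutations_used`.
#' @export
permutation_pvalue <- function(a_calls, b_calls, B = 1000L, r = 10L,
                               seed = 1L) {
  stopifnot(length(a_calls) > 0, length(b_calls) > 0, B >= r, r >= 1)
  res <- withr::with_seed(seed,
    .perm_p(sum(a_calls == 1), length(a_calls),
            sum(b_calls == 1), length(b_calls), B, r))
  res
}

# core sequential permutation; uses the current RNG stream
.perm_p <- function(mA, nA, mB, nB, B, r) {
  M <- mA + mB
  p_sup <- .fisher_p_support(nA, nB, M)
  off <- attr(p_sup, "offset")
  obs <- p_sup[mA - off + 1L]
  perm_x <- stats::rhyper(B, M, nA + nB - M, nA)
  exceed <- p_sup[perm_x - off + 1L] <= obs * (1 + 1e-12)
  cum <- cumsum(exceed)
  hit <- which(cum >= r)
  if (length(hit)) {
    b <- hit[1]
    list(p = r / b, permutations_used = b)
  } else {
    list(p = (cum[B] + 1) / (B + 1), permutations_used = B)
  }
}

#' Histogram estimate of the number of true null hypotheses
#'
#' Builds an equal-width histogram of the p-values on (0,1\] and iterates:
#' given the current m0, the expected count per bin is `m0 / bins`; let `i*`
#' be the leftmost bin whose observed count does not exceed that expectation;
#' the updated m0 rescales the total count in bins `i*..bins` to the full
#' unit interval. The recursion is non-increasing and bounded, hence
#' converges; the fixed point, clipped to \[0, m\], is returned.
#'
#' @param p_values Vector of p-values in (0,1\].
#' @param bins Number of histogram bins (default 20).
#' @return Estimated m0 (numeric).
#' @export
estimate_m0 <- function(p_values, bins = 20L) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0,1]")
  stopifnot(bins >= 2)
  m <- length(p_values)
  idx <- pmin(bins, pmax(1L, ceiling(p_values * bins)))
  counts <- tabulate(idx, nbins = bins)
  m0 <- m
  for (iter in 1:100) {
    expected <- m0 / bins
    istar <- which(counts <= expected)[1]
    if (is.na(istar)) break
    new_m0 <- sum(counts[istar:bins]) * bins / (bins - istar + 1)
    new_m0 <- min(max(new_m0, 0), m)
    if (abs(new_m0 - m0) < 1e-9) { m0 <- new_m0; break }
    m0 <- new_m0
  }
  m0
}

#' m0-scaled step-up p-value adjustment
#'
#' Benjamini–Hochberg-style step-up adjustment with the estimated number of
#' true nulls `m0` in place of the total test count: after sorting
#' ascending, `q(i) = min over j >= i of min(1, p(j) * m0 / j)`, restored to
#' input order. With `m0 = m` this is exactly textbook BH.
#'
#' @param p_values Vector of p-values.
#' @param m0 Estimated true null count in \[0, length(p_values)\].
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p_values, m0) {
  m <- length(p_values)
  if (m0 < 0 || m0 > m) stop("m0 must lie in [0, m]")
  if (!m) return(numeric())
  o <- order(p_values)
  q <- pmin(1, p_values[o] * m0 / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Configure the FDR model for DMS calling
#'
#' @param B Permutations per site (default 1000).
#' @param r Sequential stopping exceedance count (default 10).
#' @param bins Histogram bins for the m0 estimate (default 20).
#' @param permute Use the sequential permutation p (default `TRUE`) in place
#'   of the exact Fisher p as input to the m0 adjustment.
#' @param seed Integer seed driving all permutations.
#' @return List of class `fdr_model`.
#' @export
fdr_model <- function(B = 1000L, r = 10L, bins = 20L, permute = TRUE,
                      seed = 1L) {
  stopifnot(B >= r, r >= 1, bins >= 2)
  structure(list(B = as.integer(B), r = as.integer(r),
                 bins = as.integer(bins), permute = permute,
                 seed = as.integer(seed)),
            class = "fdr_model")
}

#' Call differentially methylated sites between two methylomes
#'
#' Sites with at least `min_coverage` calls in BOTH samples are tested with
#' the Fisher exact test; when the FDR model enables permutation, the
#' sequential permutation p-value replaces the exact p. The number of true
#' nulls m0 is estimated from the p-value histogram and drives the step-up
#' adjustment; a site is a DMS iff its adjusted p is at most `alpha`. The
#' methylation difference `delta = beta_a - beta_b` and its direction
#' (`hyper` = higher in A) are recorded per site.
#'
#' @param methylome_a,methylome_b `methylome` objects sharing a coordinate
#'   system (condition A is e.g. the knockout, B the wild type).
#' @param min_coverage Per-sample coverage bar (default 10).
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @param fdr An [fdr_model()] configuration.
#' @return List of class `dms_result`: `sites` (data frame with chrom, pos,
#'   beta_a, beta_b, p, adjusted_p, delta, direction, is_dms), `m` tested
#'   sites, `m0`, `alpha`, `fdr`.
#' @export
call_dms <- function(methylome_a, methylome_b, min_coverage = 10L,
                     alpha = 0.05, fdr = fdr_model()) {
  a <- as.data.frame(methylome_a)
  b <- as.data.frame(methylome_b)
  key_a <- paste(a$chrom, a$pos)
  key_b <- paste(b$chrom, b$pos)
  ib <- match(key_a, key_b)
  shared <- which(!is.na(ib))
  a2 <- a[shared, , drop = FALSE]
  b2 <- b[ib[shared], , drop = FALSE]
  ok <- a2$total >= min_coverage & b2$total >= min_coverage
  a2 <- a2[ok, , drop = FALSE]
  b2 <- b2[ok, , drop = FALSE]
  m <- nrow(a2)
  if (!m) {
    warning("no shared sites meet the coverage bar; empty result")
    sites <- data.frame(chrom = character(), pos = integer(),
                        beta_a = numeric(), beta_b = numeric(),
                        p = numeric(), adjusted_p = numeric(),
                        delta = numeric(), direction = character(),
                        is_dms = logical())
    return(structure(list(sites = sites, m = 0L, m0 = 0, alpha = alpha,
                          fdr = fdr), class = "dms_result"))
  }
  p_fisher <- vapply(seq_len(m), function(i)
    fisher_test_site(a2$meth[i], a2$total[i] - a2$meth[i],
                     b2$meth[i], b2$total[i] - b2$meth[i]), numeric(1))
  if (isTRUE(fdr$permute)) {
    p_used <- withr::with_seed(fdr$seed, vapply(seq_len(m), function(i)
      .perm_p(a2$meth[i], a2$total[i], b2$meth[i], b2$total[i],
              fdr$B, fdr$r)$p, numeric(1)))
  } else {
    p_used <- p_fisher
  }
  m0 <- estimate_m0(p_used, bins = fdr$bins)
  adj <- adjust_pvalues(p_used, m0)
  beta_a <- a2$meth / a2$total
  beta_b <- b2$meth / b2$total
  delta <- beta_a - beta_b
  sites <- data.frame(
    chrom = a2$chrom, pos = a2$pos, beta_a = beta_a, beta_b = beta_b,
    p = p_used, adjusted_p = adj, delta = delta,
    direction = ifelse(delta > 0, "hyper",
                       ifelse(delta < 0, "hypo", NA_character_)),
    is_dms = adj <= alpha & delta != 0,
    stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites, m = m, m0 = m0, alpha = alpha, fdr = fdr),
            class = "dms_result")
}

#' @export
print.dms_result <- function(x, ...) {
  cat(sprintf("dms_result: %d sites tested, m0 = %.1f, %d DMS at alpha = %g\n",
              x$m, x$m0, sum(x$sites$is_dms), x$alpha))
  invisible(x)
}

#' @export
summary.dms_result <- function(object, ...) {
  s <- object$sites[object$sites$is_dms, , drop = FALSE]
  n <- nrow(s)
  n_hyper <- sum(s$direction == "hyper")
  n_hypo <- sum(s$direction == "hypo")
  out <- list(n_tested = object$m, m0 = object$m0, n_dms = n,
              n_hyper = n_hyper, n_hypo = n_hypo,
              pct_hyper = if (n) round(100 * n_hyper / n, 1) else NA_real_,
              pct_hypo = if (n) round(100 * n_hypo / n, 1) else NA_real_)
  class(out) <- "summary.dms_result"
  out
}

#' @export
print.summary.dms_result <- function(x, ...) {
  cat(sprintf("%d sites tested (m0 = %.1f): %d DMS — %d hypermethylated (%.1f%%), %d hypomethylated (%.1f%%)\n",
              x$n_tested, x$m0, x$n_dms, x$n_hyper, x$pct_hyper,
              x$n_hypo, x$pct_hypo))
  invisible(x)
}
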