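#' Locus x sample methylation matrix
#'
#' Each cell is the coverage-weighted methylation level of a locus in one
#' sample: sum(meth)/sum(total) over the CpGs inside the locus, or `NA` when
#' total calls fall below `min_calls` (regions with fewer than ten calls in
#' any sample are too noisy to correlate).
#'
#' @param methylomes Named list of `methylome` objects (names become column
#'   labels).
#' @param loci A `peak_set` of loci (rows).
#' @param min_calls Minimum total calls per cell (default 10).
#' @return Numeric matrix (loci x samples) of class `methylation_matrix`,
#'   with attribute `complete` flagging rows without missing values.
#' @export
locus_methylation_matrix <- function(methylomes, loci, min_calls = 10L) {
  stopifnot(length(methylomes) >= 1)
  if (is.null(names(methylomes)))
    names(methylomes) <- paste0("sample", seq_along(methylomes))
  mat <- vapply(methylomes, function(m)
    .region_levels(loci, m, min_calls), numeric(nrow(loci)))
  if (nrow(loci) == 1L) mat <- matrix(mat, 1,
                                      dimnames = list(NULL, names(methylomes)))
  rn <- ifelse(is.na(loci$name),
               paste0(loci$chrom, ":", loci$start, "-", loci$end), loci$name)
  rownames(mat) <- rn
  structure(mat, class = c("methylation_matrix", class(mat)),
            complete = stats::complete.cases(mat), min_calls = min_calls)
}

#' All-pairs locus correlation
#'
#' Pearson correlation of methylation profiles between every pair of loci.
#' Loci with any missing value are excluded listwise; zero-variance loci are
#' dropped with a warning (their correlation is undefined).
#'
#' @param mat A `methylation_matrix` (loci x samples), >= 3 samples.
#' @return Symmetric correlation matrix with unit diagonal over the retained
#'   loci.
#' @export
pairwise_correlation <- function(mat) {
  if (ncol(mat) < 3) stop("need >= 3 samples for locus correlations")
  keep <- stats::complete.cases(mat)
  if (any(!keep))
    warning(sum(!keep), " locus(i) with missing values excluded")
  m <- mat[keep, , drop = FALSE]
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance locus(i) dropped")
    m <- m[v > 0, , drop = FALSE]
  }
  stats::cor(t(m))
}

#' Partition loci into co-methylated modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - r`, cut
#' to exactly `k` modules. Deterministic given the input order. When the
#' underlying methylation matrix is supplied, per-module mean profiles are
#' attached.
#'
#' @param corr Symmetric correlation matrix from [pairwise_correlation()].
#' @param k Number of modules (default 5).
#' @param values Optional `methylation_matrix` restricted to the loci of
#'   `corr`, used for module mean profiles.
#' @return List of class `module_assignment` with `assignment` (named
#'   integer vector in 1..k), `k` and `profiles` (k x samples matrix or
#'   `NULL`).
#' @export
detect_modules <- function(corr, k = 5L, values = NULL) {
  n <- nrow(corr)
  if (k > n) stop("k must not exceed the number of loci")
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  assignment <- stats::cutree(hc, k = k)
  profiles <- NULL
  if (!is.null(values)) {
    values <- values[rownames(corr), , drop = FALSE]
    profiles <- do.call(rbind, lapply(seq_len(k), function(g)
      colMeans(values[assignment == g, , drop = FALSE], na.rm = TRUE)))
    rownames(profiles) <- paste0("module_", seq_len(k))
  }
  structure(list(assignment = assignment, k = as.integer(k),
                 profiles = profiles),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module_assignment: %d loci in %d modules\n",
              length(x$assignment), x$k))
  print(table(module = x$assignment))
  invisible(x)
}
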