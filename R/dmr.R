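#' Chain adjacent DMSs into clusters
#'
#' Single-linkage chaining: consecutive DMSs (sorted by position within a
#' chromosome) whose gap is at most `max_gap` bp join the same cluster;
#' clusters never span chromosomes.
#'
#' @param dms Data frame with at least `chrom` and `pos` (e.g. the DMS rows
#'   of a [call_dms()] result).
#' @param max_gap Maximum bp distance between adjacent cluster members
#'   (default 500).
#' @return The input with an integer `cluster` column, sorted by
#'   (chrom, pos).
#' @export
cluster_dms <- function(dms, max_gap = 500L) {
  if (!nrow(dms)) {
    dms$cluster <- integer()
    return(dms)
  }
  dms <- dms[order(dms$chrom, dms$pos), , drop = FALSE]
  new_chrom <- c(TRUE, dms$chrom[-1] != dms$chrom[-nrow(dms)])
  gap <- c(0L, diff(dms$pos))
  dms$cluster <- cumsum(new_chrom | gap > max_gap)
  rownames(dms) <- NULL
  dms
}

#' Call differentially methylated regions (two-step)
#'
#' Step 1: a cluster from [cluster_dms()] is a candidate iff it holds at
#' least `min_dms` DMSs and at least `consistency` of them share one
#' direction (the dominant one). Step 2: over ALL covered CpGs in the
#' candidate span, a CpG supports the region iff the sign of its methylation
#' difference matches the dominant direction AND its absolute difference is
#' at least `min_delta`; the region is emitted iff the supporting fraction
#' reaches `consistency`. The region interval is
#' \[first DMS position, last DMS position + 1).
#'
#' @param clusters Output of [cluster_dms()] (must carry `delta`).
#' @param all_sites Data frame with `chrom`, `pos`, `delta` for every
#'   covered (tested) CpG, spanning the cluster intervals.
#' @param min_dms Minimum DMSs per cluster (default 5).
#' @param consistency Direction-consistency fraction for both steps
#'   (default 0.8).
#' @param min_delta Per-CpG absolute methylation difference bar in step 2
#'   (default 0.1).
#' @return Data frame of class `dmr_result`: chrom, start, end, n_dms,
#'   n_cpg, direction, support_fraction, mean_delta.
#' @export
call_dmrs <- function(clusters, all_sites, min_dms = 5L, consistency = 0.8,
                      min_delta = 0.1) {
  empty <- structure(
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_dms = integer(), n_cpg = integer(), direction = character(),
               support_fraction = numeric(), mean_delta = numeric(),
               stringsAsFactors = FALSE),
    class = c("dmr_result", "data.frame"))
  if (!nrow(clusters)) return(empty)
  rows <- lapply(split(seq_len(nrow(clusters)), clusters$cluster),
                 function(idx) {
    cl <- clusters[idx, , drop = FALSE]
    if (nrow(cl) < min_dms) return(NULL)
    n_up <- sum(cl$delta > 0)
    n_dn <- sum(cl$delta < 0)
    dominant <- if (n_up >= n_dn) 1 else -1
    frac_dom <- max(n_up, n_dn) / nrow(cl)
    if (frac_dom < consistency) return(NULL)
    lo <- min(cl$pos); hi <- max(cl$pos)
    span <- all_sites[all_sites$chrom == cl$chrom[1] &
                      all_sites$pos >= lo & all_sites$pos <= hi, ,
                      drop = FALSE]
    support <- sign(span$delta) == dominant & abs(span$delta) >= min_delta
    sf <- if (nrow(span)) sum(support) / nrow(span) else 0
    if (sf < consistency) return(NULL)
    data.frame(chrom = cl$chrom[1], start = lo, end = hi + 1L,
               n_dms = nrow(cl), n_cpg = nrow(span),
               direction = if (dominant > 0) "hyper" else "hypo",
               support_fraction = sf, mean_delta = mean(span$delta),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("dmr_result", "data.frame"))
}

#' @export
print.dmr_result <- function(x, ...) {
  cat(sprintf("dmr_result: %d region(s) (%d hyper, %d hypo)\n", nrow(x),
              sum(x$direction == "hyper"), sum(x$direction == "hypo")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Hypergeometric overlap test between two region sets
#'
#' Counts A regions sharing at least 1 bp with any B region and evaluates
#' the upper hypergeometric tail P(X >= n_overlap) with X ~
#' Hypergeometric(universe_size, |A|, |B|): the chance of at least that many
#' shared regions if both sets were drawn independently from a universe of
#' `universe_size` candidate regions.
#'
#' @param set_a,set_b `peak_set` objects (e.g. DMRs from two knockouts).
#' @param universe_size Number of candidate regions in the universe; must be
#'   at least `max(|A|, |B|)`.
#' @return List with `n_overlap` and `p_value`.
#' @export
region_overlap_test <- function(set_a, set_b, universe_size) {
  if (universe_size < nrow(set_a) || universe_size < nrow(set_b))
    stop("universe_size must be at least as large as either set")
  n_overlap <- overlap_peaks(set_a, set_b)$n_a_overlapping
  p <- stats::phyper(n_overlap - 1, nrow(set_b),
                     universe_size - nrow(set_b), nrow(set_a),
                     lower.tail = FALSE)
  list(n_overlap = n_overlap, p_value = p)
}

#' Convert DMR records to a peak set
#'
#' @param dmrs A `dmr_result`.
#' @return A `peak_set` over the DMR intervals.
#' @export
dmrs_as_peaks <- function(dmrs) {
  if (!nrow(dmrs)) return(peak_set())
  peak_set(dmrs$chrom, dmrs$start, dmrs$end,
           sprintf("dmr_%d_%s", seq_len(nrow(dmrs)), dmrs$direction))
}
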