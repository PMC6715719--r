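#' Construct a peak set
#'
#' A peak set is a data frame of genomic intervals in 0-based half-open
#' coordinates (the BED convention used throughout the package) with columns
#' `chrom`, `start`, `end` and optional `name`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start coordinates.
#' @param end Integer vector, 0-based exclusive end coordinates.
#' @param name Optional character vector of interval labels.
#' @param source Optional label for the whole set (e.g. `"EGR1"`).
#' @return A data frame of class `peak_set`.
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     name = NA_character_, source = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) && any(start < 0)) stop("start coordinates must be >= 0")
  if (length(start) && any(end <= start)) stop("intervals require end > start")
  n <- length(start)
  df <- data.frame(chrom = rep_len(as.character(chrom), n), start = start,
                   end = end, name = rep_len(as.character(name), n),
                   stringsAsFactors = FALSE)
  structure(df, class = c("peak_set", "data.frame"), source = source)
}

#' @export
print.peak_set <- function(x, ...) {
  src <- attr(x, "source")
  cat(sprintf("peak_set%s with %d interval(s)\n",
              if (is.null(src)) "" else paste0(" [", src, "]"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Interval centers
#'
#' The center of a half-open interval \[start, end) is `floor((start+end)/2)`,
#' the convention used for peak-to-peak distances.
#'
#' @param peaks A `peak_set` or data frame with `start`/`end` columns.
#' @return Integer vector of center coordinates.
#' @export
interval_centers <- function(peaks) {
  as.integer(floor((peaks$start + peaks$end) / 2))
}

# GRanges bridge: 0-based half-open -> 1-based closed
.as_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

#' Merge overlapping intervals
#'
#' Computes the transitive closure of interval overlap (at least 1 bp shared)
#' and replaces every connected group with its spanning interval. Touching but
#' non-overlapping intervals (end of one equals start of the next) are kept
#' separate. Output is sorted and pairwise disjoint.
#'
#' @param loci A `peak_set` (or compatible data frame).
#' @return A `peak_set` of merged intervals.
#' @export
merge_overlapping_loci <- function(loci) {
  if (nrow(loci) == 0) return(peak_set())
  gr <- GenomicRanges::reduce(.as_granges(loci), min.gapwidth = 0L)
  out <- peak_set(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1L,
                  GenomicRanges::end(gr))
  # GRanges sorts by order of chromosome appearance; fix a lexicographic
  # chromosome order so output is independent of input row order
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep loci near transcription start sites
#'
#' A locus is kept iff it overlaps the window \[t - window, t + window) of at
#' least one TSS `t` on the same chromosome.
#'
#' @param loci A `peak_set`.
#' @param tss Data frame with columns `chrom`, `pos` (0-based TSS positions).
#' @param window Flank size in bp (default 10000).
#' @return The retained subset of `loci` (a `peak_set`).
#' @export
filter_near_tss <- function(loci, tss, window = 10000L) {
  stopifnot(window > 0)
  if (nrow(loci) == 0) return(loci)
  if (nrow(tss) == 0) return(loci[0, , drop = FALSE])
  win <- peak_set(tss$chrom, pmax(0L, tss$pos - as.integer(window)),
                  tss$pos + as.integer(window))
  hits <- GenomicRanges::countOverlaps(.as_granges(loci), .as_granges(win))
  loci[hits > 0, , drop = FALSE]
}

#' Peak-wise overlap accounting between two peak sets
#'
#' A peak "overlaps" iff it shares at least 1 bp with any peak of the other
#' set; counts are peak-wise per set, not pair-wise.
#'
#' @param a,b `peak_set` objects.
#' @return List with `n_a_overlapping`, `n_a_only`, `n_b_overlapping`,
#'   `n_b_only` and `pairs` (data frame of overlapping index pairs).
#' @export
overlap_peaks <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(n_a_overlapping = 0L, n_a_only = nrow(a),
                n_b_overlapping = 0L, n_b_only = nrow(b),
                pairs = data.frame(a_idx = integer(), b_idx = integer())))
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(a), .as_granges(b))
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  list(n_a_overlapping = length(unique(ai)),
       n_a_only = nrow(a) - length(unique(ai)),
       n_b_overlapping = length(unique(bi)),
       n_b_only = nrow(b) - length(unique(bi)),
       pairs = data.frame(a_idx = ai, b_idx = bi))
}

#' Distance to the nearest peak in a reference set
#'
#' For every query peak, the minimum over same-chromosome reference peaks of
#' the absolute difference between peak centers (`floor((start+end)/2)`).
#' Queries on chromosomes absent from the reference get `NA`.
#'
#' @param query,reference `peak_set` objects; `reference` must be non-empty.
#' @return Numeric vector of center distances (bp), one per query peak.
#' @export
nearest_peak_distance <- function(query, reference) {
  if (nrow(reference) == 0) stop("reference peak set is empty")
  qc <- interval_centers(query)
  rc <- interval_centers(reference)
  out <- rep(NA_real_, nrow(query))
  for (ch in unique(query$chrom)) {
    r <- rc[reference$chrom == ch]
    if (!length(r)) next
    qi <- which(query$chrom == ch)
    out[qi] <- vapply(qc[qi], function(c0) min(abs(c0 - r)), numeric(1))
  }
  out
}
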