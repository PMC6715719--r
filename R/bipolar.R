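#' Construct a read pattern set
#'
#' Per-locus matrix of read-level binary methylation calls: one row per read,
#' one column per CpG; `1` = methylated, `0` = unmethylated, `NA` = CpG not
#' covered by the read. Patterns may be supplied as strings over `{1,0,.}`.
#'
#' @param locus_id Locus label.
#' @param chrom,start,end Locus coordinates (0-based half-open).
#' @param patterns Character vector of pattern strings, or `NULL` if `calls`
#'   is given directly.
#' @param calls Integer matrix of calls (reads x CpGs), alternative to
#'   `patterns`.
#' @param cpg_positions Optional 0-based positions of the locus CpGs.
#' @param read_ids Optional read labels.
#' @return List of class `read_pattern_set`.
#' @export
read_pattern_set <- function(locus_id, chrom, start, end, patterns = NULL,
                             calls = NULL, cpg_positions = NULL,
                             read_ids = NULL) {
  if (is.null(calls)) {
    calls <- patterns_to_calls(patterns)
  }
  if (!is.null(cpg_positions) && length(cpg_positions) != ncol(calls))
    stop("cpg_positions length must equal the number of CpG columns")
  structure(list(locus_id = locus_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 calls = calls, cpg_positions = cpg_positions,
                 read_ids = read_ids),
            class = "read_pattern_set")
}

#' @export
print.read_pattern_set <- function(x, ...) {
  cat(sprintf("read_pattern_set %s (%s:%d-%d): %d read(s) x %d CpG(s)\n",
              x$locus_id, x$chrom, x$start, x$end, nrow(x$calls),
              ncol(x$calls)))
  invisible(x)
}

#' Convert pattern strings to a call matrix
#'
#' @param patterns Character vector over the alphabet `{1,0,.}`.
#' @return Integer matrix, reads x CpGs, with `NA` for `.`.
#' @export
patterns_to_calls <- function(patterns) {
  if (!length(patterns)) return(matrix(integer(), 0, 0))
  lens <- nchar(patterns)
  if (length(unique(lens)) != 1) stop("inconsistent pattern lengths")
  chars <- do.call(rbind, strsplit(patterns, "", fixed = TRUE))
  bad <- !(chars %in% c("0", "1", "."))
  if (any(bad)) stop("pattern contains characters outside {1,0,.}")
  m <- matrix(NA_integer_, nrow(chars), ncol(chars))
  m[chars == "1"] <- 1L
  m[chars == "0"] <- 0L
  m
}

#' Convert a call matrix back to pattern strings
#' @param calls Integer matrix with values 0/1/NA.
#' @return Character vector of pattern strings.
#' @export
calls_to_patterns <- function(calls) {
  if (!nrow(calls)) return(character())
  apply(calls, 1, function(r) paste(ifelse(is.na(r), ".",
                                           as.character(r)), collapse = ""))
}

#' Classify a single read's methylation pattern
#'
#' A read is `uninformative` when it covers fewer than `min_informative`
#' CpGs; `full_meth` when its unmethylated calls number at most
#' `max_discordant` and it has at least one methylated call; symmetrically
#' `full_unmeth`; otherwise `mixed`. (A short read that would satisfy both
#' the full_meth and full_unmeth conditions — only possible when the number of
#' covered CpGs is at most `2 * max_discordant` — is classified `mixed`,
#' which keeps the classification symmetric under call inversion.)
#'
#' @param calls Integer vector over 0/1/NA (one read's per-CpG calls).
#' @param min_informative Minimum covered CpGs for an informative read.
#' @param max_discordant Maximum discordant calls tolerated in a "complete"
#'   class (default 0: strictly completely methylated/unmethylated).
#' @return One of `"full_meth"`, `"full_unmeth"`, `"mixed"`,
#'   `"uninformative"`.
#' @export
classify_read <- function(calls, min_informative = 3L, max_discordant = 0L) {
  if (!length(calls)) stop("empty call vector")
  n_meth <- sum(calls == 1L, na.rm = TRUE)
  n_unmeth <- sum(calls == 0L, na.rm = TRUE)
  n_inf <- n_meth + n_unmeth
  if (n_inf < min_informative) return("uninformative")
  fm <- n_unmeth <= max_discordant && n_meth >= 1
  fu <- n_meth <= max_discordant && n_unmeth >= 1
  if (fm && fu) return("mixed")
  if (fm) return("full_meth")
  if (fu) return("full_unmeth")
  "mixed"
}

# vectorized classification over a call matrix -> character vector
.classify_reads <- function(calls, min_informative = 3L, max_discordant = 0L) {
  if (!nrow(calls)) return(character())
  n_meth <- rowSums(calls == 1L, na.rm = TRUE)
  n_unmeth <- rowSums(calls == 0L, na.rm = TRUE)
  n_inf <- n_meth + n_unmeth
  fm <- n_unmeth <= max_discordant & n_meth >= 1
  fu <- n_meth <= max_discordant & n_unmeth >= 1
  cls <- ifelse(fm & !fu, "full_meth",
                ifelse(fu & !fm, "full_unmeth", "mixed"))
  cls[n_inf < min_informative] <- "uninformative"
  cls
}

# Bimodality score: posterior probability of a symmetric two-component
# beta-binomial mixture over per-read methylated fractions versus a single
# flat beta-binomial component, with equal model priors.
# Two-component: 0.5 * BB(Beta(1, shape)) + 0.5 * BB(Beta(shape, 1)).
.bimodality_score <- function(k, m, shape = 9) {
  if (!length(k)) return(NA_real_)
  lbb <- function(k, m, a, b) {
    lchoose(m, k) + lbeta(k + a, m - k + b) - lbeta(a, b)
  }
  l1 <- sum(lbb(k, m, 1, 1))
  lo <- lbb(k, m, 1, shape)
  hi <- lbb(k, m, shape, 1)
  mx <- pmax(lo, hi)
  l2 <- sum(log(0.5) + mx + log(exp(lo - mx) + exp(hi - mx)))
  1 / (1 + exp(l1 - l2))
}

#' Call bipolar methylation at one locus
#'
#' Reads are classified with [classify_read()]; a locus is bipolar iff the
#' number of informative reads reaches `min_coverage` (default 100x) AND the
#' fractions of completely methylated and completely unmethylated reads among
#' informative reads both reach `min_class_fraction`. A bimodality score —
#' the posterior probability of a symmetric two-component beta-binomial
#' mixture over per-read methylated fractions against a single-component
#' model — is reported regardless of the threshold outcome, as a ranking
#' statistic.
#'
#' @param patterns A `read_pattern_set`.
#' @param min_coverage Minimum informative reads (default 100).
#' @param min_class_fraction Minimum fraction per complete class (default
#'   0.2).
#' @param min_informative,max_discordant Passed to [classify_read()].
#' @return One-row data frame with locus coordinates, `n_informative_reads`,
#'   `frac_full_meth`, `frac_full_unmeth`, `bimodality_score`, `is_bipolar`
#'   and `reason` (`NA` when bipolar, else `"coverage"` or
#'   `"class_fraction"`).
#' @export
call_bipolar_locus <- function(patterns, min_coverage = 100L,
                               min_class_fraction = 0.2,
                               min_informative = 3L, max_discordant = 0L) {
  cls <- .classify_reads(patterns$calls, min_informative, max_discordant)
  inf <- cls != "uninformative"
  n_inf <- sum(inf)
  fm <- if (n_inf) sum(cls == "full_meth") / n_inf else NA_real_
  fu <- if (n_inf) sum(cls == "full_unmeth") / n_inf else NA_real_
  k <- rowSums(patterns$calls == 1L, na.rm = TRUE)[inf]
  m <- rowSums(!is.na(patterns$calls))[inf]
  score <- .bimodality_score(k, m)
  if (n_inf < min_coverage) {
    bip <- FALSE; reason <- "coverage"
  } else if (is.na(fm) || fm < min_class_fraction || fu < min_class_fraction) {
    bip <- FALSE; reason <- "class_fraction"
  } else {
    bip <- TRUE; reason <- NA_character_
  }
  data.frame(locus_id = patterns$locus_id, chrom = patterns$chrom,
             start = patterns$start, end = patterns$end,
             n_informative_reads = n_inf,
             frac_full_meth = fm, frac_full_unmeth = fu,
             bimodality_score = score, is_bipolar = bip, reason = reason,
             stringsAsFactors = FALSE)
}

#' Scan many loci for bipolar methylation
#'
#' Pattern sets sharing a `locus_id` (e.g. the same locus observed in several
#' samples) are pooled by concatenating their reads before calling, so
#' coverage accumulates across samples.
#'
#' @param pattern_sets List of `read_pattern_set` objects.
#' @param ... Passed to [call_bipolar_locus()].
#' @return Data frame of class `bipolar_calls`, one row per distinct locus.
#' @export
scan_bipolar <- function(pattern_sets, ...) {
  empty <- data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_informative_reads = integer(),
                      frac_full_meth = numeric(), frac_full_unmeth = numeric(),
                      bimodality_score = numeric(), is_bipolar = logical(),
                      reason = character(), stringsAsFactors = FALSE)
  if (!length(pattern_sets))
    return(structure(empty, class = c("bipolar_calls", "data.frame")))
  ids <- vapply(pattern_sets, `[[`, character(1), "locus_id")
  rows <- lapply(unique(ids), function(id) {
    group <- pattern_sets[ids == id]
    pooled <- group[[1]]
    if (length(group) > 1) {
      ncpg <- vapply(group, function(g) ncol(g$calls), integer(1))
      if (length(unique(ncpg)) != 1)
        stop("cannot pool locus ", id, ": differing CpG counts")
      pooled$calls <- do.call(rbind, lapply(group, `[[`, "calls"))
      pooled$read_ids <- NULL
    }
    call_bipolar_locus(pooled, ...)
  })
  structure(do.call(rbind, rows), class = c("bipolar_calls", "data.frame"))
}

#' @export
print.bipolar_calls <- function(x, ...) {
  cat(sprintf("bipolar scan: %d locus(i), %d bipolar\n",
              nrow(x), sum(x$is_bipolar)))
  invisible(x)
}
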