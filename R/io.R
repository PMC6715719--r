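#' Construct a methylome
#'
#' A methylome holds one sample's CpG counts: per site, the number of
#' methylated calls (`meth`) and of all calls (`total`). Coordinates are
#' 0-based positions of the CpG cytosine on the plus strand. Rows are sorted
#' by (chrom, pos) and positions are unique per chromosome.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based CpG positions.
#' @param meth,total Integer count vectors, `0 <= meth <= total`.
#' @param sample_id Optional sample label.
#' @return A data frame of class `methylome`.
#' @export
methylome <- function(chrom = character(), pos = integer(), meth = integer(),
                      total = integer(), sample_id = NULL) {
  pos <- as.integer(pos); meth <- as.integer(meth); total <- as.integer(total)
  if (length(meth) && any(meth < 0 | total < 0 | meth > total))
    stop("counts must satisfy 0 <= meth <= total")
  df <- data.frame(chrom = as.character(chrom), pos = pos,
                   meth = meth, total = total, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in methylome; sum counts before constructing")
  rownames(df) <- NULL
  structure(df, class = c("methylome", "data.frame"), sample_id = sample_id)
}

#' @export
print.methylome <- function(x, ...) {
  id <- attr(x, "sample_id")
  cat(sprintf("methylome%s: %d CpG site(s)",
              if (is.null(id)) "" else paste0(" [", id, "]"), nrow(x)))
  if (nrow(x)) {
    cov <- x$total
    cat(sprintf(", median coverage %s", stats::median(cov)))
  }
  cat("\n")
  invisible(x)
}

#' Read a BED file of intervals
#'
#' Parses 3+ column tab-separated BED; coordinates are taken as 0-based
#' half-open and input order is preserved. Column 4, when present, becomes the
#' interval name.
#'
#' @param path Path to a BED file.
#' @return A `peak_set`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(peak_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3))
    stop("BED parse error at line ", which(n < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": non-integer coordinate")
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": requires 0 <= start < end")
  name <- ifelse(n >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                character(1)), NA_character_)
  peak_set(chrom, start, end, name)
}

#' Write a peak set as BED
#'
#' Round-trip identity holds: `read_bed(write_bed(x, path))` equals `x`.
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  has_name <- !is.na(peaks$name)
  lines <- ifelse(has_name,
                  paste(peaks$chrom, peaks$start, peaks$end, peaks$name, sep = "\t"),
                  paste(peaks$chrom, peaks$start, peaks$end, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bismark-coverage-style CpG count table
#'
#' Expects 6 tab-separated columns: chrom, start (1-based), end,
#' methylation percentage, methylated count, unmethylated count. Positions are
#' converted to 0-based (`start - 1`); duplicate positions are summed; when
#' the stated percentage disagrees with the counts by more than 0.5
#' percentage points a warning is raised and the counts win.
#'
#' @param path Path to the TSV.
#' @param sample_id Optional sample label for the returned methylome.
#' @return A `methylome`.
#' @export
read_cpg_counts <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "numeric", "integer", "integer"))
  names(raw) <- c("chrom", "start", "end", "pct", "meth", "unmeth")
  if (nrow(raw)) {
    total <- raw$meth + raw$unmeth
    stated <- raw$pct
    implied <- ifelse(total > 0, 100 * raw$meth / total, NA_real_)
    off <- which(!is.na(implied) & abs(implied - stated) > 0.5)
    if (length(off))
      warning(sprintf(
        "%d row(s) with methylation%% inconsistent with counts (first: line %d); counts win",
        length(off), off[1]))
  }
  if (!nrow(raw)) return(methylome(sample_id = sample_id))
  pos <- raw$start - 1L
  key <- paste(raw$chrom, pos)
  agg_m <- rowsum(raw$meth, key, reorder = FALSE)
  agg_u <- rowsum(raw$unmeth, key, reorder = FALSE)
  first <- !duplicated(key)
  k <- key[first]
  methylome(raw$chrom[first], pos[first],
            agg_m[k, 1], agg_m[k, 1] + agg_u[k, 1], sample_id = sample_id)
}

#' Read a read-level methylation pattern table
#'
#' TSV dialect: locus_id, chrom, start, end, read_id, pattern. The pattern is
#' a string over `{1,0,.}` giving per-CpG calls left to right (`.` = CpG not
#' covered by the read). Rows are grouped by locus_id into one
#' `read_pattern_set` each; pattern length must be constant within a locus.
#'
#' @param path Path to the TSV.
#' @return A named list of `read_pattern_set` objects (one per locus).
#' @export
read_read_patterns <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "character", "integer",
                                          "integer", "character", "character"))
  names(raw) <- c("locus_id", "chrom", "start", "end", "read_id", "pattern")
  if (!nrow(raw)) return(list())
  out <- list()
  for (id in unique(raw$locus_id)) {
    rows <- raw[raw$locus_id == id, , drop = FALSE]
    lens <- nchar(rows$pattern)
    if (length(unique(lens)) != 1)
      stop("inconsistent pattern lengths within locus ", id)
    out[[id]] <- read_pattern_set(
      locus_id = id, chrom = rows$chrom[1], start = rows$start[1],
      end = rows$end[1], patterns = rows$pattern, read_ids = rows$read_id)
  }
  out
}

#' Write read-level methylation patterns
#'
#' Inverse of [read_read_patterns()].
#'
#' @param pattern_sets List of `read_pattern_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_patterns <- function(pattern_sets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ps in pattern_sets) {
    pats <- calls_to_patterns(ps$calls)
    ids <- if (!is.null(ps$read_ids)) ps$read_ids
           else sprintf("%s_r%d", ps$locus_id, seq_along(pats))
    if (length(pats))
      writeLines(paste(ps$locus_id, ps$chrom, ps$start, ps$end, ids, pats,
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Collapse symmetric CpG counts onto the plus strand
#'
#' CpG dinucleotides are symmetric: the minus-strand cytosine sits at
#' (plus-strand position + 1). For every supplied pair, counts at both
#' positions are summed onto the plus-strand coordinate; unpaired sites pass
#' through unchanged. Total calls are conserved.
#'
#' @param meth A `methylome`.
#' @param pairs Data frame with columns `chrom`, `plus_pos` (0-based position
#'   of the plus-strand cytosine).
#' @return A `methylome` with minus-strand rows folded in.
#' @export
collapse_strands <- function(meth, pairs) {
  if (!nrow(meth) || !nrow(pairs)) return(meth)
  key <- paste(meth$chrom, meth$pos)
  plus_key <- paste(pairs$chrom, pairs$plus_pos)
  minus_key <- paste(pairs$chrom, pairs$plus_pos + 1L)
  i_minus <- match(minus_key, key)
  take <- which(!is.na(i_minus))
  if (!length(take)) return(meth)
  df <- as.data.frame(meth)
  for (j in take) {
    im <- i_minus[j]
    ip <- match(plus_key[j], key)
    if (is.na(ip)) {
      # no plus-strand row yet: re-coordinate the minus row
      df$pos[im] <- pairs$plus_pos[j]
    } else {
      df$meth[ip] <- df$meth[ip] + df$meth[im]
      df$total[ip] <- df$total[ip] + df$total[im]
      df$meth[im] <- NA_integer_
    }
  }
  keep <- is.na(df$meth) == FALSE
  methylome(df$chrom[keep], df$pos[keep], df$meth[keep], df$total[keep],
            sample_id = attr(meth, "sample_id"))
}

#' Bisulfite conversion rate from an unmethylated spike-in
#'
#' The spike-in genome is fully unmethylated, so every methylated call is a
#' non-conversion event: `conversion_rate = 1 - sum(meth)/sum(total)`.
#'
#' @param spike A `methylome` (or data frame with `meth`/`total`) of spike-in
#'   CpG counts.
#' @return List of class `spikein_summary` with `meth_calls`, `total_calls`
#'   and `conversion_rate`.
#' @export
estimate_bisulfite_conversion <- function(spike) {
  m <- sum(spike$meth)
  t <- sum(spike$total)
  if (t == 0) stop("conversion rate undefined: zero total calls")
  structure(list(meth_calls = m, total_calls = t,
                 conversion_rate = 1 - m / t),
            class = "spikein_summary")
}

#' @export
print.spikein_summary <- function(x, ...) {
  cat(sprintf("spike-in QC: %d / %d methylated calls, conversion rate %.4f\n",
              x$meth_calls, x$total_calls, x$conversion_rate))
  invisible(x)
}
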