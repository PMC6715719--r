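# internal: coverage-weighted level of every peak in one methylome
.region_levels <- function(peaks, meth, min_calls = 10L) {
  out <- rep(NA_real_, nrow(peaks))
  if (!nrow(peaks) || !nrow(meth)) return(out)
  gr_p <- .as_granges(peaks)
  gr_s <- GenomicRanges::GRanges(meth$chrom,
                                 IRanges::IRanges(meth$pos + 1L,
                                                  meth$pos + 1L))
  hits <- GenomicRanges::findOverlaps(gr_p, gr_s)
  pi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(pi)) {
    msum <- rowsum(meth$meth[si], pi)
    tsum <- rowsum(meth$total[si], pi)
    idx <- as.integer(rownames(msum))
    lev <- ifelse(tsum[, 1] >= min_calls, msum[, 1] / tsum[, 1], NA_real_)
    out[idx] <- lev
  }
  out
}

#' Methylation level of a region
#'
#' Coverage-weighted level sum(meth)/sum(total) over the CpGs in
#' \[start, end); `NA` when the region holds fewer than `min_calls` total
#' calls.
#'
#' @param region One-row `peak_set` (or data frame with chrom/start/end).
#' @param meth A `methylome`.
#' @param min_calls Minimum total calls (default 10).
#' @return Methylation level in \[0,1\], or `NA`.
#' @export
region_methylation_level <- function(region, meth, min_calls = 10L) {
  .region_levels(region[1, , drop = FALSE], meth, min_calls)
}

#' Classify a methylation series across stages
#'
#' `constant_hypo` when the maximum level stays at or below
#' `hypo_threshold`; otherwise `dynamic` when the range (max - min) reaches
#' `dynamic_threshold`; otherwise `neither`. Fewer than two non-missing
#' levels give `missing`. Constant hypomethylation takes precedence: a
#' region never exceeding the hypo threshold is constitutively
#' hypomethylated regardless of its micro-range, keeping the two flags
#' mutually exclusive.
#'
#' @param levels Ordered numeric vector of stage methylation levels (`NA`
#'   allowed).
#' @param hypo_threshold Constant-hypomethylation ceiling (default 0.2).
#' @param dynamic_threshold Minimum max-min range for `dynamic`
#'   (default 0.2).
#' @return One of `"constant_hypo"`, `"dynamic"`, `"neither"`, `"missing"`.
#' @export
classify_dynamics <- function(levels, hypo_threshold = 0.2,
                              dynamic_threshold = 0.2) {
  lv <- levels[!is.na(levels)]
  if (length(lv) < 2) return("missing")
  if (max(lv) <= hypo_threshold) return("constant_hypo")
  if (max(lv) - min(lv) >= dynamic_threshold) return("dynamic")
  "neither"
}

#' Directional methylation change between two conditions
#'
#' `decrease` when the level drops from reference to alternative by at least
#' `threshold` (an absolute difference on the 0-1 methylation scale);
#' `increase` symmetrically; else `none`. Missing input gives `missing`.
#'
#' @param level_ref,level_alt Methylation levels.
#' @param threshold Absolute change bar (default 0.2).
#' @return One of `"decrease"`, `"increase"`, `"none"`, `"missing"`.
#' @export
delta_class <- function(level_ref, level_alt, threshold = 0.2) {
  n <- max(length(level_ref), length(level_alt))
  level_ref <- rep_len(level_ref, n)
  level_alt <- rep_len(level_alt, n)
  out <- ifelse(is.na(level_ref) | is.na(level_alt), "missing",
         ifelse(level_ref - level_alt >= threshold, "decrease",
         ifelse(level_alt - level_ref >= threshold, "increase", "none")))
  out
}

#' Per-peak methylation dynamics records
#'
#' Computes each peak's methylation level in every stage methylome,
#' classifies the series ([classify_dynamics()]), and derives the
#' developmental change between a reference/alternative stage pair and,
#' optionally, the cell-type change between two cell-type methylomes
#' ([delta_class()]).
#'
#' @param peaks A `peak_set`.
#' @param stage_methylomes Named list of `methylome` objects in stage order.
#' @param dev_pair Length-2 character vector naming the reference and
#'   alternative stages for the developmental change (default the first and
#'   last stage).
#' @param celltype_methylomes Optional named list of two `methylome`s
#'   (reference first, e.g. glia then neuron).
#' @param min_calls Coverage bar per peak per methylome (default 10).
#' @param hypo_threshold,dynamic_threshold,change_threshold Classification
#'   thresholds (defaults 0.2).
#' @return Data frame of class `dynamics_records`: peak coordinates, one
#'   level column per stage, `class`, `dev_change`, `celltype_change`.
#' @export
peak_dynamics <- function(peaks, stage_methylomes, dev_pair = NULL,
                          celltype_methylomes = NULL, min_calls = 10L,
                          hypo_threshold = 0.2, dynamic_threshold = 0.2,
                          change_threshold = 0.2) {
  stopifnot(length(stage_methylomes) >= 2)
  if (is.null(names(stage_methylomes)))
    names(stage_methylomes) <- paste0("stage", seq_along(stage_methylomes))
  stages <- names(stage_methylomes)
  if (is.null(dev_pair)) dev_pair <- c(stages[1], stages[length(stages)])
  lv <- vapply(stage_methylomes, function(m)
    .region_levels(peaks, m, min_calls), numeric(nrow(peaks)))
  if (nrow(peaks) == 1L) lv <- matrix(lv, 1, dimnames = list(NULL, stages))
  cls <- apply(lv, 1, classify_dynamics, hypo_threshold = hypo_threshold,
               dynamic_threshold = dynamic_threshold)
  dev <- delta_class(lv[, dev_pair[1]], lv[, dev_pair[2]], change_threshold)
  ct <- rep("missing", nrow(peaks))
  if (!is.null(celltype_methylomes)) {
    stopifnot(length(celltype_methylomes) == 2)
    ct_lv <- vapply(celltype_methylomes, function(m)
      .region_levels(peaks, m, min_calls), numeric(nrow(peaks)))
    if (nrow(peaks) == 1L) ct_lv <- matrix(ct_lv, 1)
    ct <- delta_class(ct_lv[, 1], ct_lv[, 2], change_threshold)
  }
  out <- data.frame(chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end, stringsAsFactors = FALSE)
  for (s in stages) out[[s]] <- lv[, s]
  out$class <- cls
  out$dev_change <- dev
  out$celltype_change <- ct
  structure(out, class = c("dynamics_records", "data.frame"),
            stages = stages, dev_pair = dev_pair)
}

#' Summarize methylation-dynamics classifications
#'
#' Counts and percentages per class. Denominators follow the reporting
#' convention for developmental peak methylation: `constant_hypo` and
#' `dynamic` are fractions of all classified peaks; the directional change
#' classes (`dev_decrease`, `dev_increase`, `celltype_decrease`,
#' `celltype_increase`) are fractions of the dynamic peaks. Percentages are
#' reported to one decimal; a zero denominator yields `NA`.
#'
#' @param records A `dynamics_records` data frame (needs columns `class`,
#'   `dev_change`, `celltype_change`).
#' @return Data frame with `class`, `count`, `denominator`, `percentage`.
#' @export
summarize_dynamics <- function(records) {
  if (!nrow(records))
    return(data.frame(class = character(), count = integer(),
                      denominator = integer(), percentage = numeric()))
  n_total <- nrow(records)
  dyn <- records$class == "dynamic"
  n_dyn <- sum(dyn)
  pct <- function(count, denom)
    if (denom > 0) round(100 * count / denom, 1) else NA_real_
  rows <- list(
    c("constant_hypo", sum(records$class == "constant_hypo"), n_total),
    c("dynamic", n_dyn, n_total),
    c("neither", sum(records$class == "neither"), n_total),
    c("dev_decrease", sum(dyn & records$dev_change == "decrease"), n_dyn),
    c("dev_increase", sum(dyn & records$dev_change == "increase"), n_dyn),
    c("celltype_decrease",
      sum(dyn & records$celltype_change == "decrease"), n_dyn),
    c("celltype_increase",
      sum(dyn & records$celltype_change == "increase"), n_dyn))
  out <- data.frame(class = vapply(rows, `[`, character(1), 1),
                    count = as.integer(vapply(rows, `[`, character(1), 2)),
                    denominator = as.integer(vapply(rows, `[`,
                                                    character(1), 3)),
                    stringsAsFactors = FALSE)
  out$percentage <- mapply(pct, out$count, out$denominator)
  out
}

#' Correlation of paired methylation changes
#'
#' Pearson (t-transform p) or Spearman (rank-null p) correlation of two
#' vectors of per-region methylation deltas.
#'
#' @param x,y Numeric vectors of paired deltas (`NA` pairs dropped).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate` and `p_value`.
#' @export
change_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Density of sites around anchor centers
#'
#' Every site contributes one incidence to the bin of its signed offset from
#' every anchor center within the half-window; density is
#' `count / (n_anchors * bin_size)`.
#'
#' @param sites Data frame with `chrom` and `pos` (e.g. DMS coordinates).
#' @param anchors A `peak_set` whose centers anchor the profile.
#' @param half_window Window half-width in bp (default 5000); must be a
#'   multiple of `bin_size`.
#' @param bin_size Bin width in bp (default 100).
#' @return Data frame with `offset_start`, `offset_end`, `count`, `density`;
#'   offsets are signed (site minus anchor center), bins half-open
#'   \[offset_start, offset_end).
#' @export
site_density_profile <- function(sites, anchors, half_window = 5000L,
                                 bin_size = 100L) {
  if (half_window %% bin_size != 0)
    stop("half_window must be divisible by bin_size")
  nbins <- 2L * (half_window %/% bin_size)
  starts <- seq(-half_window, half_window - bin_size, by = bin_size)
  counts <- integer(nbins)
  centers <- interval_centers(anchors)
  for (ch in unique(anchors$chrom)) {
    sp <- sort(sites$pos[sites$chrom == ch])
    if (!length(sp)) next
    for (c0 in centers[anchors$chrom == ch]) {
      lo <- findInterval(c0 - half_window - 0.5, sp) + 1L
      hi <- findInterval(c0 + half_window - 0.5, sp)
      if (hi < lo) next
      off <- sp[lo:hi] - c0
      idx <- (off + half_window) %/% bin_size + 1L
      tab <- tabulate(idx, nbins = nbins)
      counts <- counts + tab
    }
  }
  data.frame(offset_start = starts, offset_end = starts + bin_size,
             count = counts,
             density = counts / (nrow(anchors) * bin_size))
}

#' Enrichment of query sites in a target interval set
#'
#' Builds the 2x2 table (query in/out of target vs background in/out),
#' reports the descriptive odds ratio `(a/b)/(c/d)` and a one-sided binomial
#' p-value P(X >= a) with X ~ Binomial(a + b, c/(c + d)): the query
#' in-target count against the background in-target proportion.
#'
#' @param query_sites,background_sites Data frames with `chrom`, `pos`.
#' @param target A `peak_set`.
#' @return List of class `enrichment_result` with `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`.
#' @export
interval_enrichment <- function(query_sites, target, background_sites) {
  if (!nrow(background_sites)) stop("background must be non-empty")
  in_target <- function(sites) {
    if (!nrow(sites) || !nrow(target)) return(0L)
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1L,
                                                  sites$pos + 1L))
    sum(GenomicRanges::countOverlaps(gr, .as_granges(target)) > 0)
  }
  a <- in_target(query_sites)
  b <- nrow(query_sites) - a
  cc <- in_target(background_sites)
  d <- nrow(background_sites) - cc
  or <- if (a == 0) 0
        else if (b == 0 || cc == 0) Inf
        else if (d == 0) 0
        else (a / b) / (cc / d)
  p0 <- cc / (cc + d)
  p <- stats::pbinom(a - 1, a + b, p0, lower.tail = FALSE)
  structure(list(a = a, b = b, c = cc, d = d, odds_ratio = or, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %d/%d query vs %d/%d background in target; OR = %.3g, binomial p = %.3g\n",
    x$a, x$a + x$b, x$c, x$c + x$d, x$odds_ratio, x$p_value))
  invisible(x)
}
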