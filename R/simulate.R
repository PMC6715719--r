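#' Assemble a simulation scenario from explicit components
#'
#' Low-level constructor for custom designs (e.g. hand-specified
#' developmental trajectories); [build_scenario()] is the parametric
#' front end.
#'
#' @param loci A `peak_set`.
#' @param cpg_positions List of integer vectors (one per locus).
#' @param cell_types Named proportions summing to 1.
#' @param meth_prob Matrix loci x cell types, values in \[0,1\].
#' @param stages Character vector of stage labels.
#' @param trajectories Matrix loci x stages, values in \[0,1\].
#' @param is_neuron_hypo Logical vector flagging neuron-hypomethylated loci.
#' @param seed Integer seed recorded with the scenario.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(loci, cpg_positions, cell_types, meth_prob, stages,
                         trajectories, is_neuron_hypo = NULL, seed = 1L) {
  if (abs(sum(cell_types) - 1) > 1e-9)
    stop("cell-type proportions must sum to 1")
  stopifnot(length(cpg_positions) == nrow(loci),
            nrow(meth_prob) == nrow(loci),
            ncol(meth_prob) == length(cell_types),
            nrow(trajectories) == nrow(loci),
            ncol(trajectories) == length(stages))
  if (length(meth_prob) && any(meth_prob < 0 | meth_prob > 1))
    stop("methylation probabilities must lie in [0,1]")
  if (length(trajectories) && any(trajectories < 0 | trajectories > 1))
    stop("trajectory values must lie in [0,1]")
  if (is.null(is_neuron_hypo)) is_neuron_hypo <- rep(FALSE, nrow(loci))
  colnames(trajectories) <- stages
  structure(list(loci = loci, cpg_positions = cpg_positions,
                 cell_types = cell_types, meth_prob = meth_prob,
                 stages = stages, trajectories = trajectories,
                 is_neuron_hypo = is_neuron_hypo, config = NULL,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Build a simulation scenario
#'
#' Defines the ground truth for synthetic methylomes: a set of loci (each
#' with evenly spaced CpGs), a neural cell-type mixture with per-locus
#' per-cell-type methylation probabilities, and per-locus developmental
#' trajectories. A configurable fraction of loci are "neuron-hypo": strongly
#' hypomethylated in neurons (probability `neuron_hypo_p`, default 0.05) and
#' methylated in glia (`neuron_hypo_glia_p`, default 0.95) — the read-level
#' bipolar signature of a mixed cell population. Control loci draw a single
#' baseline probability shared by all cell types from
#' `baseline_range` (default U(0.1, 0.9)). Neuron-hypo loci follow a
#' logistic developmental decline from `traj_high` to `traj_low`; control
#' loci are flat at their baseline.
#'
#' @param config Named list. Recognised entries (defaults in parentheses):
#'   `n_loci` (100), `n_cpg_per_locus` (4), `cell_types` (named proportions,
#'   `c(neuron = .5, glia = .5)`; must sum to 1), `stages` (E11.5, E14.5, d0,
#'   1wk, 6wk, 22mo), `fraction_neuron_hypo` (0.5), `neuron_hypo_p` (0.05),
#'   `neuron_hypo_glia_p` (0.95), `baseline_range` (c(0.1, 0.9)),
#'   `cpg_spacing` (20 bp), `locus_gap` (10000 bp), `chrom` ("chrS"),
#'   `traj_high` (0.8), `traj_low` (0.1), `seed` (1).
#' @return List of class `sim_scenario` with elements `loci` (a `peak_set`),
#'   `cpg_positions` (list of integer vectors), `cell_types`, `meth_prob`
#'   (loci x cell types), `stages`, `trajectories` (loci x stages),
#'   `is_neuron_hypo`, `seed`.
#' @export
build_scenario <- function(config = list()) {
  def <- list(n_loci = 100L, n_cpg_per_locus = 4L,
              cell_types = c(neuron = 0.5, glia = 0.5),
              stages = c("E11.5", "E14.5", "d0", "1wk", "6wk", "22mo"),
              fraction_neuron_hypo = 0.5, neuron_hypo_p = 0.05,
              neuron_hypo_glia_p = 0.95, baseline_range = c(0.1, 0.9),
              cpg_spacing = 20L, locus_gap = 10000L, chrom = "chrS",
              traj_high = 0.8, traj_low = 0.1, seed = 1L)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  if (abs(sum(cfg$cell_types) - 1) > 1e-9)
    stop("cell-type proportions must sum to 1")
  n <- as.integer(cfg$n_loci)
  ncpg <- as.integer(cfg$n_cpg_per_locus)
  width <- cfg$cpg_spacing * (ncpg + 1L)
  starts <- (seq_len(n) - 1L) * (width + cfg$locus_gap)
  loci <- if (n) peak_set(rep(cfg$chrom, n), starts, starts + width,
                          sprintf("locus_%04d", seq_len(n)))
          else peak_set()
  cpg_positions <- lapply(starts, function(s)
    as.integer(s + cfg$cpg_spacing * seq_len(ncpg)))
  n_hypo <- as.integer(round(cfg$fraction_neuron_hypo * n))
  is_hypo <- seq_len(n) <= n_hypo
  k <- length(cfg$cell_types)
  meth_prob <- matrix(NA_real_, n, k,
                      dimnames = list(loci$name, names(cfg$cell_types)))
  traj <- matrix(NA_real_, n, length(cfg$stages),
                 dimnames = list(loci$name, cfg$stages))
  if (n) {
    baseline <- withr::with_seed(cfg$seed,
      stats::runif(n, cfg$baseline_range[1], cfg$baseline_range[2]))
    for (j in seq_len(k)) meth_prob[, j] <- baseline
    if (n_hypo) {
      meth_prob[is_hypo, ] <- cfg$neuron_hypo_glia_p
      if ("neuron" %in% colnames(meth_prob))
        meth_prob[is_hypo, "neuron"] <- cfg$neuron_hypo_p
    }
    s <- length(cfg$stages)
    t01 <- if (s > 1) (seq_len(s) - 1) / (s - 1) else 0
    logistic <- cfg$traj_low + (cfg$traj_high - cfg$traj_low) /
      (1 + exp(10 * (t01 - 0.5)))
    for (i in seq_len(n)) {
      traj[i, ] <- if (is_hypo[i]) logistic else baseline[i]
    }
  }
  structure(list(loci = loci, cpg_positions = cpg_positions,
                 cell_types = cfg$cell_types, meth_prob = meth_prob,
                 stages = cfg$stages, trajectories = traj,
                 is_neuron_hypo = is_hypo, config = cfg, seed = cfg$seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "sim_scenario: %d loci (%d neuron-hypo), %d cell types, %d stages, seed %d\n",
    nrow(x$loci), sum(x$is_neuron_hypo), length(x$cell_types),
    length(x$stages), x$seed))
  invisible(x)
}

#' Simulate bisulfite reads over a scenario's loci
#'
#' Each read samples a cell type from the mixing proportions and then draws
#' per-CpG Bernoulli calls from that cell type's locus methylation
#' probability. Bisulfite non-conversion flips an unmethylated call to
#' methylated with probability `1 - conversion_rate`; `error_rate` flips any
#' call symmetrically. The aggregated mixture methylome equals the column
#' sums of the read pattern matrices by construction.
#'
#' @param scenario A `sim_scenario`.
#' @param coverage Reads per locus.
#' @param conversion_rate Bisulfite conversion rate in \[0,1\] (default
#'   0.99, the spike-in-estimated rate typical of RRBS libraries).
#' @param error_rate Symmetric per-call error probability (default 0).
#' @param seed Integer seed; the simulation is a pure function of
#'   (scenario, arguments, seed).
#' @return List with `patterns` (list of `read_pattern_set`) and `methylome`
#'   (aggregated mixture `methylome`).
#' @export
simulate_reads <- function(scenario, coverage = 100L, conversion_rate = 0.99,
                           error_rate = 0, seed = 1L) {
  stopifnot(coverage >= 1, conversion_rate >= 0, conversion_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  n <- nrow(scenario$loci)
  withr::with_seed(seed, {
    patterns <- vector("list", n)
    for (i in seq_len(n)) {
      ncpg <- length(scenario$cpg_positions[[i]])
      ct <- sample.int(length(scenario$cell_types), coverage, replace = TRUE,
                       prob = scenario$cell_types)
      p <- scenario$meth_prob[i, ct]
      calls <- matrix(stats::rbinom(coverage * ncpg, 1L, rep(p, ncpg)),
                      nrow = coverage, ncol = ncpg)
      if (conversion_rate < 1) {
        flip <- calls == 0L &
          matrix(stats::runif(coverage * ncpg) < 1 - conversion_rate,
                 coverage, ncpg)
        calls[flip] <- 1L
      }
      if (error_rate > 0) {
        err <- matrix(stats::runif(coverage * ncpg) < error_rate,
                      coverage, ncpg)
        calls[err] <- 1L - calls[err]
      }
      patterns[[i]] <- read_pattern_set(
        locus_id = scenario$loci$name[i], chrom = scenario$loci$chrom[i],
        start = scenario$loci$start[i], end = scenario$loci$end[i],
        calls = calls, cpg_positions = scenario$cpg_positions[[i]])
    }
  })
  chrom <- rep(scenario$loci$chrom, lengths(scenario$cpg_positions))
  pos <- unlist(scenario$cpg_positions)
  meth <- unlist(lapply(patterns, function(ps) colSums(ps$calls == 1L)))
  total <- unlist(lapply(patterns, function(ps) colSums(!is.na(ps$calls))))
  list(patterns = patterns,
       methylome = methylome(chrom, pos, meth, total, sample_id = "mixture"))
}

#' Plant a knockout methylation effect
#'
#' Shifts the methylation probabilities (all cell types) and developmental
#' trajectories of the affected loci by `+delta` (hyper) or `-delta` (hypo),
#' clipped to \[0,1\]. Unaffected loci are returned bit-identical.
#'
#' @param scenario A `sim_scenario`.
#' @param affected Integer indices (or locus names) of affected loci.
#' @param delta Methylation shift in (0,1\] (0 allowed and is a no-op).
#' @param direction `"hyper"` or `"hypo"`.
#' @return The modified `sim_scenario`.
#' @export
apply_ko_effect <- function(scenario, affected, delta,
                            direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  if (is.character(affected))
    affected <- match(affected, scenario$loci$name)
  if (any(is.na(affected)) || any(affected < 1) ||
      any(affected > nrow(scenario$loci)))
    stop("affected loci must be a subset of the scenario's loci")
  s <- delta * if (direction == "hyper") 1 else -1
  scenario$meth_prob[affected, ] <-
    pmin(1, pmax(0, scenario$meth_prob[affected, , drop = FALSE] + s))
  scenario$trajectories[affected, ] <-
    pmin(1, pmax(0, scenario$trajectories[affected, , drop = FALSE] + s))
  scenario$ko_affected <- sort(unique(c(scenario$ko_affected, affected)))
  scenario
}

#' Simulate a pair of ChIP-seq peak sets with controlled overlap
#'
#' `round(n_a * overlap_fraction)` peaks of set A are placed with centers
#' Gaussian-jittered (sd `center_offset_sd`) around distinct set-B centers;
#' all remaining peaks of both sets are placed on disjoint positions. Peak
#' placement uses a slot grid so non-overlap of the independently placed
#' peaks holds by construction.
#'
#' @param n_a,n_b Peak counts for the two sets.
#' @param overlap_fraction Fraction of A peaks constructed to overlap B.
#' @param center_offset_sd Center jitter sd in bp for constructed overlaps.
#' @param genome_span Genome length in bp available for placement.
#' @param seed Integer seed.
#' @param width Peak width in bp (default 400).
#' @return List with `a` and `b` (`peak_set` objects) and
#'   `n_constructed_overlap`.
#' @export
simulate_peak_sets <- function(n_a, n_b, overlap_fraction, center_offset_sd,
                               genome_span, seed = 1L, width = 400L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  n_over <- as.integer(round(n_a * overlap_fraction))
  if (n_over > n_b) stop("n_a * overlap_fraction must not exceed n_b")
  slot <- 4L * width
  n_slots <- genome_span %/% slot
  need <- n_b + (n_a - n_over)
  if (n_slots < need)
    stop("genome_span too small to place peaks disjointly")
  withr::with_seed(seed, {
    slots <- sample.int(n_slots, need) - 1L
    centers_b <- slots[seq_len(n_b)] * slot + slot %/% 2L
    centers_a_free <- if (n_a > n_over)
      slots[n_b + seq_len(n_a - n_over)] * slot + slot %/% 2L else integer()
    partner <- sample.int(n_b, n_over)
    jitter <- if (center_offset_sd > 0)
      as.integer(round(stats::rnorm(n_over, 0, center_offset_sd)))
      else integer(n_over)
    centers_a_over <- centers_b[partner] + jitter
  })
  centers_a <- c(centers_a_over, centers_a_free)
  half <- width %/% 2L
  mk <- function(centers, prefix) {
    if (!length(centers)) return(peak_set(source = prefix))
    peak_set(rep("chr1", length(centers)),
             pmax(0L, as.integer(centers) - half),
             pmax(0L, as.integer(centers) - half) + width,
             sprintf("%s_%d", prefix, seq_along(centers)), source = prefix)
  }
  list(a = mk(centers_a, "A"), b = mk(centers_b, "B"),
       n_constructed_overlap = n_over)
}

#' Simulate an unmethylated spike-in control
#'
#' Every call comes from a fully unmethylated genome, so each is methylated
#' only by bisulfite non-conversion, with probability `1 - conversion_rate`.
#' Calls are spread over sites of ~50 calls each.
#'
#' @param n_calls Total number of calls.
#' @param conversion_rate Conversion rate in \[0,1\].
#' @param seed Integer seed.
#' @return A `methylome` on the synthetic `lambda` chromosome.
#' @export
simulate_spike_in <- function(n_calls, conversion_rate, seed = 1L) {
  stopifnot(n_calls >= 1)
  per_site <- 50L
  n_sites <- ceiling(n_calls / per_site)
  totals <- rep(per_site, n_sites)
  totals[n_sites] <- n_calls - per_site * (n_sites - 1L)
  meth <- withr::with_seed(seed,
    stats::rbinom(n_sites, totals, 1 - conversion_rate))
  methylome(rep("lambda", n_sites), 100L * seq_len(n_sites), meth, totals,
            sample_id = "spike_in")
}

#' Simulate per-stage bulk methylomes from a scenario's trajectories
#'
#' For each developmental stage, every CpG of every locus receives
#' `calls_per_cpg` calls with methylated count Binomial(calls,
#' trajectory value).
#'
#' @param scenario A `sim_scenario`.
#' @param calls_per_cpg Calls per CpG per stage.
#' @param seed Integer seed.
#' @return Named list of `methylome` objects, one per stage, in stage order.
#' @export
simulate_stage_methylomes <- function(scenario, calls_per_cpg = 50L,
                                      seed = 1L) {
  chrom <- rep(scenario$loci$chrom, lengths(scenario$cpg_positions))
  pos <- unlist(scenario$cpg_positions)
  locus_of <- rep(seq_len(nrow(scenario$loci)),
                  lengths(scenario$cpg_positions))
  withr::with_seed(seed, {
    out <- lapply(seq_along(scenario$stages), function(s) {
      p <- scenario$trajectories[locus_of, s]
      meth <- stats::rbinom(length(pos), calls_per_cpg, p)
      methylome(chrom, pos, meth, rep(calls_per_cpg, length(pos)),
                sample_id = scenario$stages[s])
    })
  })
  names(out) <- scenario$stages
  out
}

#' Simulate a bulk (cell-type mixed) methylome from a scenario
#'
#' The bulk methylation probability of a CpG is the mixture
#' `sum(proportion * per-cell-type probability)` of its locus; methylated
#' counts are Binomial(calls, probability).
#'
#' @param scenario A `sim_scenario`.
#' @param calls_per_cpg Calls per CpG.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return A `methylome`.
#' @export
simulate_bulk_methylome <- function(scenario, calls_per_cpg = 30L, seed = 1L,
                                    sample_id = "bulk") {
  chrom <- rep(scenario$loci$chrom, lengths(scenario$cpg_positions))
  pos <- unlist(scenario$cpg_positions)
  locus_of <- rep(seq_len(nrow(scenario$loci)),
                  lengths(scenario$cpg_positions))
  p_bulk <- as.numeric(scenario$meth_prob %*% scenario$cell_types)
  meth <- withr::with_seed(seed,
    stats::rbinom(length(pos), calls_per_cpg, p_bulk[locus_of]))
  methylome(chrom, pos, meth, rep(calls_per_cpg, length(pos)),
            sample_id = sample_id)
}
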