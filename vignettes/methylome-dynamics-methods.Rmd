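---
title: "Statistical methods for brain methylome dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for brain methylome dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdyn)
```

This vignette documents the statistical model behind `methdyn`, the reasoning
for its default parameters, and the scope and limitations of its synthetic-data
generators. The worked example in the README shows the pipelines end to end;
here the focus is on *why* each piece is the way it is.

## The data model

All methylation data reduce to per-CpG count pairs: `meth` methylated calls
out of `total` bisulfite calls, with the methylation level
$\beta = \mathrm{meth}/\mathrm{total} \in [0, 1]$. Coordinates are 0-based
internally; `read_cpg_counts()` converts from the 1-based coverage-file
convention on input, and intervals follow the 0-based half-open BED
convention throughout. Counts, never precomputed percentages, are the source
of truth: when a file's percentage column disagrees with its counts, the
counts win (with a warning), because every downstream test consumes counts.

Two assumptions run through the package:

1. **Binomial sampling.** Conditional on a site's true methylation
   probability, calls are independent Bernoulli draws. This ignores overlapping
   read pairs and local haplotype structure; it is the standard working model
   for coverage-level bisulfite statistics.
2. **Mixture structure.** Bulk neural tissue is a mixture of cell types with
   potentially different methylation states at the same locus. Read-level
   patterns, not site-level averages, carry the mixture signal — a locus at
   bulk $\beta = 0.5$ may be half-methylated in every cell or fully methylated
   in half the cells, and only the reads distinguish the two.

## Bipolar methylated loci

A read covering $k$ CpGs is classified from its non-missing calls:
`full_meth` if at most `max_discordant` (default 0) calls are unmethylated,
`full_unmeth` symmetrically, `mixed` otherwise, and `uninformative` below
`min_informative = 3` usable calls. Three calls is the minimum at which
"completely methylated" is materially different from "mostly methylated";
shorter reads are too easy to classify by chance.

A locus is **bipolar** when, after pooling reads across samples:

* informative coverage is at least `min_coverage = 100` reads — the scale at
  which a 20% minority class still yields ~20 reads, enough that complete
  classes cannot arise from a handful of stray molecules;
* both complete classes hold at least `min_class_fraction = 0.2` of
  informative reads — below that, non-conversion artifacts and rare cell
  states masquerade as bipolarity.

The continuous `bimodality_score` complements the hard call: it compares the
marginal likelihood of the full-methylation read-class counts under a
balanced two-component beta-binomial mixture
($\tfrac12\mathrm{BB}(1,9) + \tfrac12\mathrm{BB}(9,1)$) against a flat
$\mathrm{BB}(1,1)$ single component, mapped through a logistic. The score
deliberately ignores the class-fraction filter, so it ranks evidence for
*any* two-state structure; the filter then decides whether the minority state
is abundant enough to call. The shape parameter 9 encodes "a complete class
sits near 0 or 1"; the score is used for ranking, not testing, so its exact
value matters less than its monotonicity in class balance and coverage.

## Differential methylation

### Site test

Each shared CpG with at least `min_coverage = 10` calls in both samples is
tested with the two-sided Fisher exact test on the
(meth, unmeth) × (sample A, sample B) table. Ten calls per sample is the
floor below which the exact test has essentially no power at effect sizes of
interest and $\beta$ estimates are dominated by sampling noise.

### Sequential permutation p-value

The permutation p-value for a site conditions on the pooled methylated-call
margin and redraws sample A's share — a hypergeometric draw, which is
distributionally identical to re-splitting the pooled calls. The loop is
*sequential*: it stops as soon as $r = 10$ permutation statistics at least as
extreme as the observed one have occurred, returning $\hat p = r/b$ after $b$
draws, and otherwise returns $(e + 1)/(B + 1)$ after the full $B = 1000$
draws with $e$ exceedances. Early stopping spends permutations where they
matter — small p-values — and makes genome-scale permutation affordable.

The price is granularity. The estimator's support is
$\{r/b : b \ge r\} \cup \{(e+1)/(B+1)\}$, and under a true null the stopping
rule concentrates mass at large values; in particular $\hat p = 1$ (stopping
at $b = r$) occurs with probability $E[p^r]$, about $1/(r+1)$ when the
underlying p-value is uniform. Combined with the discreteness of the exact
test itself, the null distribution of $\hat p$ is *super-uniform*
(stochastically larger than uniform) rather than uniform: valid — it never
anti-conservatively inflates significance — but visibly non-uniform to a
one-sample Kolmogorov–Smirnov comparison, which measures deviation in both
directions and therefore sits near $1/(r+1)$ regardless of sample size. The
test suite asserts super-uniformity directly and reports the KS statistic as
a descriptive calibration number.

### Estimating the number of true nulls

Multiple testing uses the step-up adjustment with the Benjamini–Hochberg
denominator $m$ replaced by an estimate $m_0$ of the number of true null
hypotheses: sorted p-values are compared against $\alpha\,i\,/\,m_0$ rather
than $\alpha\,i\,/\,m$. $m_0$ comes from a histogram recursion: p-values are
binned into `bins = 20` equal-width bins; starting from the left, a bin
*conforms* when its count does not exceed the average count of it and all
bins to its right; $m_0$ is `bins/(bins - first conforming bin + 1)` times the
count from that bin rightward, iterated to a fixed point (capped at 100
iterations, clipped to $[0, m]$). The idea: true nulls are uniform, so the
right tail of the histogram estimates the null density; signal piles up near
zero and is excluded by the conforming-bin rule. With $m_0 < m$ the
adjustment recovers power that plain BH leaves on the table, which is exactly
where its practical benefit shows up in the planted-effect suites. Twenty
bins balances tail-count stability against resolution of the signal spike;
the estimator is insensitive to this choice for the problem sizes here.

### From sites to regions

DMSs (adjusted $p \le 0.05$, the conventional FDR level) become DMRs in two
steps. First, DMSs on the same chromosome chain together while consecutive
gaps are at most 500 bp — about the scale over which neighbouring CpGs share
methylation state — and a chain survives with at least 5 DMSs of which at
least 80% agree in direction. Second, the chain's span is re-examined against
*all* covered CpGs, significant or not: at least 80% must change in the
dominant direction by at least $|\Delta\beta| = 0.1$. The second step is the
substantive one — it rejects chains of scattered significant sites riding on
an inconsistent background, which is the common failure mode of
clustering-only DMR callers.

## Peak-set integration

`peak_dynamics()` classifies each peak from its coverage-weighted per-stage
$\beta$ (at least `min_calls = 10` calls per region per stage):
`constant_hypo` when no stage exceeds 0.2, `dynamic` when the stage range is
at least 0.2, `neither` otherwise — `constant_hypo` takes precedence so the
classes partition the peaks. Directional change classes between a stage pair
or a cell-type pair use the same absolute 0.2 threshold on the 0-to-1
$\beta$ scale. Summaries report class percentages over all classified peaks
and directional percentages over the *dynamic* peaks, the two denominators a
reader of such tables expects.

Overlap accounting is peak-wise with a 1-bp overlap rule;
`region_overlap_test()` gives the hypergeometric tail probability of the
observed overlap count given a universe of candidate regions, and
`interval_enrichment()` the one-sided binomial tail of the query's in-target
count against the background proportion, with the 2×2 odds ratio reported
descriptively. Nearest-peak distances are center-to-center and intentionally
asymmetric in query and reference; density profiles bin signed center offsets
and normalize by (number of anchors × bin width), so a flat profile has a
direct interpretation as sites per base pair per anchor.

## Synthetic generators: scope and limits

The generators exist so that every statistical claim in the package can be
exercised against planted truth, offline and in seconds. They are emulators,
not sequence simulators:

* `build_scenario()` / `sim_scenario()` define loci, a cell-type mixture,
  per-cell-type methylation probabilities and per-stage trajectories. The
  parametric front end plants "neuron-hypo" loci (neuron probability 0.05,
  glia 0.95 by default — strong but not degenerate mixture signal) and a
  logistic developmental decline between `traj_high = 0.8` and
  `traj_low = 0.1`.
* `simulate_reads()` draws each read's cell type from the mixture and its
  calls as Bernoullis, then applies *asymmetric* non-conversion noise
  (unmethylated calls flip to methylated with probability
  1 − `conversion_rate`), matching the direction of the real artifact. The
  aggregate methylome equals the column sums of the read patterns by
  construction, which the tests assert.
* `simulate_peak_sets()` places peaks on a slot grid with a constructed
  number of overlapping pairs, so overlap percentages are exact by design.
* `simulate_spike_in()` yields a fully unmethylated control genome for
  conversion-rate recovery.

Everything is a pure function of its arguments and a seed
(`withr::with_seed`), so results are reproducible across sessions without
touching the global RNG state. What the generators do **not** model:
read-length variation and positional biases, correlated non-conversion along
a molecule, copy-number or mapping artifacts, and spatial autocorrelation of
$\beta$ beyond the planted locus structure. Conclusions about those effects
cannot be drawn from these simulations.

Problem sizes in the test suite and in `scripts/acceptance.R` (hundreds of
loci, thousands of peaks, coverage 30–100) were chosen to finish in seconds
while keeping Monte-Carlo standard errors well below the effect sizes being
asserted; they are not claims about real-data scale, which the algorithms
handle by virtue of being linear or near-linear in the number of sites.

## Numerical choices

* Two-sided Fisher p-values sum the probabilities of all tables with point
  probability at most $(1 + 10^{-7})$ times the observed one — the same tie
  tolerance as `stats::fisher.test`, so site p-values agree with it exactly.
* The permutation machinery precomputes the p-value over the full
  hypergeometric support of a site's margins once, then evaluates draws by
  table lookup.
* Adjusted p-values are computed by the usual step-up cumulative-minimum
  recursion, clipped to 1; $m_0 = 0$ maps everything to 0 (all discoveries),
  and $m_0 = m$ reproduces `p.adjust(..., "BH")` exactly, both asserted in
  the tests.
* Region levels pool counts before dividing (coverage-weighted $\beta$)
  rather than averaging site-level $\beta$ values, so low-coverage CpGs do
  not get outsized influence; the `min_calls` floor governs missingness.

## Limitations

The package tests two-sample site contrasts only — no replicates, no
covariates, no beta-binomial overdispersion; with biological replicates a
regression framework is the right tool. The bipolar caller needs unusual
depth (100×), which restricts it to targeted or downsampled designs. The m0
histogram estimator assumes the p-value distribution is a mixture of uniform
nulls and a left-concentrated alternative; heavy discreteness at small $m$
can make it conservative. DMR boundaries inherit the resolution of the
covered CpGs — the reported span runs from the first to the last member DMS
and should not be read as a base-pair-accurate regulatory element boundary.
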