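test_that("region methylation levels are coverage-weighted with a 10-call floor", {
  m <- methylome(rep("chr1", 3), c(10, 20, 500), c(3, 7, 9), c(10, 10, 9))
  reg <- peak_set("chr1", 0, 100)
  expect_equal(region_methylation_level(reg, m), 0.5)
  expect_true(is.na(region_methylation_level(peak_set("chr1", 400, 600), m)))
  expect_true(is.na(region_methylation_level(peak_set("chr1", 900, 950), m)))
  expect_equal(region_methylation_level(reg, m, min_calls = 5), 0.5)
})

test_that("dynamics classification separates constant-hypo, dynamic and neither", {
  expect_equal(classify_dynamics(c(0.05, 0.10, 0.18)), "constant_hypo")
  expect_equal(classify_dynamics(c(0.8, 0.5, 0.2)), "dynamic")
  expect_equal(classify_dynamics(c(0.25, 0.30, 0.35)), "neither")
  expect_equal(classify_dynamics(c(0.3, NA)), "missing")
  # constant-hypo precedence keeps the flags mutually exclusive
  expect_equal(classify_dynamics(c(0.0, 0.2)), "constant_hypo")
  # NA levels are ignored, not propagated
  expect_equal(classify_dynamics(c(NA, 0.8, 0.5, 0.2)), "dynamic")
})

test_that("delta classes use an absolute 0.2 change on the 0-1 scale", {
  expect_equal(delta_class(0.6, 0.3), "decrease")
  expect_equal(delta_class(0.3, 0.6), "increase")
  expect_equal(delta_class(0.5, 0.4), "none")
  expect_equal(delta_class(NA, 0.4), "missing")
  expect_equal(delta_class(c(0.6, 0.3), c(0.3, 0.6)),
               c("decrease", "increase"))
})

test_that("dynamics summaries use the documented denominators", {
  # counts mirroring a developmental peak-methylation survey:
  # 12014 peaks, 6127 constant hypo, 4125 dynamic of which 2106 decrease
  # and 111 increase development-wise, 3451 decrease cell-type-wise
  n <- 12014
  class <- rep("neither", n)
  class[1:6127] <- "constant_hypo"
  class[6128:(6127 + 4125)] <- "dynamic"
  dev <- rep("none", n)
  dev[6128:(6127 + 2106)] <- "decrease"
  dev[(6127 + 2107):(6127 + 2106 + 111)] <- "increase"
  ct <- rep("none", n)
  ct[6128:(6127 + 3451)] <- "decrease"
  rec <- data.frame(class = class, dev_change = dev, celltype_change = ct,
                    stringsAsFactors = FALSE)
  sm <- summarize_dynamics(rec)
  g <- function(cl, col) sm[[col]][sm$class == cl]
  expect_equal(g("constant_hypo", "percentage"), 51.0)
  expect_equal(g("dynamic", "percentage"), 34.3)
  expect_equal(g("dev_decrease", "percentage"), 51.1)
  expect_equal(g("dev_increase", "percentage"), 2.7)
  expect_equal(g("celltype_decrease", "percentage"), 83.7)
  expect_equal(g("dev_decrease", "denominator"), 4125L)
  # counts are conserved across classes
  expect_equal(sum(sm$count[sm$class %in%
                            c("constant_hypo", "dynamic", "neither")]), n)
  # zero denominator: percentage undefined
  rec0 <- data.frame(class = "constant_hypo", dev_change = "none",
                     celltype_change = "none")
  sm0 <- summarize_dynamics(rec0)
  expect_true(is.na(sm0$percentage[sm0$class == "dev_decrease"]))
  expect_equal(nrow(summarize_dynamics(rec0[0, ])), 0L)
})

test_that("end-to-end dynamics pipeline classifies planted trajectories", {
  # 100 peaks, all dynamic by construction: 40% lose >= 0.2 beta d0 -> 6wk
  stages <- c("d0", "1wk", "6wk")
  n <- 100; n_dec <- 40
  loci <- peak_set(rep("chr1", n), (0:(n - 1)) * 10000,
                   (0:(n - 1)) * 10000 + 400)
  cpg <- lapply(loci$start, function(s) as.integer(s + 50 * 1:5))
  traj <- rbind(
    matrix(rep(c(0.65, 0.45, 0.25), each = n_dec), n_dec),
    matrix(rep(c(0.25, 0.45, 0.65), each = n - n_dec), n - n_dec))
  sc <- sim_scenario(loci, cpg, c(neuron = 0.5, glia = 0.5),
                     matrix(0.5, n, 2), stages, traj)
  sm <- simulate_stage_methylomes(sc, calls_per_cpg = 10, seed = 61)
  rec <- peak_dynamics(loci, sm, dev_pair = c("d0", "6wk"))
  tab <- summarize_dynamics(rec)
  pct_dec <- tab$percentage[tab$class == "dev_decrease"]
  expect_lt(abs(pct_dec - 40), 3)
  expect_gt(tab$percentage[tab$class == "dynamic"], 90)
})

test_that("change correlations match the covariance formula", {
  expect_equal(change_correlation(1:3, c(2, 4, 6))$estimate, 1.0)
  expect_equal(change_correlation(1:3, c(3, 2, 1))$estimate, -1.0)
  withr::with_seed(62, {
    x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  })
  got <- change_correlation(x, y)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$estimate, oracle, tolerance = 1e-12)
  expect_equal(got$p_value, cor.test(x, y)$p.value)
  sp <- change_correlation(x, y, method = "spearman")
  expect_equal(sp$estimate, cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_error(change_correlation(1:2, 2:3), ">= 3")
  expect_error(change_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("peak overlap accounting is peak-wise and matches brute force", {
  a <- peak_set(c("c", "c"), c(0, 200), c(100, 300))
  b <- peak_set("c", 50, 150)
  ov <- overlap_peaks(a, b)
  expect_equal(ov$n_a_overlapping, 1L)
  expect_equal(ov$n_a_only, 1L)
  expect_equal(ov$n_b_only, 0L)
  same <- overlap_peaks(a, a)
  expect_equal(same$n_a_overlapping, 2L)
  withr::with_seed(63, {
    x <- rand_peaks(80)
    y <- rand_peaks(60)
  })
  got <- overlap_peaks(x, y)
  bf <- vapply(seq_len(nrow(x)), function(i)
    any(y$chrom == x$chrom[i] & x$start[i] < y$end & x$end[i] > y$start),
    logical(1))
  expect_equal(got$n_a_overlapping, sum(bf))
  expect_equal(got$n_a_overlapping + got$n_a_only, nrow(x))
})

test_that("nearest-peak distances are center-based, asymmetric, brute-force exact", {
  q <- peak_set("c", 100, 200)          # center 150
  r <- peak_set(c("c", "c"), c(50, 350), c(150, 450))  # centers 100, 400
  expect_equal(nearest_peak_distance(q, r), 50)
  expect_equal(nearest_peak_distance(r[1, ], r[1, ]), 0)
  # asymmetry counter-example
  expect_false(isTRUE(all.equal(
    sort(nearest_peak_distance(r, q)), sort(nearest_peak_distance(q, r)))))
  # chromosome absent from reference
  expect_true(is.na(nearest_peak_distance(peak_set("chrZ", 0, 10), r)))
  withr::with_seed(64, {
    qq <- rand_peaks(50)
    rr <- rand_peaks(40)
  })
  got <- nearest_peak_distance(qq, rr)
  qc <- interval_centers(qq); rc <- interval_centers(rr)
  bf <- vapply(seq_len(nrow(qq)), function(i) {
    d <- abs(qc[i] - rc[rr$chrom == qq$chrom[i]])
    if (length(d)) min(d) else NA_real_
  }, numeric(1))
  expect_equal(got, bf)
  expect_true(all(got[!is.na(got)] >= 0))
})

test_that("site density profiles concentrate mass correctly", {
  anchors <- peak_set(rep("c", 3), c(1000, 5000, 9000) - 200,
                      c(1000, 5000, 9000) + 200)
  centered <- data.frame(chrom = "c", pos = interval_centers(anchors))
  prof <- site_density_profile(centered, anchors, half_window = 1000,
                               bin_size = 100)
  central <- prof$offset_start == 0
  expect_equal(prof$count[central], 3L)
  expect_equal(sum(prof$count[!central]), 0L)
  expect_equal(sum(prof$density) * 100 * 3, 3)  # mass bookkeeping
  # no sites in window: zero vector
  far <- data.frame(chrom = "c", pos = 20000L)
  expect_true(all(site_density_profile(far, anchors, 1000, 100)$count == 0))
  expect_error(site_density_profile(far, anchors, 1000, 300), "divisible")
  # uniform sites give a flat profile within Monte-Carlo error
  withr::with_seed(65, {
    sites <- data.frame(chrom = "c", pos = sample.int(2e6, 40000))
    anc <- peak_set(rep("c", 30), seq(1e5, 1.9e6, length.out = 30),
                    seq(1e5, 1.9e6, length.out = 30) + 400)
  })
  p2 <- site_density_profile(sites, anc, half_window = 5000, bin_size = 500)
  lambda <- mean(p2$count)
  expect_true(all(abs(p2$count - lambda) <= 3 * sqrt(lambda) + 3))
})

test_that("interval enrichment matches the exact binomial tail", {
  target <- peak_set("c", 1000, 2000)
  inside <- function(n) data.frame(chrom = "c",
                                   pos = as.integer(seq(1000, 1999,
                                                        length.out = n)))
  outside <- function(n) data.frame(chrom = "c",
                                    pos = as.integer(seq(5000, 9999,
                                                         length.out = n)))
  # equal proportions: OR = 1
  q <- rbind(inside(10), outside(90))
  bg <- rbind(inside(30), outside(270))
  r <- interval_enrichment(q, target, bg)
  expect_equal(r$odds_ratio, 1.0)
  expect_equal(r$p_value, bf_binom_tail(10, 100, 0.1), tolerance = 1e-12)
  # a = 30 of 100 query, background proportion 0.1
  q2 <- rbind(inside(30), outside(70))
  r2 <- interval_enrichment(q2, target, bg)
  expect_equal(r2$a, 30L)
  expect_equal(r2$p_value, bf_binom_tail(30, 100, 0.1), tolerance = 1e-12)
  expect_gt(r2$odds_ratio, 1)
  # no query hits: OR 0, p 1
  r0 <- interval_enrichment(outside(20), target, bg)
  expect_equal(r0$odds_ratio, 0)
  expect_equal(r0$p_value, 1.0)
  expect_error(interval_enrichment(q, target, bg[0, ]), "non-empty")
})
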