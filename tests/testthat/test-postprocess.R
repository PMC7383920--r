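test_that("replicate consolidation picks the top-PVE overlapping record", {
  # identical QTL in all three replicates -> one record, support 3
  reps <- lapply(1:3, function(i) qtl_table(make_rec(pve = 10 + i)))
  out <- consolidate_replicates(reps, min_support = 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$PVE, 13)
  expect_equal(out$n_replicates_detected, 3L)

  # a QTL seen in one replicate only is dropped at min_support 2
  reps1 <- list(qtl_table(make_rec()), qtl_table(NULL), qtl_table(NULL))
  expect_equal(nrow(consolidate_replicates(reps1, 2)), 0)
  expect_equal(nrow(consolidate_replicates(reps1, 1)), 1)

  # peaks at 48/50/53 with overlapping extended intervals,
  # PVEs 12/18/15 -> single record carrying PVE 18
  reps3 <- list(qtl_table(make_rec(peak = 48, lo = 43, hi = 53, pve = 12)),
                qtl_table(make_rec(peak = 50, lo = 45, hi = 55, pve = 18)),
                qtl_table(make_rec(peak = 53, lo = 48, hi = 58, pve = 15)))
  out3 <- consolidate_replicates(reps3)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$PVE, 18)
  expect_equal(out3$peak_cM, 50)
})

test_that("consolidation separates non-overlapping loci and odd traits", {
  reps <- list(
    qtl_table(rbind(make_rec(peak = 20, lo = 15, hi = 25),
                    make_rec(peak = 100, lo = 95, hi = 105))),
    qtl_table(rbind(make_rec(peak = 22, lo = 17, hi = 27, pve = 25),
                    make_rec(peak = 101, lo = 96, hi = 106, pve = 8))))
  out <- consolidate_replicates(reps)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$PVE), c(20, 25))
  expect_true(all(out$n_replicates_detected == 2))
  # output never exceeds input count
  expect_lte(nrow(out), 4)
  # replicate lists that are single but different traits are a mix-up
  mix <- list(qtl_table(make_rec(trait = "m1")),
              qtl_table(make_rec(trait = "m2")))
  expect_error(consolidate_replicates(mix), "different traits")
})

test_that("chromosome distribution test matches its hand-computed case", {
  map <- simulate_map(2, 100, 10)
  recs <- qtl_table(do.call(rbind, c(
    lapply(1:30, function(i) make_rec(trait = paste0("t", i), chrom = "chr1")),
    lapply(1:10, function(i) make_rec(trait = paste0("u", i), chrom = "chr2")))))
  res <- chromosome_distribution_test(recs, map)
  # equal lengths -> expected (20, 20); chi2 = 100/20 + 100/20 = 10
  expect_equal(res$chi2, 10, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(10, 1, lower.tail = FALSE))
  # observed exactly proportional to lengths -> chi2 = 0
  map3 <- simulate_map(2, c(100, 50), 10)
  recs3 <- qtl_table(do.call(rbind, c(
    lapply(1:20, function(i) make_rec(trait = paste0("t", i), chrom = "chr1")),
    lapply(1:10, function(i) make_rec(trait = paste0("u", i), chrom = "chr2")))))
  expect_equal(chromosome_distribution_test(recs3, map3)$chi2, 0,
               tolerance = 1e-12)
})

test_that("chromosome test rejects at nominal rate for uniform placement", {
  map <- simulate_map(5, 100, 20)
  set.seed(17)
  rej <- vapply(1:300, function(i) {
    chrom <- sample(paste0("chr", 1:5), 50, replace = TRUE)
    recs <- qtl_table(do.call(rbind, lapply(seq_along(chrom), function(j)
      make_rec(trait = paste0("t", j), chrom = chrom[j]))))
    chromosome_distribution_test(recs, map)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 300) + 0.015)
})

test_that("genome bins tile chromosomes without overlap", {
  map <- simulate_map(2, c(95, 40), 5)
  bins <- genome_bins(map, 10)
  expect_equal(sum(bins$end_cM - bins$start_cM),
               sum(chrom_lengths(map)))
  b1 <- bins[bins$chromosome == "chr1", ]
  expect_equal(b1$start_cM, seq(0, 90, by = 10))
  expect_equal(max(b1$end_cM), 95)   # last bin truncated
})

test_that("hotspot cutoff follows the multinomial maximum quantile", {
  # a single QTL can only ever give a maximum of 1
  expect_equal(as.integer(hotspot_cutoff(1, 50, 200, 0.01, seed = 1)), 1L)
  # with one bin the 'permutation' is a point mass at n_qtl
  expect_equal(as.integer(hotspot_cutoff(5, 1, 100, 0.5, seed = 1)), 5L)
  # monotone in n_qtl, antitone in B
  c1 <- hotspot_cutoff(100, 50, 400, 0.05, seed = 3)
  c2 <- hotspot_cutoff(400, 50, 400, 0.05, seed = 3)
  c3 <- hotspot_cutoff(100, 200, 400, 0.05, seed = 3)
  expect_lte(as.integer(c1), as.integer(c2))
  expect_gte(as.integer(c1), as.integer(c3))
  # independence (binomial) approximation to the multinomial maximum:
  # cutoff c is the smallest c with P(max <= c) >= 1 - alpha
  n <- 300; B <- 60; alpha <- 0.05
  pmax_le <- function(c) pbinom(c, n, 1 / B)^B
  oracle <- which(vapply(0:50, pmax_le, numeric(1)) >= 1 - alpha)[1] - 1L
  got <- as.integer(hotspot_cutoff(n, B, 1000, alpha, seed = 9))
  expect_lte(abs(got - oracle), 1)
})

test_that("hotspot calling assigns peaks to half-open bins", {
  map <- simulate_map(1, 50, 10)
  peaks <- c(0, 9.9, 10, 19.9, 50)   # boundary at 10 goes right; end stays
  recs <- qtl_table(do.call(rbind, lapply(seq_along(peaks), function(i)
    make_rec(trait = paste0("t", i), peak = peaks[i],
             lo = max(peaks[i] - 2, 0), hi = min(peaks[i] + 2, 50)))))
  hot <- call_hotspots(recs, map, 10, cutoff = 0)
  all_bins <- attr(hot, "all_bins")
  expect_equal(sum(all_bins$count), length(peaks))   # conservation
  expect_equal(all_bins$count[all_bins$bin_index == 1], 2)  # 0, 9.9
  expect_equal(all_bins$count[all_bins$bin_index == 2], 2)  # 10, 19.9
  expect_equal(all_bins$count[all_bins$bin_index == 5], 1)  # chromosome end
  # cutoff filter and ordering
  hot2 <- call_hotspots(recs, map, 10, cutoff = 1)
  expect_true(all(hot2$count > 1))
  expect_equal(hot2$count, sort(hot2$count, decreasing = TRUE))
  # a peak beyond the chromosome end is a map mismatch
  bad <- qtl_table(make_rec(peak = 60, lo = 58, hi = 60))
  expect_error(call_hotspots(bad, map, 10, 0), "beyond chromosome end")
})

test_that("colocalization uses closed-interval overlap on one chromosome", {
  m <- qtl_table(make_rec(trait = "met1", lo = 10, hi = 20, peak = 15))
  p_touch <- qtl_table(make_rec(trait = "agroA", lo = 20, hi = 30, peak = 25))
  p_far <- qtl_table(make_rec(trait = "agroB", lo = 30, hi = 40, peak = 35))
  p_other <- qtl_table(make_rec(trait = "agroC", chrom = "chr9",
                                lo = 10, hi = 20, peak = 15))
  pairs <- colocalize(m, qtl_table(rbind(p_touch, p_far, p_other)))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$trait_id, "agroA")
  expect_equal(pairs$overlap_lo_cM, 20)
  expect_equal(pairs$overlap_hi_cM, 20)
  expect_equal(nrow(colocalize(m, p_far)), 0)
  expect_equal(nrow(colocalize(qtl_table(NULL), p_far)), 0)
})

test_that("cross-referencing flags pairs with significant correlations", {
  pairs <- colocalize(
    qtl_table(make_rec(trait = "met1", peak = 15, lo = 10, hi = 20)),
    qtl_table(make_rec(trait = "agroA", peak = 20, lo = 15, hi = 25)))
  # no edges -> all uncorrelated
  out0 <- cross_reference(pairs, NULL)
  expect_false(any(out0$correlated))
  edges <- data.frame(trait_a = "agroA", trait_b = "met1",
                      r = 0.5, p_value = 1e-4)
  out <- cross_reference(pairs, edges, p_threshold = 0.01)
  expect_true(all(out$correlated))
  expect_equal(out$r, 0.5)
  weak <- data.frame(trait_a = "met1", trait_b = "agroA",
                     r = 0.2, p_value = 0.2)
  expect_false(any(cross_reference(pairs, weak)$correlated))
})
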