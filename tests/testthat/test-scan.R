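test_that("interval-mapping LOD matches the least-squares worked example", {
  # x = (1,1,-1,-1), y = (1,0,0,-1): RSS0 = 2, RSS1 = 1,
  # LOD = (4/2) log10(2)
  m1 <- simulate_map(1, 10, 10)
  g4 <- matrix(rep(c(1, 1, -1, -1), 2), 4, 2,
               dimnames = list(paste0("L", 1:4), m1$marker))
  prof <- icim_scan(g4, m1, stats::setNames(c(1, 0, 0, -1), paste0("L", 1:4)),
                    step = 10)
  expect_equal(prof$lod[1], 2 * log10(2), tolerance = 1e-12)
  expect_equal(prof$additive_effect[1], 0.5, tolerance = 1e-12)
})

test_that("scan LOD at typed markers equals single-marker regression LOD", {
  toy <- toy_single_qtl(n_lines = 80, seed = 4)
  prof <- icim_scan(toy$geno, toy$map, toy$y, step = 1)
  at_marker <- which(prof$positions$pos_cM %in% toy$map$pos_cM)
  for (i in at_marker[seq(1, length(at_marker), by = 5)]) {
    x <- toy$geno[, match(prof$positions$pos_cM[i], toy$map$pos_cM)]
    rss0 <- sum((toy$y - mean(toy$y))^2)
    rss1 <- sum(stats::lm(toy$y ~ x)$residuals^2)
    expect_equal(prof$lod[i], (80 / 2) * log10(rss0 / rss1),
                 tolerance = 1e-10)
  }
})

test_that("LOD profile is invariant to affine transformation of the trait", {
  toy <- toy_single_qtl(n_lines = 60, seed = 8)
  cof <- select_cofactors(toy$geno, toy$y)
  p1 <- icim_scan(toy$geno, toy$map, toy$y, cofactors = cof)
  p2 <- icim_scan(toy$geno, toy$map, -3 * toy$y + 40, cofactors = cof)
  expect_equal(p1$lod, p2$lod, tolerance = 1e-9)
  expect_equal(p2$additive_effect, -3 * p1$additive_effect,
               tolerance = 1e-9)
})

test_that("stepwise selection finds the marker nearest a strong QTL", {
  hits <- vapply(1:300, function(s) {
    toy <- toy_single_qtl(n_lines = 145, pve = 0.3, pos = 72.5, seed = s)
    cof <- select_cofactors(toy$geno, toy$y)
    length(cof) >= 1 &&
      abs(toy$map$pos_cM[match(cof[1], toy$map$marker)] - 72.5) <= 2.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("stepwise entry rate is calibrated at PIN on independent markers", {
  # one marker per chromosome -> candidates are essentially independent,
  # so pure-noise traits should admit about pin * n_markers entries
  map <- simulate_map(200, 200, 200)       # 2 markers/chrom, 200 cM apart
  map <- map[map$pos_cM == 0, ]; class(map) <- c("genetic_map", "data.frame")
  set.seed(31)
  geno <- matrix(sample(c(1, -1), 120 * 200, replace = TRUE), 120, 200,
                 dimnames = list(sprintf("L%03d", 1:120), map$marker))
  n_runs <- 400
  n_sel <- vapply(seq_len(n_runs), function(i) {
    y <- stats::setNames(rnorm(120), rownames(geno))
    length(select_cofactors(geno, y, pin = 0.001))
  }, numeric(1))
  expected <- n_runs * 200 * 0.001    # 80 entries in total
  se <- sqrt(n_runs * 200 * 0.001 * 0.999)
  expect_lt(abs(sum(n_sel) - expected), 3 * se)
})

test_that("degenerate entry thresholds trip the overfitting guard", {
  toy <- toy_single_qtl(n_lines = 40, seed = 2, len = 100)
  expect_warning(cof <- select_cofactors(toy$geno, toy$y, pin = 1, pout = 1),
                 "n/2")
  expect_lte(length(cof), 20)
})

test_that("permutation thresholds behave like max-LOD quantiles", {
  toy <- toy_single_qtl(n_lines = 60, pve = 0, seed = 13, n_chrom = 2)
  gp <- scan_genoprob(toy$geno, toy$map, 2)
  y <- stats::setNames(rnorm(60), rownames(toy$geno))
  thr05 <- permutation_threshold(toy$geno, toy$map, y, n_perm = 120,
                                 alpha = 0.05, seed = 5, step = 2,
                                 genoprob = gp)
  thr20 <- permutation_threshold(toy$geno, toy$map, y, n_perm = 120,
                                 alpha = 0.20, seed = 5, step = 2,
                                 genoprob = gp)
  thr100 <- permutation_threshold(toy$geno, toy$map, y, n_perm = 120,
                                  alpha = 1, seed = 5, step = 2,
                                  genoprob = gp)
  expect_gte(thr05, thr20)            # monotone nonincreasing in alpha
  expect_equal(as.numeric(thr100), min(attr(thr05, "max_lods")))
  expect_identical(attr(thr05, "max_lods"), attr(thr20, "max_lods"))
})

test_that("QTL calling returns peaks, support intervals and PVE", {
  toy <- toy_single_qtl(n_lines = 145, pve = 0.3, pos = 72.5, seed = 3)
  cof <- select_cofactors(toy$geno, toy$y)
  prof <- icim_scan(toy$geno, toy$map, toy$y, cofactors = cof)
  rec <- call_qtl(prof, toy$map, lod_threshold = 2.5, trait_id = "t")
  expect_equal(nrow(rec), 1)
  expect_lte(rec$ci_lo_cM, rec$peak_cM)
  expect_gte(rec$ci_hi_cM, rec$peak_cM)
  expect_true(rec$ci_lo_marker %in% toy$map$marker)
  expect_true(rec$PVE > 15 && rec$is_major)
  # support interval endpoints are mapped marker positions
  expect_true(all(c(rec$ci_lo_cM, rec$ci_hi_cM) %in% toy$map$pos_cM))
  # everything below threshold -> empty table
  none <- call_qtl(prof, toy$map, lod_threshold = 1e6)
  expect_equal(nrow(none), 0)
})

test_that("two well-separated QTL on one chromosome give two records", {
  found <- vapply(1:20, function(s) {
    map <- simulate_map(1, 150, 5)
    geno <- simulate_ril_genotypes(map, 145, seed = s)
    set.seed(1000 + s)
    x1 <- metaboqtl:::sample_locus_genotype(geno, map, "chr1", 40)
    x2 <- metaboqtl:::sample_locus_genotype(geno, map, "chr1", 100)
    y <- stats::setNames(sqrt(0.25) * x1 + sqrt(0.25) * x2 +
                           rnorm(145, 0, sqrt(0.5)), rownames(geno))
    cof <- select_cofactors(geno, y)
    prof <- icim_scan(geno, map, y, cofactors = cof)
    nrow(call_qtl(prof, map, 2.5))
  }, numeric(1))
  expect_gte(mean(found >= 2), 0.9)
})

test_that("PVE peaks dominate their segment and stay within [0, 100]", {
  toy <- toy_single_qtl(n_lines = 100, pve = 0.4, seed = 6)
  prof <- icim_scan(toy$geno, toy$map, toy$y)
  pve_profile <- 100 * (1 - 10^(-2 * prof$lod / prof$n))
  expect_true(all(pve_profile >= 0 & pve_profile <= 100))
  rec <- call_qtl(prof, toy$map, 2.5)
  seg <- prof$positions$chromosome == rec$chromosome[1]
  # the strongest called peak carries the chromosome-wide PVE maximum
  expect_equal(max(pve_profile[seg]), max(rec$PVE), tolerance = 1e-9)
})

test_that("monomorphic regions scan to LOD zero with a flag", {
  map <- simulate_map(1, 20, 10)
  geno <- matrix(1, 30, 3, dimnames = list(sprintf("L%02d", 1:30),
                                           map$marker))
  y <- stats::setNames(rnorm(30), rownames(geno))
  prof <- icim_scan(geno, map, y, step = 5)
  expect_true(all(prof$lod == 0))
  expect_true(all(prof$monomorphic))
})
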