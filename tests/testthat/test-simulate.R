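test_that("RIL genotype switch rate matches the Haldane-Waddington rate", {
  map <- genetic_map(c("a", "b"), c("1", "1"), c(0, 10))
  geno <- simulate_ril_genotypes(map, 10000, seed = 7)
  obs <- mean(geno[, 1] != geno[, 2])
  R <- ril_recomb(haldane_r(10))          # 0.1533
  se <- sqrt(R * (1 - R) / 10000)
  expect_lt(abs(obs - R), 3 * se)
  # allele frequency ~ 0.5 at every marker
  af <- colMeans(geno == 1)
  expect_true(all(abs(af - 0.5) < 3 * sqrt(0.25 / 10000)))
})

test_that("zero map distance gives zero switches; seeds reproduce", {
  map <- genetic_map(c("a", "b"), c("1", "1"), c(5, 5))
  geno <- simulate_ril_genotypes(map, 500, seed = 3)
  expect_true(all(geno[, 1] == geno[, 2]))
  expect_identical(simulate_ril_genotypes(map, 50, seed = 9),
                   simulate_ril_genotypes(map, 50, seed = 9))
})

test_that("a noiseless single-QTL metabolite has H2 = 1 and marker R2 = 1", {
  map <- simulate_map(1, 100, 5)
  geno <- simulate_ril_genotypes(map, 60, seed = 2)
  arch <- structure(list(
    traits = list(met1 = list(
      qtl = data.frame(chromosome = "chr1", pos_cM = 50, pve = 1),
      h2 = 1)),
    hotspots = data.frame(chromosome = character(), pos_cM = numeric())),
    class = "sim_architecture")
  sim <- simulate_metabolome(geno, map, arch, n_replicates = 3, seed = 4)
  h2 <- broad_sense_heritability(log2_transform(sim$traits))
  expect_equal(unname(h2), 1, tolerance = 1e-9)
  # abundance is a deterministic function of the planted locus genotype
  m <- trait_matrix(log2_transform(sim$traits))
  x <- sign(m[, 1] - mean(m[, 1]))
  expect_equal(abs(cor(m[, 1], x)), 1, tolerance = 1e-9)
  expect_equal(sim$truth$planted_qtl$pve_realized, 100, tolerance = 1e-9)
})

test_that("near-zero genetic architecture yields near-zero heritability", {
  map <- simulate_map(1, 100, 10)
  geno <- simulate_ril_genotypes(map, 100, seed = 2)
  arch <- structure(list(
    traits = list(met1 = list(
      qtl = data.frame(chromosome = character(), pos_cM = numeric(),
                       pve = numeric()),
      h2 = 0.01)),
    hotspots = data.frame(chromosome = character(), pos_cM = numeric())),
    class = "sim_architecture")
  sim <- simulate_metabolome(geno, map, arch, n_replicates = 3, seed = 6)
  h2 <- broad_sense_heritability(log2_transform(sim$traits))
  expect_lt(unname(h2), 0.15)
  # target outside (0, 1] is rejected
  arch$traits$met1$h2 <- 1.2
  expect_error(simulate_metabolome(geno, map, arch, seed = 1), "H2")
})

test_that("realized planted PVE is centred on its target (Monte Carlo)", {
  map <- simulate_map(3, 150, 5)
  arch <- structure(list(
    traits = list(met1 = list(
      qtl = data.frame(chromosome = "chr2", pos_cM = 70, pve = 0.3),
      h2 = 0.7)),
    hotspots = data.frame(chromosome = character(), pos_cM = numeric())),
    class = "sim_architecture")
  pves <- vapply(1:60, function(s) {
    geno <- simulate_ril_genotypes(map, 145, seed = s)
    sim <- simulate_metabolome(geno, map, arch, n_replicates = 3,
                               seed = 1000 + s)
    sim$truth$planted_qtl$pve_realized
  }, numeric(1))
  expect_lt(abs(mean(pves) - 30), 2)
})

test_that("estimated H2 recovers the simulated target on study-scale data", {
  sim <- sim_ril_study("paper", seed = 11)
  h2_hat <- broad_sense_heritability(log2_transform(sim$metabolome))
  target <- sim$truth_metabolome$trait_h2[names(h2_hat)]
  expect_lt(abs(mean(h2_hat - target)), 0.05)
  expect_lt(mean(abs(h2_hat - target) > 0.1), 0.1)
  # heritabilities are centred near 0.6, as in a kernel metabolome study
  expect_gt(mean(h2_hat > 0.6), 0.4)
})

test_that("phenotypic variance decomposes into planted + polygenic + noise", {
  map <- simulate_map(2, 120, 5)
  geno <- simulate_ril_genotypes(map, 145, seed = 3)
  arch <- structure(list(
    traits = list(met1 = list(
      qtl = data.frame(chromosome = "chr1", pos_cM = 60, pve = 0.25),
      h2 = 0.65)),
    hotspots = data.frame(chromosome = character(), pos_cM = numeric())),
    class = "sim_architecture")
  sim <- simulate_metabolome(geno, map, arch, n_replicates = 3, seed = 8)
  vals <- log2_transform(sim$traits)
  # total per-observation variance approx genetic variance / h2
  g <- sim$truth$genetic_values[, 1]
  vP <- var(vals$value)
  expect_equal(vP, var(g) / 0.65, tolerance = 0.15)
})

test_that("agronomic sharing produces correlated, colocalized pairs", {
  map <- simulate_map(2, 100, 5)
  geno <- simulate_ril_genotypes(map, 80, seed = 5)
  arch <- structure(list(
    traits = list(met1 = list(
      qtl = data.frame(chromosome = "chr1", pos_cM = 50, pve = 1),
      h2 = 1)),
    hotspots = data.frame(chromosome = "chr1", pos_cM = 50)),
    class = "sim_architecture")
  met <- simulate_metabolome(geno, map, arch, n_replicates = 1, seed = 2)
  # deterministic link: trait loads fully on the metabolite genetic value
  sharing <- data.frame(trait_id = "agro01", metabolite_id = "met1",
                        med_share = 1)
  agro <- simulate_agronomic(geno, map, met$truth, n_traits = 1,
                             sharing = sharing, h2 = 1, seed = 3)
  mm <- trait_matrix(met$traits); am <- trait_matrix(agro$traits)
  expect_equal(abs(cor(log2(mm[, 1]), am[, 1])), 1, tolerance = 1e-9)
  expect_equal(agro$truth$expected_coloc$metabolite_id, "met1")
  expect_equal(agro$truth$expected_coloc$chromosome, "chr1")
  # empty sharing -> no expected colocalization
  agro0 <- simulate_agronomic(geno, map, met$truth, n_traits = 1,
                              sharing = sharing[0, ], h2 = 0.6, seed = 3)
  expect_equal(nrow(agro0$truth$expected_coloc), 0)
  # unknown metabolite in sharing is an error
  bad <- data.frame(trait_id = "agro01", metabolite_id = "nope",
                    med_share = 0.5)
  expect_error(simulate_agronomic(geno, map, met$truth, n_traits = 1,
                                  sharing = bad, seed = 1), "nonexistent")
})

test_that("study presets are deterministic under a fixed master seed", {
  a <- sim_ril_study("tiny", seed = 21)
  b <- sim_ril_study("tiny", seed = 21)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$metabolome$value, b$metabolome$value)
  expect_identical(a$truth_metabolome$planted_qtl,
                   b$truth_metabolome$planted_qtl)
  c <- sim_ril_study("tiny", seed = 22)
  expect_false(identical(a$metabolome$value, c$metabolome$value))
})
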