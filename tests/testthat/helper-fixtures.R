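# Small deterministic fixtures shared across test files.

# 3 lines x 2 markers genotype file in a given dialect
write_tiny_geno_file <- function(path, codes = c("A", "B"),
                                 extra_code = NULL, sep = "\t") {
  calls <- matrix(c(codes[1], codes[1], codes[2],
                    codes[1], codes[2], codes[2]), nrow = 2, byrow = TRUE)
  if (!is.null(extra_code)) calls[2, 2] <- extra_code
  df <- data.frame(marker = c("m1", "m2"), chromosome = "chr1",
                   pos_cM = c(0, 10),
                   L1 = calls[, 1], L2 = calls[, 2], L3 = calls[, 3])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# one-chromosome population with a single planted additive locus
toy_single_qtl <- function(n_lines = 145, pve = 0.3, pos = 72.5,
                           chrom = "chr1", n_chrom = 1, len = 150,
                           spacing = 5, seed = 1) {
  map <- simulate_map(n_chrom, len, spacing)
  geno <- simulate_ril_genotypes(map, n_lines, seed = seed)
  x <- metaboqtl:::sample_locus_genotype(geno, map, chrom, pos)
  y <- sqrt(pve) * x + stats::rnorm(n_lines, 0, sqrt(1 - pve))
  list(map = map, geno = geno, x = x,
       y = stats::setNames(y, rownames(geno)))
}

# hand-built QTL record
make_rec <- function(trait = "t1", chrom = "chr1", peak = 50, lod = 5,
                     pve = 20, lo = 45, hi = 55, eff = 0.5) {
  data.frame(trait_id = trait, chromosome = chrom, peak_cM = peak,
             LOD = lod, additive_effect = eff, PVE = pve,
             ci_lo_cM = lo, ci_hi_cM = hi,
             ci_lo_marker = "mA", ci_hi_marker = "mB",
             stringsAsFactors = FALSE)
}
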