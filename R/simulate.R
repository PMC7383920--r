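#' @name synthetic-population
#' @title Synthetic RIL populations with known genetic architecture
#' @description
#' The generator emulates a biparental recombinant-inbred-line (RIL)
#' study of the kernel metabolome: ~145 lines genotyped on a
#' multi-chromosome genetic map, metabolite abundances measured in three
#' biological replicates with broad-sense heritabilities centred near
#' 0.6, planted QTL spanning a wide range of explained variance,
#' deliberately pleiotropic hotspot loci, and agronomic traits that
#' share loci with (and are partly mediated by) metabolites. Every
#' planted effect is recorded in a `sim_truth` object so downstream
#' stages can be scored against ground truth.
NULL

# deterministic per-stage substreams from one master seed
stage_seed <- function(seed, stage) {
  stages <- c("map", "genotypes", "architecture", "metabolome",
              "agronomic", "permutation", "folds", "misc")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown seed stage: ", stage)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, 8L)[i]
}

#' Simulate RIL genotypes along a genetic map
#'
#' Lines are generated directly at inbreeding equilibrium: per
#' chromosome, the first marker is drawn uniformly from the two parental
#' states and the state switches between adjacent markers with
#' probability R = 2r/(1+2r) (Haldane-Waddington), where r is the
#' Haldane recombination fraction for the marker distance. Each line is
#' therefore a mosaic of parental blocks with no heterozygous class.
#'
#' @param map A `genetic_map`.
#' @param n_lines Number of lines (>= 2).
#' @param seed Integer seed; the same seed reproduces the matrix.
#' @return Numeric lines x markers matrix coded +1 (P1) / -1 (P2).
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed = 1) {
  stopifnot(is_genetic_map(map), n_lines >= 2)
  set.seed(seed)
  chroms <- unique(map$chromosome)
  geno <- matrix(NA_real_, n_lines, nrow(map),
                 dimnames = list(sprintf("RIL%03d", seq_len(n_lines)),
                                 map$marker))
  for (ch in chroms) {
    idx <- which(map$chromosome == ch)
    pos <- map$pos_cM[idx]
    m <- length(idx)
    R <- ril_recomb(haldane_r(diff(pos)))
    states <- matrix(0, n_lines, m)
    states[, 1L] <- sample(c(1, -1), n_lines, replace = TRUE)
    if (m > 1L) {
      switch_mat <- matrix(stats::runif(n_lines * (m - 1L)), n_lines) <
        matrix(R, n_lines, m - 1L, byrow = TRUE)
      # cumulative parity of switches gives the state mosaic
      flips <- t(apply(switch_mat, 1L, cumsum)) %% 2
      states[, -1L] <- states[, 1L] * (1 - 2 * flips)
    }
    geno[, idx] <- states
  }
  geno
}

# P(Q = P1) at an untyped position given flanking genotypes coded
# +1/-1/0 (0 = missing, marginalized at the 1/2 prior). cL, cR are
# 0.5 - R for the left/right gap. Vectorized over lines x positions.
.flank_expectation <- function(GL, GR, cL, cR) {
  num_diff <- GL * cL + GR * cR
  num_sum <- 0.5 + 2 * GL * GR * cL * cR
  num_diff / num_sum   # = E[x] = 2 P(Q=P1) - 1
}

# sample a biallelic locus at an arbitrary map position, consistent
# with the Markov recombination model given the flanking markers
sample_locus_genotype <- function(genotypes, map, chromosome, pos_cM) {
  idx <- which(map$chromosome == chromosome)
  if (!length(idx)) stop("chromosome not on map: ", chromosome)
  pos <- map$pos_cM[idx]
  if (pos_cM < min(pos) - 1e-9 || pos_cM > max(pos) + 1e-9)
    stop("planted position outside the chromosome span")
  li <- findInterval(pos_cM, pos)
  li <- max(1L, min(li, length(pos)))
  ri <- if (pos[li] >= pos_cM - 1e-12) li else min(li + 1L, length(pos))
  GL <- genotypes[, idx[li]]
  GR <- genotypes[, idx[ri]]
  GL[is.na(GL)] <- 0; GR[is.na(GR)] <- 0
  cL <- 0.5 - ril_recomb(haldane_r(abs(pos_cM - pos[li])))
  cR <- 0.5 - ril_recomb(haldane_r(abs(pos[ri] - pos_cM)))
  ex <- .flank_expectation(GL, GR, cL, cR)
  p1 <- (ex + 1) / 2
  ifelse(stats::runif(nrow(genotypes)) < p1, 1, -1)
}

#' Draw a random metabolome architecture
#'
#' Assigns each metabolite a target broad-sense heritability (Beta
#' distributed, centred near 0.6), background QTL with explained
#' variance drawn from a right-skewed distribution spanning roughly
#' 1-50% of phenotypic variance, and attaches a subset of metabolites
#' to a small number of pleiotropic hotspot loci.
#'
#' @param map A `genetic_map`.
#' @param n_metabolites Number of metabolite features.
#' @param n_hotspots Number of pleiotropic hotspot loci.
#' @param metabolites_per_hotspot Metabolites attached to each hotspot.
#' @param seed Integer seed.
#' @return A `sim_architecture`: list with `traits` (per-metabolite list
#'   of `qtl` data frame and target `h2`) and `hotspots`
#'   (data frame chromosome / pos_cM).
#' @export
sim_architecture <- function(map, n_metabolites = 200, n_hotspots = 3,
                             metabolites_per_hotspot = 25, seed = 1) {
  set.seed(seed)
  chroms <- unique(map$chromosome)
  lens <- chrom_lengths(map)
  met_ids <- sprintf("met%04d", seq_len(n_metabolites))
  classes <- sample(c("flavonoid", "phenolamide", "amino_acid", "lipid",
                      "polyphenol", "unknown"),
                    n_metabolites, replace = TRUE,
                    prob = c(0.2, 0.1, 0.15, 0.15, 0.1, 0.3))
  hot_chr <- sample(chroms, n_hotspots)
  hot_pos <- round(stats::runif(n_hotspots, 0.25, 0.75) * lens[hot_chr], 1)
  hotspots <- data.frame(chromosome = hot_chr, pos_cM = as.numeric(hot_pos),
                         stringsAsFactors = FALSE)
  traits <- stats::setNames(vector("list", n_metabolites), met_ids)
  for (i in seq_len(n_metabolites)) {
    h2 <- min(0.95, max(0.2, stats::rbeta(1, 3.6, 2.4)))
    n_bg <- stats::rpois(1, 0.9)
    qtl <- data.frame(chromosome = character(), pos_cM = numeric(),
                      pve = numeric(), stringsAsFactors = FALSE)
    if (n_bg > 0) {
      ch <- sample(chroms, n_bg, replace = TRUE)
      qtl <- data.frame(chromosome = ch,
                        pos_cM = round(stats::runif(n_bg) * lens[ch], 1),
                        pve = 0.008 + stats::rbeta(n_bg, 0.9, 3.5) * 0.5,
                        stringsAsFactors = FALSE)
    }
    traits[[i]] <- list(qtl = qtl, h2 = h2, class = classes[i])
  }
  for (h in seq_len(n_hotspots)) {
    members <- sample(met_ids, metabolites_per_hotspot)
    for (m in members) {
      pve <- stats::runif(1, 0.12, 0.40)
      traits[[m]]$qtl <- rbind(traits[[m]]$qtl,
                               data.frame(chromosome = hotspots$chromosome[h],
                                          pos_cM = hotspots$pos_cM[h],
                                          pve = pve,
                                          stringsAsFactors = FALSE))
      traits[[m]]$h2 <- max(traits[[m]]$h2, min(0.95, pve + 0.25))
    }
  }
  # keep total planted variance inside the heritable share
  for (m in met_ids) {
    tot <- sum(traits[[m]]$qtl$pve)
    cap <- traits[[m]]$h2 - 0.05
    if (tot > cap && tot > 0)
      traits[[m]]$qtl$pve <- traits[[m]]$qtl$pve * cap / tot
  }
  structure(list(traits = traits, hotspots = hotspots),
            class = "sim_architecture")
}

#' Simulate replicated metabolite abundances from an architecture
#'
#' The generative model for metabolite j on the log2 scale is
#' y_ijk = mu_j + sum_q a_q x_iq + g_i + e_ijk, where x_iq is the
#' planted-locus genotype (+1/-1) of line i sampled consistently with
#' the recombination model, g_i a polygenic line effect filling the
#' heritable variance not claimed by planted QTL, and e_ijk replicate
#' noise scaled so that the broad-sense heritability (per-observation
#' basis) hits the architecture's target. Abundances are exponentiated
#' (2^y) before output so the pipeline's log2 transform is exercised.
#'
#' @param genotypes Lines x markers matrix from
#'   [simulate_ril_genotypes()].
#' @param map The matching `genetic_map`.
#' @param architecture A `sim_architecture` (see [sim_architecture()]).
#' @param n_replicates Biological replicates per line (default 3).
#' @param seed Integer seed.
#' @return List with `traits` (a `trait_table` of abundances) and
#'   `truth` (a `sim_truth`: planted QTL with realized PVE, target H2
#'   per trait, hotspot loci, and per-line genetic values).
#' @export
simulate_metabolome <- function(genotypes, map, architecture,
                                n_replicates = 3, seed = 1) {
  stopifnot(inherits(architecture, "sim_architecture"), n_replicates >= 1)
  set.seed(seed)
  n <- nrow(genotypes)
  met_ids <- names(architecture$traits)
  lines <- rownames(genotypes)
  gvals <- matrix(0, n, length(met_ids), dimnames = list(lines, met_ids))
  planted <- vector("list", length(met_ids))
  values <- array(NA_real_, c(n, length(met_ids), n_replicates))
  h2_target <- numeric(length(met_ids))
  var1 <- function(v) sum((v - mean(v))^2) / length(v)  # population variance
  for (j in seq_along(met_ids)) {
    arch <- architecture$traits[[j]]
    if (is.null(arch$h2) || arch$h2 <= 0 || arch$h2 > 1)
      stop("target H2 must lie in (0, 1]: trait ", met_ids[j])
    h2 <- h2_target[j] <- arch$h2
    qtl <- arch$qtl
    G <- rep(0, n)
    rec <- NULL
    if (nrow(qtl)) {
      a <- numeric(nrow(qtl))
      X <- matrix(0, n, nrow(qtl))
      for (q in seq_len(nrow(qtl))) {
        x <- sample_locus_genotype(genotypes, map, qtl$chromosome[q],
                                   qtl$pos_cM[q])
        sdx <- sqrt(var1(x))
        a[q] <- sample(c(-1, 1), 1) * sqrt(qtl$pve[q]) /
          ifelse(sdx > 0, sdx, 1)
        X[, q] <- x
      }
      G <- drop(X %*% a)
      rec <- data.frame(trait_id = met_ids[j], chromosome = qtl$chromosome,
                        pos_cM = qtl$pos_cM, additive_effect = a,
                        pve_target = 100 * qtl$pve,
                        stringsAsFactors = FALSE)
    }
    poly_share <- max(h2 - sum(if (nrow(qtl)) qtl$pve else 0), 0)
    if (poly_share > 0)
      G <- G + stats::rnorm(n, 0, sqrt(poly_share))
    vG <- var1(G)
    sigma_e <- if (h2 >= 1) 0 else sqrt(vG * (1 - h2) / h2)
    if (vG == 0 && h2 < 1) sigma_e <- 1   # pure-noise trait
    vP <- vG + sigma_e^2
    if (!is.null(rec)) {
      rec$pve_realized <- if (vP > 0)
        100 * rec$additive_effect^2 *
          apply(as.matrix(X), 2, var1) / vP else 0
      planted[[j]] <- rec
    }
    mu <- stats::rnorm(1, 10, 2)
    gvals[, j] <- G
    for (k in seq_len(n_replicates))
      values[, j, k] <- mu + G + stats::rnorm(n, 0, sigma_e)
  }
  classes <- vapply(architecture$traits, function(t)
    if (is.null(t$class)) "unknown" else t$class, character(1))
  tt <- trait_table(
    line_id = rep(lines, times = length(met_ids) * n_replicates),
    trait_id = rep(rep(met_ids, each = n), times = n_replicates),
    replicate_id = rep(seq_len(n_replicates), each = n * length(met_ids)),
    value = 2^as.vector(values),
    trait_class = rep(rep(classes, each = n), times = n_replicates))
  planted_df <- if (length(pl <- Filter(Negate(is.null), planted)))
    do.call(rbind, pl) else
    data.frame(trait_id = character(), chromosome = character(),
               pos_cM = numeric(), additive_effect = numeric(),
               pve_target = numeric(), pve_realized = numeric(),
               stringsAsFactors = FALSE)
  rownames(planted_df) <- NULL
  truth <- structure(list(planted_qtl = planted_df,
                          trait_h2 = stats::setNames(h2_target, met_ids),
                          hotspots = architecture$hotspots,
                          genetic_values = gvals),
                     class = "sim_truth")
  list(traits = tt, truth = truth)
}

#' Simulate agronomic traits sharing loci with the metabolome
#'
#' Each designated (metabolite, trait) pair receives a
#' metabolite-mediated component: the trait loads on the metabolite's
#' genetic value, so the metabolite's planted hotspot locus also drives
#' the trait (an expected mQTL-pQTL colocalization) and the pair is
#' phenotypically correlated. Traits additionally carry private QTL and
#' polygenic background up to a target heritability.
#'
#' @param genotypes,map As for [simulate_metabolome()].
#' @param metabolome_truth The `sim_truth` from [simulate_metabolome()].
#' @param n_traits Number of agronomic traits (default 17).
#' @param sharing Data frame with columns `trait_id` (agronomic),
#'   `metabolite_id`, `med_share` (variance share of the mediated
#'   component). `NULL` builds a default: one pair per hotspot locus,
#'   med_share 0.45 (so the shared locus is a clearly
#'   detectable pQTL). Metabolite ids must exist in the truth object.
#' @param h2 Target heritability of the agronomic traits (default 0.61).
#' @param seed Integer seed.
#' @return List with `traits` (single-measurement `trait_table`,
#'   class "agronomic") and `truth` (`sim_truth` whose
#'   `expected_coloc` lists the designated metabolite-trait pairs with
#'   their shared locus).
#' @export
simulate_agronomic <- function(genotypes, map, metabolome_truth,
                               n_traits = 17, sharing = NULL, h2 = 0.61,
                               seed = 1) {
  stopifnot(inherits(metabolome_truth, "sim_truth"))
  set.seed(seed)
  n <- nrow(genotypes)
  lines <- rownames(genotypes)
  trait_ids <- sprintf("agro%02d", seq_len(n_traits))
  lens <- chrom_lengths(map)
  chroms <- unique(map$chromosome)
  hot <- metabolome_truth$hotspots
  pq <- metabolome_truth$planted_qtl
  if (is.null(sharing)) {
    sharing <- data.frame(trait_id = character(), metabolite_id = character(),
                          med_share = numeric(), stringsAsFactors = FALSE)
    if (!is.null(hot) && nrow(hot)) {
      for (h in seq_len(nrow(hot))) {
        at_h <- pq[pq$chromosome == hot$chromosome[h] &
                     abs(pq$pos_cM - hot$pos_cM[h]) < 1e-9, , drop = FALSE]
        if (!nrow(at_h)) next
        best <- at_h$trait_id[which.max(at_h$pve_realized)]
        sharing <- rbind(sharing, data.frame(
          trait_id = trait_ids[(h - 1L) %% n_traits + 1L],
          metabolite_id = best, med_share = 0.45,
          stringsAsFactors = FALSE))
      }
    }
  }
  bad <- setdiff(sharing$metabolite_id, colnames(metabolome_truth$genetic_values))
  if (length(bad))
    stop("sharing references nonexistent planted metabolite(s): ",
         paste(bad, collapse = ", "))
  var1 <- function(v) sum((v - mean(v))^2) / length(v)
  planted <- list()
  coloc <- list()
  values <- matrix(NA_real_, n, n_traits, dimnames = list(lines, trait_ids))
  gvals <- matrix(0, n, n_traits, dimnames = list(lines, trait_ids))
  for (j in seq_len(n_traits)) {
    tid <- trait_ids[j]
    G <- rep(0, n)
    used_share <- 0
    sh <- sharing[sharing$trait_id == tid, , drop = FALSE]
    for (s in seq_len(nrow(sh))) {
      gm <- metabolome_truth$genetic_values[, sh$metabolite_id[s]]
      sdg <- sqrt(var1(gm))
      if (sdg == 0) next
      beta <- sqrt(sh$med_share[s]) / sdg
      G <- G + beta * (gm - mean(gm))
      used_share <- used_share + sh$med_share[s]
      # the metabolite's planted loci become expected pQTL for this trait
      mq <- pq[pq$trait_id == sh$metabolite_id[s], , drop = FALSE]
      h2m <- metabolome_truth$trait_h2[[sh$metabolite_id[s]]]
      if (nrow(mq)) {
        planted[[length(planted) + 1L]] <- data.frame(
          trait_id = tid, chromosome = mq$chromosome, pos_cM = mq$pos_cM,
          additive_effect = beta * mq$additive_effect,
          pve_target = sh$med_share[s] * mq$pve_target / max(h2m, 1e-9),
          stringsAsFactors = FALSE)
        coloc[[length(coloc) + 1L]] <- data.frame(
          metabolite_id = sh$metabolite_id[s], trait_id = tid,
          chromosome = mq$chromosome, pos_cM = mq$pos_cM,
          pve_metabolite = mq$pve_target,
          pve_trait = sh$med_share[s] * mq$pve_target / max(h2m, 1e-9),
          stringsAsFactors = FALSE)
      }
    }
    # one private QTL per trait, unlinked to the mediation loci
    ch <- sample(chroms, 1)
    own_pos <- round(stats::runif(1) * lens[[ch]], 1)
    own_pve <- stats::runif(1, 0.08, 0.2)
    if (used_share + own_pve < h2 - 0.05) {
      x <- sample_locus_genotype(genotypes, map, ch, own_pos)
      a <- sample(c(-1, 1), 1) * sqrt(own_pve) / max(sqrt(var1(x)), 1e-9)
      G <- G + a * x
      used_share <- used_share + own_pve
      planted[[length(planted) + 1L]] <- data.frame(
        trait_id = tid, chromosome = ch, pos_cM = own_pos,
        additive_effect = a, pve_target = 100 * own_pve,
        stringsAsFactors = FALSE)
    }
    poly <- max(h2 - used_share, 0)
    if (poly > 0) G <- G + stats::rnorm(n, 0, sqrt(poly))
    vG <- var1(G)
    sigma_e <- if (vG > 0) sqrt(vG * (1 - h2) / h2) else 1
    gvals[, j] <- G
    values[, j] <- stats::rnorm(1, 100, 20) +
      10 * (G + stats::rnorm(n, 0, sigma_e))
  }
  planted_df <- if (length(planted)) do.call(rbind, planted) else
    data.frame(trait_id = character(), chromosome = character(),
               pos_cM = numeric(), additive_effect = numeric(),
               pve_target = numeric(), stringsAsFactors = FALSE)
  coloc_df <- if (length(coloc)) do.call(rbind, coloc) else
    data.frame(metabolite_id = character(), trait_id = character(),
               chromosome = character(), pos_cM = numeric(),
               pve_metabolite = numeric(), pve_trait = numeric(),
               stringsAsFactors = FALSE)
  rownames(planted_df) <- rownames(coloc_df) <- NULL
  tt <- trait_table(line_id = rep(lines, n_traits),
                    trait_id = rep(trait_ids, each = n),
                    value = as.vector(values),
                    trait_class = "agronomic")
  truth <- structure(list(planted_qtl = planted_df,
                          trait_h2 = stats::setNames(rep(h2, n_traits),
                                                     trait_ids),
                          hotspots = metabolome_truth$hotspots,
                          genetic_values = gvals,
                          expected_coloc = coloc_df),
                     class = "sim_truth")
  list(traits = tt, truth = truth)
}

#' Simulate a complete RIL metabolome study
#'
#' Convenience wrapper chaining map, genotypes, metabolome and
#' agronomic simulation under one master seed with per-stage
#' substreams.
#'
#' @param preset `"paper"` (145 lines, 21 chromosomes of 150 cM with
#'   5 cM marker spacing, 200 metabolite features x 3 replicates, 3
#'   hotspot loci, 17 agronomic traits) or `"tiny"` (50 lines, 3
#'   chromosomes, 20 metabolites, 1 hotspot, 4 agronomic traits).
#' @param seed Master integer seed.
#' @param n_lines,n_metabolites,n_hotspots,n_traits Optional overrides.
#' @return List with `map`, `genotypes`, `metabolome`, `agronomic`,
#'   `truth_metabolome`, `truth_agronomic`, `architecture`.
#' @export
sim_ril_study <- function(preset = c("paper", "tiny"), seed = 1,
                          n_lines = NULL, n_metabolites = NULL,
                          n_hotspots = NULL, n_traits = NULL) {
  preset <- match.arg(preset)
  p <- if (preset == "paper")
    list(n_chrom = 21, len = 150, spacing = 5, n_lines = 145,
         n_met = 200, n_hot = 3, per_hot = 25, n_agro = 17)
  else
    list(n_chrom = 3, len = 100, spacing = 5, n_lines = 50,
         n_met = 20, n_hot = 1, per_hot = 6, n_agro = 4)
  if (!is.null(n_lines)) p$n_lines <- n_lines
  if (!is.null(n_metabolites)) p$n_met <- n_metabolites
  if (!is.null(n_hotspots)) p$n_hot <- n_hotspots
  if (!is.null(n_traits)) p$n_agro <- n_traits
  map <- simulate_map(p$n_chrom, p$len, p$spacing)
  geno <- simulate_ril_genotypes(map, p$n_lines,
                                 seed = stage_seed(seed, "genotypes"))
  arch <- sim_architecture(map, n_metabolites = p$n_met,
                           n_hotspots = p$n_hot,
                           metabolites_per_hotspot = p$per_hot,
                           seed = stage_seed(seed, "architecture"))
  met <- simulate_metabolome(geno, map, arch, n_replicates = 3,
                             seed = stage_seed(seed, "metabolome"))
  agro <- simulate_agronomic(geno, map, met$truth, n_traits = p$n_agro,
                             seed = stage_seed(seed, "agronomic"))
  list(map = map, genotypes = geno, metabolome = met$traits,
       agronomic = agro$traits, truth_metabolome = met$truth,
       truth_agronomic = agro$truth, architecture = arch)
}
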