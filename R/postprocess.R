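#' Consolidate per-replicate QTL into reproducible loci
#'
#' QTL mapped independently in each biological replicate are grouped
#' (per trait and chromosome) when their marker-extended support
#' intervals overlap; a group supported by at least `min_support`
#' distinct replicates is reported through its highest-PVE member, with
#' the replicate support recorded. Grouping is by overlap chaining on
#' the sorted intervals.
#'
#' @param qtl_lists A list of `qtl_table`s, one per replicate scan.
#'   Tables holding a single (but differing) trait each are rejected as
#'   a replicate/trait mix-up; multi-trait tables are grouped per trait.
#' @param min_support Minimum number of replicates (default 2 of 3).
#' @return A consolidated `qtl_table` with `n_replicates_detected` set.
#' @export
consolidate_replicates <- function(qtl_lists, min_support = 2) {
  stopifnot(is.list(qtl_lists), length(qtl_lists) >= 1)
  utraits <- lapply(qtl_lists, function(t) unique(t$trait_id))
  single <- vapply(utraits, length, integer(1)) <= 1L
  if (all(single) && length(unique(unlist(utraits))) > 1L)
    stop("replicate lists carry different traits: not replicates of one trait")
  all_rec <- do.call(rbind, Map(function(t, r) {
    if (nrow(t)) t$replicate <- r
    t
  }, lapply(qtl_lists, as.data.frame), seq_along(qtl_lists)))
  if (is.null(all_rec) || nrow(all_rec) == 0L) return(qtl_table(NULL))
  out <- list()
  for (key in unique(paste(all_rec$trait_id, all_rec$chromosome, sep = "\r"))) {
    grp <- all_rec[paste(all_rec$trait_id, all_rec$chromosome, sep = "\r") ==
                     key, , drop = FALSE]
    grp <- grp[order(grp$ci_lo_cM, grp$ci_hi_cM), , drop = FALSE]
    cluster <- cumsum(c(TRUE, grp$ci_lo_cM[-1] >
                          cummax(grp$ci_hi_cM)[-nrow(grp)]))
    for (cl in split(seq_len(nrow(grp)), cluster)) {
      support <- length(unique(grp$replicate[cl]))
      if (support < min_support) next
      best <- cl[which.max(grp$PVE[cl])]
      rec <- grp[best, setdiff(names(grp), "replicate"), drop = FALSE]
      rec$n_replicates_detected <- support
      out[[length(out) + 1L]] <- rec
    }
  }
  qtl_table(if (length(out)) do.call(rbind, out) else NULL)
}

#' Chi-squared test of QTL distribution over chromosomes
#'
#' Observed per-chromosome QTL counts against expectations proportional
#' to chromosome genetic length (or marker count).
#'
#' @param records A `qtl_table`.
#' @param map A `genetic_map`.
#' @param expected `"length"` (default) or `"markers"`.
#' @return List with `chi2`, `df`, `p_value`, `observed`, `expected`.
#' @export
chromosome_distribution_test <- function(records, map,
                                         expected = c("length", "markers")) {
  expected <- match.arg(expected)
  lens <- chrom_lengths(map)
  if (any(lens <= 0)) stop("zero-length chromosome on map")
  w <- if (expected == "length") lens else
    table(factor(map$chromosome, levels = names(lens)))
  w <- as.numeric(w) / sum(as.numeric(w))
  obs <- table(factor(records$chromosome, levels = names(lens)))
  n <- sum(obs)
  exp_counts <- n * w
  if (length(lens) < 2 || any(exp_counts < 1))
    stop("need >= 2 chromosomes with expected count >= 1")
  chi2 <- sum((as.numeric(obs) - exp_counts)^2 / exp_counts)
  df <- length(lens) - 1L
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       observed = stats::setNames(as.integer(obs), names(lens)),
       expected = stats::setNames(exp_counts, names(lens)))
}

#' Tile the genome into fixed-width bins
#'
#' Bins are anchored at 0 cM per chromosome, half-open [start, end)
#' with the last bin truncated at the chromosome end and closed.
#'
#' @param map A `genetic_map`.
#' @param bin_width Bin width in cM (default 10).
#' @return Data frame: `chromosome`, `bin_index` (1-based per
#'   chromosome), `start_cM`, `end_cM`.
#' @export
genome_bins <- function(map, bin_width = 10) {
  lens <- chrom_lengths(map)
  do.call(rbind, lapply(names(lens), function(ch) {
    nb <- max(1L, ceiling(lens[[ch]] / bin_width))
    data.frame(chromosome = ch, bin_index = seq_len(nb),
               start_cM = (seq_len(nb) - 1) * bin_width,
               end_cM = pmin(seq_len(nb) * bin_width, lens[[ch]]),
               stringsAsFactors = FALSE)
  }))
}

#' Permutation cutoff for QTL hotspot calling
#'
#' Each of the n QTL is assigned independently and uniformly to one of
#' the B genome bins; the cutoff is the ceiling of the (1 - alpha)
#' quantile of the per-permutation maximum bin count. A bin holding
#' more QTL than the cutoff is a hotspot.
#'
#' @param n_qtl Number of QTL to scatter.
#' @param bins Number of bins B, or a bin data frame from
#'   [genome_bins()].
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param alpha Genome-wide significance (default 0.01).
#' @param seed Integer seed.
#' @return Integer cutoff with the permutation maxima in
#'   `attr(, "max_counts")`.
#' @export
hotspot_cutoff <- function(n_qtl, bins, n_perm = 1000, alpha = 0.01,
                           seed = 1) {
  B <- if (is.data.frame(bins)) nrow(bins) else as.integer(bins)
  stopifnot(B >= 1, n_perm >= 100, alpha > 0, alpha <= 1, n_qtl >= 1)
  set.seed(seed)
  maxima <- vapply(seq_len(n_perm), function(i)
    max(tabulate(sample.int(B, n_qtl, replace = TRUE), nbins = B)),
    integer(1))
  cutoff <- as.integer(ceiling(stats::quantile(maxima, probs = 1 - alpha,
                                               type = 1, names = FALSE)))
  attr(cutoff, "max_counts") <- maxima
  cutoff
}

#' Count QTL per genome bin and call hotspots
#'
#' Assigns each record's peak to its bin (`[start, end)`, last bin
#' closed) and returns the bins whose count exceeds the cutoff, sorted
#' by decreasing count. The full bin tiling with counts is attached as
#' `attr(, "all_bins")`.
#'
#' @param records A `qtl_table` of (consolidated) mQTL.
#' @param map A `genetic_map`.
#' @param bin_width Bin width in cM (default 10).
#' @param cutoff Count cutoff from [hotspot_cutoff()].
#' @return Data frame of hotspot bins with a `count` column.
#' @export
call_hotspots <- function(records, map, bin_width = 10, cutoff) {
  bins <- genome_bins(map, bin_width)
  lens <- chrom_lengths(map)
  if (nrow(records)) {
    over <- records$peak_cM > lens[records$chromosome] + 1e-9
    if (any(over, na.rm = TRUE))
      stop("QTL peak beyond chromosome end: map mismatch")
  }
  nb_per <- table(factor(bins$chromosome, levels = names(lens)))
  bi <- pmin(floor(records$peak_cM / bin_width) + 1L,
             as.integer(nb_per[records$chromosome]))
  key_rec <- paste(records$chromosome, bi)
  key_bin <- paste(bins$chromosome, bins$bin_index)
  bins$count <- as.integer(table(factor(key_rec, levels = key_bin)))
  hot <- bins[bins$count > cutoff, , drop = FALSE]
  hot <- hot[order(-hot$count, hot$chromosome, hot$bin_index), ,
             drop = FALSE]
  rownames(hot) <- NULL
  attr(hot, "all_bins") <- bins
  hot
}

#' Colocalize mQTL with pQTL by support-interval overlap
#'
#' All (metabolite QTL, phenotype QTL) pairs on the same chromosome
#' whose marker-extended support intervals intersect
#' (closed-interval convention: touching endpoints overlap). Both
#' tables must come from scans on the same genetic map.
#'
#' @param mqtl_records,pqtl_records `qtl_table`s.
#' @return Data frame of pairs: `metabolite_id`, `trait_id`,
#'   `chromosome`, peak positions, and the overlap interval.
#' @export
colocalize <- function(mqtl_records, pqtl_records) {
  m <- as.data.frame(mqtl_records); p <- as.data.frame(pqtl_records)
  if (!nrow(m) || !nrow(p))
    return(data.frame(metabolite_id = character(), trait_id = character(),
                      chromosome = character(), mqtl_peak_cM = numeric(),
                      pqtl_peak_cM = numeric(), overlap_lo_cM = numeric(),
                      overlap_hi_cM = numeric(), stringsAsFactors = FALSE))
  m$.i <- seq_len(nrow(m)); p$.j <- seq_len(nrow(p))
  pairs <- merge(m[c(".i", "trait_id", "chromosome", "peak_cM",
                     "ci_lo_cM", "ci_hi_cM")],
                 p[c(".j", "trait_id", "chromosome", "peak_cM",
                     "ci_lo_cM", "ci_hi_cM")],
                 by = "chromosome", suffixes = c("_m", "_p"))
  keep <- pairs$ci_lo_cM_m <= pairs$ci_hi_cM_p &
    pairs$ci_lo_cM_p <= pairs$ci_hi_cM_m
  pairs <- pairs[keep, , drop = FALSE]
  out <- data.frame(metabolite_id = pairs$trait_id_m,
                    trait_id = pairs$trait_id_p,
                    chromosome = pairs$chromosome,
                    mqtl_peak_cM = pairs$peak_cM_m,
                    pqtl_peak_cM = pairs$peak_cM_p,
                    overlap_lo_cM = pmax(pairs$ci_lo_cM_m, pairs$ci_lo_cM_p),
                    overlap_hi_cM = pmin(pairs$ci_hi_cM_m, pairs$ci_hi_cM_p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$metabolite_id, out$trait_id, out$chromosome,
                   out$mqtl_peak_cM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reference colocalized pairs with the correlation network
#'
#' Marks each colocalized (metabolite, trait) pair as `correlated` when
#' its phenotypic correlation edge passes the P threshold; the flagged
#' pairs are the candidate causal links between metabolite and
#' agronomic trait.
#'
#' @param pairs Output of [colocalize()].
#' @param correlation_edges Edge data frame from
#'   [pairwise_correlation()].
#' @param p_threshold Significance threshold on the edge P (default
#'   0.01).
#' @return `pairs` with added `correlated`, `r`, `p_value` columns.
#' @export
cross_reference <- function(pairs, correlation_edges, p_threshold = 0.01) {
  pairs$correlated <- rep(FALSE, nrow(pairs))
  pairs$r <- rep(NA_real_, nrow(pairs))
  pairs$p_value <- rep(NA_real_, nrow(pairs))
  if (!nrow(pairs) || is.null(correlation_edges) ||
      !nrow(correlation_edges)) return(pairs)
  e <- correlation_edges
  key_e <- c(paste(e$trait_a, e$trait_b, sep = "\r"),
             paste(e$trait_b, e$trait_a, sep = "\r"))
  r_e <- c(e$r, e$r); p_e <- c(e$p_value, e$p_value)
  hit <- match(paste(pairs$metabolite_id, pairs$trait_id, sep = "\r"), key_e)
  found <- !is.na(hit)
  pairs$r[found] <- r_e[hit[found]]
  pairs$p_value[found] <- p_e[hit[found]]
  pairs$correlated <- found & !is.na(pairs$p_value) &
    pairs$p_value < p_threshold
  pairs
}
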